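#' Load QC reference ranges
#'
#' Reads a YAML file of named reference ranges. The shipped defaults
#' (`system.file("extdata", "qc_ranges.yaml", package = "mpraqc")`) are
#' editable placeholders meant to be recalibrated on each lab's own
#' historical runs.
#'
#' @param path YAML file; `NULL` loads the shipped defaults.
#' @return Named list of `reference_range` objects.
#' @export
qc_reference_ranges <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "qc_ranges.yaml", package = "mpraqc")
    raw <- yaml::read_yaml(path)
    out <- lapply(names(raw), function(nm) {
        r <- raw[[nm]]
        reference_range(
            metric_name = nm,
            low = if (is.null(r$low)) -Inf else as.numeric(r$low),
            high = if (is.null(r$high)) Inf else as.numeric(r$high),
            direction_of_risk = if (is.null(r$risk)) "both" else r$risk,
            recommendation = if (is.null(r$recommendation)) "" else
                trimws(r$recommendation))
    })
    stats::setNames(out, names(raw))
}

#' Construct a reference range
#'
#' @param metric_name Metric the range applies to.
#' @param low,high Interval bounds (closed); use `-Inf`/`Inf` for
#'   unbounded sides.
#' @param direction_of_risk Which violation is flagged: `"below"`,
#'   `"above"`, or `"both"`.
#' @param recommendation Text shown when the metric is at risk.
#' @return A `reference_range` object.
#' @export
reference_range <- function(metric_name, low = -Inf, high = Inf,
                            direction_of_risk = c("both", "below", "above"),
                            recommendation = "") {
    direction_of_risk <- match.arg(direction_of_risk)
    if (low > high) stop("low must be <= high")
    structure(list(metric_name = metric_name, low = low, high = high,
                   direction_of_risk = direction_of_risk,
                   recommendation = recommendation),
              class = "reference_range")
}

#' Evaluate a metric value against its reference range
#'
#' The interval is closed: boundary values pass. Only violations in the
#' range's risk direction are flagged.
#'
#' @param value Numeric metric value.
#' @param range A [reference_range()].
#' @param step Pipeline step label attached to the result.
#' @return A `qc_metric`: list with `name`, `value`, `status`
#'   (`"pass"`/`"risk"`), `range_used`, `step`, `recommendation`
#'   (non-empty only on risk).
#' @export
qc_evaluate <- function(value, range, step = "") {
    risky <- switch(range$direction_of_risk,
        below = value < range$low,
        above = value > range$high,
        both = value < range$low || value > range$high)
    if (is.na(risky)) risky <- FALSE
    structure(list(name = range$metric_name, value = value,
                   status = if (risky) "risk" else "pass",
                   range_used = range, step = step,
                   recommendation = if (risky) range$recommendation else ""),
              class = "qc_metric")
}

# Default pass-all range for metrics without a configured range.
unbounded_range_ <- function(name)
    reference_range(name, -Inf, Inf, "both", "")

#' Compute the QC metrics of one pipeline step
#'
#' Step labels and their metrics:
#' \describe{
#'   \item{`map`}{`frac_oligos_qualified` (oligos with >=
#'     `min_barcodes_qualified` barcodes), `median_barcodes_per_oligo`,
#'     `frac_reads_merged`, `frac_reads_matched`. Needs `artifacts$map`
#'     and `artifacts$lib`.}
#'   \item{`dna_counts`, `rna_counts`}{`frac_mapped_barcodes_detected`,
#'     `frac_oligos_detected`, `mean_detection_count`,
#'     `frac_reads_unmapped`. Needs `artifacts$coverage`.}
#'   \item{`activity`}{`dna_rna_pearson_r`, `frac_oligos_quantified`.
#'     Needs `artifacts$correlation`, `artifacts$activity`,
#'     `artifacts$map`.}
#' }
#'
#' @param step Step label.
#' @param artifacts Named list of that step's outputs (see above).
#' @param ranges Named list from [qc_reference_ranges()].
#' @param min_barcodes_qualified Barcodes an oligo needs to count as
#'   qualified at step 1.
#' @return List of `qc_metric`s.
#' @export
collect_step_metrics <- function(step, artifacts,
                                 ranges = qc_reference_ranges(),
                                 min_barcodes_qualified = 5L) {
    vals <- switch(step,
        map = {
            map <- artifacts$map
            lib <- artifacts$lib
            bpo <- barcodes_per_oligo(map, lib)
            c(frac_oligos_qualified =
                  mean(bpo >= min_barcodes_qualified),
              median_barcodes_per_oligo = stats::median(as.numeric(bpo)),
              frac_reads_merged =
                  map$n_reads_merged / max(1L, map$n_reads_processed),
              frac_reads_matched =
                  map$n_reads_matched / max(1L, map$n_reads_merged))
        },
        dna_counts = ,
        rna_counts = {
            cov <- artifacts$coverage
            c(frac_mapped_barcodes_detected =
                  cov$frac_mapped_barcodes_detected,
              frac_oligos_detected = cov$frac_oligos_detected,
              mean_detection_count = cov$mean_detection_count,
              frac_reads_unmapped = cov$frac_reads_unmapped)
        },
        activity = {
            corr <- artifacts$correlation
            act <- artifacts$activity
            map <- artifacts$map
            n_all <- length(unique(map$assignments$oligo_id))
            c(dna_rna_pearson_r = corr$pearson_r,
              frac_oligos_quantified = nrow(act) / max(1L, n_all))
        },
        stop("unknown pipeline step label: ", step)
    )
    lapply(names(vals), function(nm) {
        rg <- if (!is.null(ranges[[nm]])) ranges[[nm]] else unbounded_range_(nm)
        qc_evaluate(unname(vals[[nm]]), rg, step = step)
    })
}

qc_metric_frame_ <- function(metrics) {
    do.call(rbind, lapply(metrics, function(m) data.frame(
        step = m$step, metric = m$name, value = m$value,
        low = m$range_used$low, high = m$range_used$high,
        risk_direction = m$range_used$direction_of_risk,
        status = m$status, recommendation = m$recommendation,
        stringsAsFactors = FALSE)))
}

html_escape_ <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a per-step QC report
#'
#' Writes a self-contained HTML report (metric table with pass/risk
#' badges, a recommendation block per risk, embedded figures, and an
#' appendix of extra parameters) plus a machine-readable TSV twin
#' (`qc_<step>.tsv`) holding exactly the same metric rows. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param step Step label.
#' @param metrics List of `qc_metric`s from [collect_step_metrics()].
#' @param figures Paths of PNG figures to embed (missing files are
#'   skipped).
#' @param extras Optional data.frame appended as an appendix table.
#' @param outdir Output directory.
#' @return Invisibly, a list with the `html` and `tsv` paths.
#' @export
render_qc_report <- function(step, metrics, figures = character(),
                             extras = NULL, outdir = ".") {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(outdir, paste0("qc_", step, ".tsv"))
    df <- qc_metric_frame_(metrics)
    write_table(df, tsv)

    fmt_bound <- function(b) ifelse(is.finite(b), format(b, digits = 6), "-")
    rows <- vapply(seq_len(nrow(df)), function(i) sprintf(
        paste0("<tr class=\"%s\"><td>%s</td><td>%s</td><td>[%s, %s]</td>",
               "<td>%s</td><td class=\"badge %s\">%s</td></tr>"),
        df$status[i], html_escape_(df$metric[i]),
        format(df$value[i], digits = 6),
        fmt_bound(df$low[i]), fmt_bound(df$high[i]),
        df$risk_direction[i], df$status[i], toupper(df$status[i])),
        character(1))

    risks <- df[df$status == "risk", , drop = FALSE]
    risk_html <- if (nrow(risks) == 0L) {
        "<p>No risk flags for this step.</p>"
    } else {
        paste(vapply(seq_len(nrow(risks)), function(i) sprintf(
            paste0("<div class=\"recommendation\"><b>%s</b> ",
                   "(value %s): %s</div>"),
            html_escape_(risks$metric[i]),
            format(risks$value[i], digits = 6),
            html_escape_(risks$recommendation[i])), character(1)),
            collapse = "\n")
    }

    fig_html <- ""
    for (f in figures) {
        if (!file.exists(f)) next
        b64 <- jsonlite::base64_enc(readBin(f, "raw", file.info(f)$size))
        b64 <- gsub("\n", "", b64, fixed = TRUE)
        fig_html <- paste0(fig_html, sprintf(
            "<div class=\"figure\"><img src=\"data:image/png;base64,%s\" alt=\"%s\"/><p>%s</p></div>\n",
            b64, html_escape_(basename(f)), html_escape_(basename(f))))
    }

    extra_html <- ""
    if (!is.null(extras) && nrow(as.data.frame(extras)) > 0L) {
        ex <- as.data.frame(extras)
        hdr <- paste0("<tr>", paste0("<th>", html_escape_(colnames(ex)),
                                     "</th>", collapse = ""), "</tr>")
        body <- vapply(seq_len(nrow(ex)), function(i) paste0(
            "<tr>", paste0("<td>",
                           html_escape_(as.character(unlist(ex[i, ]))),
                           "</td>", collapse = ""), "</tr>"), character(1))
        extra_html <- paste0(
            "<h2>Additional parameters</h2>\n<table>", hdr,
            paste(body, collapse = "\n"), "</table>\n")
    }

    html <- file.path(outdir, paste0("report_", step, ".html"))
    writeLines(c(
        "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
        sprintf("<title>QC report: %s</title>", html_escape_(step)),
        "<style>",
        "body{font-family:sans-serif;margin:2em;max-width:60em}",
        "table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px 8px}",
        "tr.risk{background:#ffe5e5}.badge.risk{color:#a00;font-weight:bold}",
        ".badge.pass{color:#070}.recommendation{border-left:4px solid #a00;",
        "padding:6px 10px;margin:8px 0;background:#fff3f3}",
        ".figure img{max-width:100%}",
        "</style></head><body>",
        sprintf("<h1>QC report: step ‘%s’</h1>", html_escape_(step)),
        "<p>Reference ranges are editable placeholders; calibrate them on",
        "your own historical runs before relying on pass/risk flags.</p>",
        "<h2>Metrics</h2>",
        "<table><tr><th>metric</th><th>value</th><th>reference range</th>",
        "<th>risk direction</th><th>status</th></tr>",
        rows,
        "</table>",
        "<h2>Risk factors and recommendations</h2>",
        risk_html,
        if (nzchar(fig_html)) c("<h2>Figures</h2>", fig_html) else character(),
        extra_html,
        "</body></html>"
    ), html)
    invisible(list(html = html, tsv = tsv))
}
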