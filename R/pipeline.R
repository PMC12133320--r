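#' Re-load a barcode map written by [run_map()]
#' @param path Path to `barcode_map.tsv`.
#' @param stats_path Optional `mapping_stats.tsv` to restore counters.
#' @return A `barcode_map`.
#' @export
read_barcode_map <- function(path, stats_path = NULL) {
    df <- read_table_tsv(path)
    need <- c("barcode", "oligo_id", "support", "total", "purity")
    if (!all(need %in% colnames(df)))
        stop("not a barcode_map.tsv: missing columns")
    cnt <- list(n_reads_processed = nrow(df), n_reads_merged = nrow(df),
                n_reads_matched = nrow(df), n_reads_unmatched = 0L,
                dropped_conflicts = 0L, dropped_low_support = 0L)
    if (!is.null(stats_path) && file.exists(stats_path)) {
        st <- read_table_tsv(stats_path)
        v <- stats::setNames(st$value, st$metric)
        for (nm in names(cnt))
            if (nm %in% names(v)) cnt[[nm]] <- as.integer(v[[nm]])
    }
    structure(list(assignments = df[order(df$barcode), , drop = FALSE],
                   n_reads_processed = cnt$n_reads_processed,
                   n_reads_merged = cnt$n_reads_merged,
                   n_reads_matched = cnt$n_reads_matched,
                   n_reads_unmatched = cnt$n_reads_unmatched,
                   extraction_failures = c(no_flank = 0L, short = 0L,
                                           N_in_barcode = 0L),
                   dropped_conflicts = cnt$dropped_conflicts,
                   dropped_low_support = cnt$dropped_low_support,
                   params = list()),
              class = "barcode_map")
}

#' Re-load a count table written by [run_counts()]
#' @param path Path to `counts_<sample>.tsv`.
#' @param sample_id Sample label (default from filename).
#' @return A `barcode_counts`.
#' @export
read_counts_table <- function(path, sample_id = NULL) {
    if (is.null(sample_id))
        sample_id <- sub("^counts_", "",
                         tools::file_path_sans_ext(basename(path)))
    df <- read_table_tsv(path)
    barcode_counts(df$barcode, df$count, sample_id = sample_id)
}

plot_png_ <- function(path, expr, width = 720, height = 480) {
    ok <- tryCatch({
        grDevices::png(path, width = width, height = height, type = "cairo")
        on.exit(grDevices::dev.off(), add = TRUE)
        expr
        TRUE
    }, error = function(e) FALSE)
    if (ok && file.exists(path)) path else character(0)
}

mapping_stats_frame_ <- function(map) {
    data.frame(
        metric = c("n_reads_processed", "n_reads_merged", "n_reads_matched",
                   "n_reads_unmatched", "fail_no_flank", "fail_short",
                   "fail_N_in_barcode", "n_barcodes_assigned",
                   "dropped_conflicts", "dropped_low_support"),
        value = c(map$n_reads_processed, map$n_reads_merged,
                  map$n_reads_matched, map$n_reads_unmatched,
                  map$extraction_failures[["no_flank"]],
                  map$extraction_failures[["short"]],
                  map$extraction_failures[["N_in_barcode"]],
                  nrow(map$assignments), map$dropped_conflicts,
                  map$dropped_low_support),
        stringsAsFactors = FALSE)
}

#' Step 1 runner: association mapping with artifacts and QC report
#'
#' @param r1,r2,premerged FASTQ inputs (see [map_barcodes()]).
#' @param library_fasta Designed oligo FASTA.
#' @param outdir Output directory.
#' @param rs A [read_structure()] for the merged fragments.
#' @param ranges QC reference ranges.
#' @param min_barcodes_qualified "Qualified oligo" barcode threshold.
#' @inheritParams map_barcodes
#' @return Invisibly, list with the `barcode_map` and artifact paths.
#' @export
run_map <- function(r1 = NULL, r2 = NULL, library_fasta, outdir,
                    rs = read_structure(), premerged = NULL,
                    min_support = 3L, purity_threshold = 0.75,
                    max_mismatches = 0L, min_overlap = 10L,
                    max_mismatch_frac = 0.1,
                    ranges = qc_reference_ranges(),
                    min_barcodes_qualified = 5L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    lib <- read_fasta(library_fasta)
    map <- map_barcodes(r1, r2, lib, rs, premerged = premerged,
                        min_support = min_support,
                        purity_threshold = purity_threshold,
                        max_mismatches = max_mismatches,
                        min_overlap = min_overlap,
                        max_mismatch_frac = max_mismatch_frac)
    map_path <- file.path(outdir, "barcode_map.tsv")
    write_table(map$assignments, map_path)
    stats_path <- file.path(outdir, "mapping_stats.tsv")
    write_table(mapping_stats_frame_(map), stats_path)
    bpo <- barcodes_per_oligo(map, lib)
    bpo_path <- file.path(outdir, "barcodes_per_oligo.tsv")
    write_table(data.frame(oligo_id = names(bpo), n_barcodes = unname(bpo),
                           stringsAsFactors = FALSE), bpo_path)
    fig <- plot_png_(file.path(outdir, "barcodes_per_oligo.png"), {
        graphics::hist(bpo, breaks = 30, col = "steelblue",
                       main = "Barcodes per oligo",
                       xlab = "unique barcodes per designed oligo")
    })
    metrics <- collect_step_metrics("map", list(map = map, lib = lib),
                                    ranges = ranges,
                                    min_barcodes_qualified =
                                        min_barcodes_qualified)
    render_qc_report("map", metrics, figures = fig,
                     extras = mapping_stats_frame_(map), outdir = outdir)
    invisible(list(map = map, lib = lib,
                   paths = c(map = map_path, stats = stats_path,
                             barcodes_per_oligo = bpo_path)))
}

#' Steps 2-3 runner: barcode counting with coverage, saturation and QC
#'
#' @param reads FASTQ path of the barcode-bearing reads.
#' @param map A `barcode_map` or path to `barcode_map.tsv`.
#' @param library_fasta Designed oligo FASTA (or an `oligo_library`).
#' @param sample_id Sample label, used in artifact names.
#' @param role `"dna"` or `"rna"` (sets the QC step label).
#' @param outdir Output directory.
#' @param rs A [read_structure()] for these reads.
#' @param fractions,n_resamples,seed Saturation settings.
#' @param ranges QC reference ranges.
#' @return Invisibly, list with `counts`, `coverage`, `saturation` and
#'   artifact paths.
#' @export
run_counts <- function(reads, map, library_fasta, sample_id,
                       role = c("dna", "rna"), outdir,
                       rs = read_structure(),
                       fractions = seq(0.1, 1, by = 0.1),
                       n_resamples = 20L, seed = 17L,
                       ranges = qc_reference_ranges()) {
    role <- match.arg(role)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (is.character(map)) {
        if (!file.exists(map))
            stop("barcode map not found (run the mapping step first): ", map)
        map <- read_barcode_map(map)
    }
    lib <- if (inherits(library_fasta, "oligo_library")) library_fasta
           else read_fasta(library_fasta)
    counts <- count_barcodes(reads, rs, sample_id = sample_id)
    asg <- map$assignments
    oligo <- asg$oligo_id[match(counts$counts$barcode, asg$barcode)]
    counts_path <- file.path(outdir, paste0("counts_", sample_id, ".tsv"))
    write_table(data.frame(counts$counts,
                           oligo_id = ifelse(is.na(oligo), "NA", oligo),
                           stringsAsFactors = FALSE), counts_path)
    cov <- coverage_stats(counts, map, lib)
    cov_df <- data.frame(
        metric = c("n_mapped_barcodes_detected",
                   "frac_mapped_barcodes_detected", "n_oligos_detected",
                   "frac_oligos_detected", "mean_detection_count",
                   "frac_reads_unmapped"),
        value = c(cov$n_mapped_barcodes_detected,
                  cov$frac_mapped_barcodes_detected, cov$n_oligos_detected,
                  cov$frac_oligos_detected, cov$mean_detection_count,
                  cov$frac_reads_unmapped),
        stringsAsFactors = FALSE)
    cov_path <- file.path(outdir, paste0("coverage_", sample_id, ".tsv"))
    write_table(cov_df, cov_path)
    sat <- saturation(counts, map, lib, fractions = fractions,
                      n_resamples = n_resamples, seed = seed)
    sat_path <- file.path(outdir, paste0("saturation_", sample_id, ".tsv"))
    write_table(as.data.frame(sat), sat_path)
    figs <- c(
        plot_png_(file.path(outdir, paste0("hist_", sample_id, ".png")), {
            det <- counts$counts$count
            graphics::hist(log10(det), breaks = 40, col = "grey60",
                           main = paste("Barcode count distribution:",
                                        sample_id),
                           xlab = "log10 detection count")
        }),
        plot_png_(file.path(outdir, paste0("saturation_", sample_id,
                                           ".png")), {
            graphics::plot(sat$fraction, sat$barcode_coverage, type = "b",
                           ylim = c(0, 1), col = "steelblue", pch = 16,
                           xlab = "subsampling fraction", ylab = "coverage",
                           main = paste("Saturation:", sample_id))
            graphics::lines(sat$fraction, sat$oligo_coverage, type = "b",
                            col = "tomato", pch = 17)
            graphics::legend("bottomright", c("barcodes", "oligos"),
                             col = c("steelblue", "tomato"),
                             pch = c(16, 17), lty = 1, bty = "n")
        }))
    step <- paste0(role, "_counts")
    metrics <- collect_step_metrics(step, list(coverage = cov),
                                    ranges = ranges)
    render_qc_report(step, metrics, figures = figs, extras = cov_df,
                     outdir = outdir)
    invisible(list(counts = counts, coverage = cov, saturation = sat,
                   paths = c(counts = counts_path, coverage = cov_path,
                             saturation = sat_path)))
}

#' Step 4 runner: activity quantification with QC
#'
#' @param dna_counts,rna_counts `barcode_counts` objects or paths to
#'   `counts_*.tsv` files.
#' @param map A `barcode_map` or path to `barcode_map.tsv`.
#' @param outdir Output directory.
#' @param sample_id Label for the activity table artifacts.
#' @param min_dna_count,min_barcodes,include_missing_rna See
#'   [compute_activity()].
#' @param pseudocount Log pseudocount for the DNA-RNA correlation, CPM.
#' @param ranges QC reference ranges.
#' @return Invisibly, list with `activity`, `correlation`, `dna_norm`,
#'   `rna_norm` and artifact paths.
#' @export
run_activity <- function(dna_counts, rna_counts, map, outdir,
                         sample_id = "rep1", min_dna_count = 0,
                         min_barcodes = 1L, include_missing_rna = TRUE,
                         pseudocount = 1,
                         ranges = qc_reference_ranges()) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (is.character(map)) {
        if (!file.exists(map))
            stop("barcode map not found (run the mapping step first): ", map)
        map <- read_barcode_map(map)
    }
    if (is.character(dna_counts)) dna_counts <- read_counts_table(dna_counts)
    if (is.character(rna_counts)) rna_counts <- read_counts_table(rna_counts)
    dna <- normalize_counts(dna_counts, map)
    rna <- normalize_counts(rna_counts, map)
    act <- compute_activity(dna, rna, map, min_dna_count = min_dna_count,
                            min_barcodes = min_barcodes,
                            include_missing_rna = include_missing_rna)
    act_path <- file.path(outdir, paste0("activity_", sample_id, ".tsv"))
    write_table(as.data.frame(act), act_path)
    dropped <- attr(act, "dropped")
    drop_path <- file.path(outdir, paste0("dropped_oligos_", sample_id,
                                          ".tsv"))
    write_table(dropped, drop_path)
    corr <- dna_rna_correlation(dna, rna, pseudocount = pseudocount)
    fig <- plot_png_(file.path(outdir, paste0("dna_rna_", sample_id,
                                              ".png")), {
        shared <- intersect(dna$values$barcode, rna$values$barcode)
        x <- log2(dna$values$cpm[match(shared, dna$values$barcode)] +
                      pseudocount)
        y <- log2(rna$values$cpm[match(shared, rna$values$barcode)] +
                      pseudocount)
        graphics::plot(x, y, pch = ".", col = "#00000044",
                       xlab = "log2 DNA CPM", ylab = "log2 RNA CPM",
                       main = sprintf("DNA vs RNA abundance (r = %.3f)",
                                      corr$pearson_r))
    })
    metrics <- collect_step_metrics(
        "activity", list(correlation = corr, activity = act, map = map),
        ranges = ranges)
    render_qc_report("activity", metrics, figures = fig,
                     extras = data.frame(
                         parameter = c("min_dna_count", "min_barcodes",
                                       "pseudocount", "n_shared_barcodes"),
                         value = c(min_dna_count, min_barcodes, pseudocount,
                                   corr$n_shared_barcodes)),
                     outdir = outdir)
    invisible(list(activity = act, correlation = corr, dna_norm = dna,
                   rna_norm = rna,
                   paths = c(activity = act_path, dropped = drop_path)))
}

#' Step 5 runner: replicate concordance
#'
#' @param activity_files Paths to `activity_<rep>.tsv` files (>= 2).
#' @param outdir Output directory.
#' @param ids Replicate labels (default from file names).
#' @return Invisibly, the `replicate_comparison` plus artifact path.
#' @export
run_compare <- function(activity_files, outdir, ids = NULL) {
    if (length(activity_files) < 2L)
        stop("need at least two activity tables to compare")
    missing <- activity_files[!file.exists(activity_files)]
    if (length(missing) > 0L)
        stop("activity table(s) not found (run the activity step first): ",
             paste(missing, collapse = ", "))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(ids))
        ids <- sub("^activity_", "",
                   tools::file_path_sans_ext(basename(activity_files)))
    tables <- lapply(activity_files, read_table_tsv)
    cmp <- compare_replicates(tables, ids = ids)
    path <- file.path(outdir, "replicate_correlations.tsv")
    write_table(cmp$pairs, path)
    for (i in seq_len(nrow(cmp$pairs))) {
        a <- tables[[match(cmp$pairs$rep_a[i], ids)]]
        b <- tables[[match(cmp$pairs$rep_b[i], ids)]]
        shared <- intersect(a$oligo_id, b$oligo_id)
        x <- a$log2_activity[match(shared, a$oligo_id)]
        y <- b$log2_activity[match(shared, b$oligo_id)]
        plot_png_(file.path(outdir, sprintf("scatter_%s_vs_%s.png",
                                            cmp$pairs$rep_a[i],
                                            cmp$pairs$rep_b[i])), {
            graphics::plot(x, y, pch = 16, col = "#33557788",
                           xlab = paste("log2 activity,", cmp$pairs$rep_a[i]),
                           ylab = paste("log2 activity,", cmp$pairs$rep_b[i]),
                           main = sprintf("r = %.3f",
                                          cmp$pairs$pearson_log2[i]))
            graphics::abline(0, 1, lty = 2)
        })
    }
    invisible(list(comparison = cmp, paths = c(correlations = path)))
}

#' Simulate a full synthetic experiment to disk
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory.
#' @param gzip Write gzipped FASTQ.
#' @return Invisibly, list with the `truth` object and all file paths.
#' @export
run_simulate <- function(cfg = sim_config(), outdir = ".", gzip = FALSE) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    truth <- simulate_truth(cfg)
    lib_path <- file.path(outdir, "library.fa")
    write_truth_library(truth, lib_path)
    write_truth_tables(truth, outdir)
    r1 <- file.path(outdir, paste0("assoc_r1", ext))
    r2 <- file.path(outdir, paste0("assoc_r2", ext))
    emit_step1_reads(truth, cfg, r1, r2)
    dna <- rna <- character(cfg$n_replicates)
    for (r in seq_len(cfg$n_replicates)) {
        dna[r] <- file.path(outdir, paste0("dna_rep", r, ext))
        emit_count_reads(truth, cfg, "dna", r, dna[r])
        rna[r] <- file.path(outdir, paste0("rna_rep", r, ext))
        emit_count_reads(truth, cfg, "rna", r, rna[r])
    }
    invisible(list(truth = truth,
                   paths = list(library = lib_path, r1 = r1, r2 = r2,
                                dna = dna, rna = rna)))
}

#' Run the whole pipeline on a simulated experiment
#'
#' Simulates reads, maps barcodes, counts each DNA/RNA replicate,
#' quantifies activity per replicate, compares replicates, and writes
#' the downstream-export matrices — all under `outdir`, with a QC
#' report per step. QC risks never fail the run; they are advisories.
#'
#' @param outdir Output directory.
#' @param cfg A [sim_config()] (scale it down for smoke tests).
#' @param min_support,purity_threshold,max_mismatches Mapping filters.
#' @param min_dna_count,min_barcodes Activity filters.
#' @param n_resamples,seed Saturation settings (`seed` defaults to the
#'   simulation seed).
#' @param gzip Write gzipped FASTQ.
#' @return Invisibly, list of per-step results and paths.
#' @export
run_all <- function(outdir, cfg = sim_config(), min_support = 3L,
                    purity_threshold = 0.75, max_mismatches = 0L,
                    min_dna_count = 0, min_barcodes = 1L,
                    n_resamples = 20L, seed = NULL, gzip = FALSE) {
    if (is.null(seed)) seed <- cfg$seed
    sim <- run_simulate(cfg, outdir, gzip = gzip)
    mp <- run_map(sim$paths$r1, sim$paths$r2, sim$paths$library, outdir,
                  rs = default_read_structure(cfg, "map"),
                  min_support = min_support,
                  purity_threshold = purity_threshold,
                  max_mismatches = max_mismatches)
    rs_cnt <- default_read_structure(cfg, "counts")
    acts <- character(cfg$n_replicates)
    dna_tabs <- list(); rna_tabs <- list()
    for (r in seq_len(cfg$n_replicates)) {
        d <- run_counts(sim$paths$dna[r], mp$map, mp$lib,
                        sample_id = paste0("dna_rep", r), role = "dna",
                        outdir = outdir, rs = rs_cnt,
                        n_resamples = n_resamples, seed = seed + r)
        rn <- run_counts(sim$paths$rna[r], mp$map, mp$lib,
                         sample_id = paste0("rna_rep", r), role = "rna",
                         outdir = outdir, rs = rs_cnt,
                         n_resamples = n_resamples, seed = seed + 100L + r)
        dna_tabs[[r]] <- d$counts
        rna_tabs[[r]] <- rn$counts
        a <- run_activity(d$counts, rn$counts, mp$map, outdir,
                          sample_id = paste0("rep", r),
                          min_dna_count = min_dna_count,
                          min_barcodes = min_barcodes)
        acts[r] <- a$paths[["activity"]]
    }
    cmp <- if (cfg$n_replicates >= 2L) run_compare(acts, outdir) else NULL
    exp <- export_mpranalyze(mp$map, dna_tabs, rna_tabs, outdir,
                             dna_ids = paste0("rep", seq_along(dna_tabs)),
                             rna_ids = paste0("rep", seq_along(rna_tabs)))
    invisible(list(sim = sim, map = mp, activity_paths = acts,
                   comparison = cmp, export = exp, outdir = outdir))
}

#' Dispatch one pipeline step by name
#'
#' Thin programmatic mirror of the command-line interface: `step` is
#' one of `map`, `dna-counts`, `rna-counts`, `activity`, `compare-reps`,
#' `export-mpranalyze`, `simulate`, `all`; `args` is a named list of
#' the matching runner's arguments.
#'
#' @param step Step name.
#' @param args Named list of arguments for the step's `run_*` function.
#' @return The runner's (invisible) result.
#' @export
run_step <- function(step, args = list()) {
    fn <- switch(step,
        "map" = run_map,
        "dna-counts" = function(...) run_counts(role = "dna", ...),
        "rna-counts" = function(...) run_counts(role = "rna", ...),
        "activity" = run_activity,
        "compare-reps" = run_compare,
        "export-mpranalyze" = export_mpranalyze,
        "simulate" = run_simulate,
        "all" = run_all,
        stop("unknown step: ", step))
    do.call(fn, args)
}
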