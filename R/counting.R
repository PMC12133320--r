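#' Count barcodes in a DNA or RNA sequencing sample (steps 2 and 3)
#'
#' Tallies the barcode extracted from each read. Plasmid-DNA and
#' RNA/cDNA runs share this code path: both measure the relative
#' abundance of each random barcode, differing only in sample role. For
#' paired-end counting runs pass only the barcode-bearing mate.
#'
#' @param reads Path to a FASTQ file, a [fastq_stream()], or a
#'   data.frame with a `sequence` column.
#' @param rs A [read_structure()] describing where the barcode sits in
#'   these reads (set `barcode_revcomp` if they present it flipped).
#' @param sample_id Sample label stored with the table.
#' @return A `barcode_counts` object: `sample_id`, `counts` (data.frame
#'   `barcode`, `count`, sorted by barcode), `total_reads_processed`,
#'   `total_reads_counted`, and extraction-failure counters.
#' @export
count_barcodes <- function(reads, rs, sample_id = "sample") {
    fail <- c(no_flank = 0L, short = 0L, N_in_barcode = 0L)
    n_proc <- 0L
    tallies <- list()
    consume <- function(seqs) {
        ext <- extract_fields_(seqs, rs)
        bad <- ext$status != "ok"
        if (any(bad)) {
            tb <- table(ext$status[bad])
            fail[names(tb)] <<- fail[names(tb)] + as.integer(tb)
        }
        bcs <- ext$barcode[!bad]
        if (length(bcs) > 0L) {
            dt <- data.table::data.table(barcode = bcs)
            tallies[[length(tallies) + 1L]] <<-
                dt[, .(count = .N), by = barcode]
        }
        invisible()
    }
    if (is.character(reads)) reads <- fastq_stream(reads)
    if (inherits(reads, "fastq_stream")) {
        repeat {
            ch <- reads$read_chunk()
            if (is.null(ch)) break
            n_proc <- n_proc + nrow(ch)
            consume(ch$sequence)
        }
    } else {
        reads <- as.data.frame(reads)
        n_proc <- nrow(reads)
        if (n_proc > 0L) consume(reads$sequence)
    }
    counts <- if (length(tallies) > 0L) {
        tab <- data.table::rbindlist(tallies)[, .(count = sum(count)),
                                              by = barcode]
        data.table::setorder(tab, barcode)
        as.data.frame(tab)
    } else {
        data.frame(barcode = character(), count = integer(),
                   stringsAsFactors = FALSE)
    }
    structure(list(sample_id = sample_id, counts = counts,
                   total_reads_processed = n_proc,
                   total_reads_counted = sum(counts$count),
                   extraction_failures = fail),
              class = "barcode_counts")
}

#' Assemble a `barcode_counts` object from a barcode/count table
#'
#' For pre-counted data (e.g. re-loading `counts_<sample>.tsv`).
#'
#' @param barcodes Character vector.
#' @param counts Positive integer counts, one per barcode.
#' @param sample_id Sample label.
#' @param total_reads_processed Total reads in the run (defaults to the
#'   counted total).
#' @return A `barcode_counts` object.
#' @export
barcode_counts <- function(barcodes, counts, sample_id = "sample",
                           total_reads_processed = NULL) {
    if (length(barcodes) != length(counts))
        stop("barcodes and counts must have equal length")
    if (anyDuplicated(barcodes)) stop("duplicate barcodes in count table")
    counts <- as.integer(counts)
    if (any(counts < 1L)) stop("stored counts must be >= 1")
    ord <- order(barcodes)
    tab <- data.frame(barcode = barcodes[ord], count = counts[ord],
                      stringsAsFactors = FALSE)
    total <- sum(tab$count)
    if (is.null(total_reads_processed)) total_reads_processed <- total
    if (total > total_reads_processed)
        stop("total_reads_counted exceeds total_reads_processed")
    structure(list(sample_id = sample_id, counts = tab,
                   total_reads_processed = as.integer(total_reads_processed),
                   total_reads_counted = total,
                   extraction_failures = c(no_flank = 0L, short = 0L,
                                           N_in_barcode = 0L)),
              class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
    cat("<barcode_counts> ", x$sample_id, ": ", nrow(x$counts),
        " distinct barcodes, ", x$total_reads_counted, "/",
        x$total_reads_processed, " reads counted\n", sep = "")
    invisible(x)
}

#' Sequencing coverage of mapped barcodes and oligos
#'
#' How much of the association map a counting sample actually saw:
#' fraction of mapped barcodes detected, fraction of oligos with at
#' least one detected barcode, the mean detection count per detected
#' mapped barcode, and the detection-count histogram. Reads whose
#' barcode is absent from the map are reported as `frac_reads_unmapped`
#' and excluded from everything else.
#'
#' @param counts A `barcode_counts` object.
#' @param map A `barcode_map` (must be non-empty: step 1 precedes).
#' @param lib An `oligo_library`.
#' @return A `coverage_stats` list.
#' @export
coverage_stats <- function(counts, map, lib) {
    asg <- map$assignments
    if (nrow(asg) == 0L)
        stop("barcode map is empty; run the association-mapping step first")
    tab <- counts$counts
    idx <- match(tab$barcode, asg$barcode)
    mapped <- !is.na(idx)
    det <- tab[mapped, , drop = FALSE]
    det_oligos <- unique(asg$oligo_id[idx[mapped]])
    n_det <- nrow(det)
    reads_mapped <- sum(det$count)
    total <- counts$total_reads_counted
    hist_tb <- table(det$count)
    structure(list(
        sample_id = counts$sample_id,
        n_mapped_barcodes_detected = n_det,
        frac_mapped_barcodes_detected = n_det / nrow(asg),
        n_oligos_detected = length(det_oligos),
        frac_oligos_detected = length(det_oligos) / n_oligos(lib),
        mean_detection_count = if (n_det > 0L) reads_mapped / n_det else NaN,
        count_histogram = stats::setNames(as.integer(hist_tb),
                                          names(hist_tb)),
        frac_reads_unmapped = if (total > 0L) 1 - reads_mapped / total else NaN,
        n_map_barcodes = nrow(asg),
        n_lib_oligos = n_oligos(lib)
    ), class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
    cat(sprintf(paste0(
        "<coverage_stats> %s: %d/%d mapped barcodes detected (%.1f%%), ",
        "%d/%d oligos (%.1f%%), mean detection %.2f, %.1f%% reads unmapped\n"),
        x$sample_id, x$n_mapped_barcodes_detected, x$n_map_barcodes,
        100 * x$frac_mapped_barcodes_detected, x$n_oligos_detected,
        x$n_lib_oligos, 100 * x$frac_oligos_detected,
        x$mean_detection_count, 100 * x$frac_reads_unmapped))
    invisible(x)
}

#' Saturation analysis by downsampling
#'
#' Simulates shallower sequencing of the same pool: for each fraction
#' `f < 1`, `n_resamples` subsamples of `round(f * total)` reads are
#' drawn without replacement (multivariate hypergeometric) from the
#' counted-read multiset and barcode/oligo coverage recomputed; the mean
#' over resamples is reported. Fraction 1.0 uses the full table
#' verbatim. Deterministic given `seed`; the caller's RNG state is
#' untouched.
#'
#' @inheritParams coverage_stats
#' @param fractions Ascending subsampling fractions; the last must be 1.
#' @param n_resamples Resamples per fraction below 1.
#' @param seed RNG seed.
#' @return A `saturation_curve`: data.frame with `fraction`,
#'   `barcode_coverage`, `oligo_coverage` plus attributes `n_resamples`
#'   and `seed`.
#' @export
saturation <- function(counts, map, lib, fractions = seq(0.1, 1, by = 0.1),
                       n_resamples = 20L, seed = 17L) {
    if (is.unsorted(fractions, strictly = TRUE) ||
        abs(fractions[length(fractions)] - 1) > 1e-12 ||
        any(fractions <= 0))
        stop("fractions must be strictly ascending in (0,1] ending at 1")
    total <- counts$total_reads_counted
    if (total == 0L) stop("no counted reads; cannot downsample")
    full <- coverage_stats(counts, map, lib)

    asg <- map$assignments
    tab <- counts$counts
    bc_idx <- seq_len(nrow(tab))
    reads_bc <- rep.int(bc_idx, tab$count)       # one entry per read
    map_pos <- match(tab$barcode, asg$barcode)   # NA if unmapped
    oligo_fac <- factor(asg$oligo_id)
    oligo_of_bc <- as.integer(oligo_fac)[map_pos]  # per count-table row
    n_oligo_lib <- n_oligos(lib)
    n_map_bc <- nrow(asg)

    bc_cov <- numeric(length(fractions))
    ol_cov <- numeric(length(fractions))
    with_seed_(seed, {
        for (k in seq_along(fractions)) {
            f <- fractions[k]
            if (abs(f - 1) <= 1e-12) {
                bc_cov[k] <- full$frac_mapped_barcodes_detected
                ol_cov[k] <- full$frac_oligos_detected
                next
            }
            m <- max(1L, round(f * total))
            bsum <- 0; osum <- 0
            for (r in seq_len(n_resamples)) {
                hit <- tabulate(reads_bc[sample.int(total, m)],
                                nbins = nrow(tab)) > 0L
                det_mapped <- hit & !is.na(map_pos)
                bsum <- bsum + sum(det_mapped) / n_map_bc
                osum <- osum +
                    length(unique(oligo_of_bc[det_mapped])) / n_oligo_lib
            }
            bc_cov[k] <- bsum / n_resamples
            ol_cov[k] <- osum / n_resamples
        }
    })
    structure(data.frame(fraction = fractions, barcode_coverage = bc_cov,
                         oligo_coverage = ol_cov),
              n_resamples = as.integer(n_resamples), seed = as.integer(seed),
              class = c("saturation_curve", "data.frame"))
}
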