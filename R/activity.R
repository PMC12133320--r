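#' Normalize barcode counts to counts-per-million over mapped barcodes
#'
#' The activity ratio presupposes depth-normalized counts; CPM over
#' mapped barcodes is used so the ratio is invariant to sequencing
#' depth. The library size is the total of reads on barcodes present in
#' the association map; unmapped barcodes are excluded.
#'
#' @param counts A `barcode_counts` object.
#' @param map A `barcode_map`.
#' @return A `normalized_counts` object: `sample_id`, `values`
#'   (data.frame `barcode`, `oligo_id`, `cpm`), `library_size`.
#' @export
normalize_counts <- function(counts, map) {
    asg <- map$assignments
    if (nrow(asg) == 0L) stop("barcode map is empty")
    tab <- counts$counts
    idx <- match(tab$barcode, asg$barcode)
    keep <- !is.na(idx)
    lib_size <- sum(tab$count[keep])
    if (lib_size == 0L)
        stop("no counted reads fall on mapped barcodes in sample ",
             counts$sample_id)
    values <- data.frame(barcode = tab$barcode[keep],
                         oligo_id = asg$oligo_id[idx[keep]],
                         cpm = tab$count[keep] / lib_size * 1e6,
                         stringsAsFactors = FALSE)
    structure(list(sample_id = counts$sample_id, values = values,
                   library_size = lib_size),
              class = "normalized_counts")
}

#' Per-oligo regulatory activity: ratio of summed normalized counts
#'
#' For each oligo, activity = (sum of normalized RNA counts over its
#' usable barcodes) / (sum of normalized plasmid counts over the same
#' barcodes). A barcode is usable iff it is present in the DNA sample
#' with CPM >= `min_dna_count`; a usable barcode absent from the RNA
#' sample contributes 0 to the numerator (set `include_missing_rna =
#' FALSE` to drop such barcodes instead). Oligos with fewer than
#' `min_barcodes` usable barcodes are dropped and reported.
#'
#' Aggregation is ratio-of-sums, not mean-of-ratios: barcodes are
#' weighted by their plasmid abundance, which stabilizes the estimate
#' when barcode representation is skewed.
#'
#' @param dna,rna `normalized_counts` derived from the same map.
#' @param map The `barcode_map` both were normalized against.
#' @param min_dna_count Minimum DNA CPM for a barcode to be usable
#'   (0 = presence in the DNA sample suffices).
#' @param min_barcodes Minimum usable barcodes per reported oligo.
#' @param include_missing_rna Include usable barcodes missing from RNA
#'   as zero-RNA observations (default) or drop them.
#' @return An `activity_table`: data.frame with `oligo_id`,
#'   `n_barcodes_used`, `dna_sum`, `rna_sum`, `activity`,
#'   `log2_activity`, sorted by `oligo_id`; attribute `dropped` is a
#'   data.frame (`oligo_id`, `reason`) of filtered oligos.
#' @export
compute_activity <- function(dna, rna, map, min_dna_count = 0,
                             min_barcodes = 1L,
                             include_missing_rna = TRUE) {
    dv <- dna$values
    usable <- dv[dv$cpm >= min_dna_count, , drop = FALSE]
    rna_cpm <- rna$values$cpm[match(usable$barcode, rna$values$barcode)]
    if (include_missing_rna) {
        rna_cpm[is.na(rna_cpm)] <- 0
    } else {
        keep <- !is.na(rna_cpm)
        usable <- usable[keep, , drop = FALSE]
        rna_cpm <- rna_cpm[keep]
    }
    dt <- data.table::data.table(oligo_id = usable$oligo_id,
                                 dna_cpm = usable$cpm, rna_cpm = rna_cpm)
    agg <- dt[, .(n_barcodes_used = .N, dna_sum = sum(dna_cpm),
                  rna_sum = sum(rna_cpm)), by = oligo_id]
    data.table::setorder(agg, oligo_id)
    enough <- agg$n_barcodes_used >= min_barcodes
    out <- as.data.frame(agg[enough])
    out$activity <- out$rna_sum / out$dna_sum
    out$log2_activity <- log2(out$activity)

    all_oligos <- sort(unique(map$assignments$oligo_id))
    dropped <- data.frame(oligo_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
    no_bc <- setdiff(all_oligos, agg$oligo_id)
    if (length(no_bc) > 0L)
        dropped <- rbind(dropped, data.frame(oligo_id = no_bc,
                                             reason = "no_usable_barcodes"))
    few <- agg$oligo_id[!enough]
    if (length(few) > 0L)
        dropped <- rbind(dropped, data.frame(oligo_id = few,
                                             reason = "too_few_barcodes"))
    dropped <- dropped[order(dropped$oligo_id), , drop = FALSE]
    rownames(dropped) <- NULL
    structure(out, dropped = dropped, class = c("activity_table",
                                                "data.frame"))
}

#' DNA-RNA abundance correlation (residual-plasmid QC)
#'
#' Pearson correlation of log2(CPM + pseudocount) over barcodes present
#' in both samples. Reporter RNA abundance should decouple from plasmid
#' abundance once oligo activities vary; an excessively high correlation
#' indicates plasmid DNA was not removed before reverse transcription.
#'
#' @param dna,rna `normalized_counts` objects.
#' @param pseudocount Added before taking log2 (CPM units).
#' @return List with `pearson_r`, `n_shared_barcodes`, `zero_variance`
#'   (TRUE when either sample is constant across shared barcodes, in
#'   which case `pearson_r` is reported as 0).
#' @export
dna_rna_correlation <- function(dna, rna, pseudocount = 1) {
    shared <- intersect(dna$values$barcode, rna$values$barcode)
    if (length(shared) < 3L)
        stop("need >= 3 shared barcodes for the DNA-RNA correlation, got ",
             length(shared))
    x <- log2(dna$values$cpm[match(shared, dna$values$barcode)] + pseudocount)
    y <- log2(rna$values$cpm[match(shared, rna$values$barcode)] + pseudocount)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(pearson_r = 0, n_shared_barcodes = length(shared),
                    zero_variance = TRUE))
    list(pearson_r = stats::cor(x, y), n_shared_barcodes = length(shared),
         zero_variance = FALSE)
}

#' Pairwise concordance of replicate activity tables
#'
#' Pearson and Spearman correlations of `log2_activity` over the oligos
#' shared by each pair of replicates (non-finite log-activities, i.e.
#' zero-RNA oligos, are excluded pairwise). Pairs sharing fewer than 3
#' oligos are reported as `NA`.
#'
#' @param tables List of `activity_table`s (>= 2).
#' @param ids Replicate labels (default `rep1`, `rep2`, ...).
#' @return A `replicate_comparison`: list of symmetric matrices
#'   `pearson`, `spearman`, `n_shared`, and a long-format data.frame
#'   `pairs`.
#' @export
compare_replicates <- function(tables, ids = NULL) {
    k <- length(tables)
    if (k < 2L) stop("need at least 2 activity tables")
    if (is.null(ids)) ids <- paste0("rep", seq_len(k))
    pe <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
    sp <- pe
    ns <- matrix(0L, k, k, dimnames = list(ids, ids))
    diag(pe) <- 1; diag(sp) <- 1
    for (i in seq_len(k)) ns[i, i] <- nrow(tables[[i]])
    rows <- list()
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
        a <- tables[[i]]; b <- tables[[j]]
        shared <- intersect(a$oligo_id, b$oligo_id)
        x <- a$log2_activity[match(shared, a$oligo_id)]
        y <- b$log2_activity[match(shared, b$oligo_id)]
        fin <- is.finite(x) & is.finite(y)
        x <- x[fin]; y <- y[fin]
        n <- length(x)
        ns[i, j] <- ns[j, i] <- n
        if (n >= 3L) {
            pe[i, j] <- pe[j, i] <- stats::cor(x, y)
            sp[i, j] <- sp[j, i] <- stats::cor(x, y, method = "spearman")
        }
        rows[[length(rows) + 1L]] <- data.frame(
            rep_a = ids[i], rep_b = ids[j], n_shared_oligos = n,
            pearson_log2 = pe[i, j], spearman_log2 = sp[i, j],
            stringsAsFactors = FALSE)
    }
    structure(list(pearson = pe, spearman = sp, n_shared = ns,
                   pairs = do.call(rbind, rows)),
              class = "replicate_comparison")
}

#' @export
print.replicate_comparison <- function(x, ...) {
    cat("<replicate_comparison> Pearson(log2 activity):\n")
    print(round(x$pearson, 3))
    invisible(x)
}
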