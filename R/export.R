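#' Export count matrices for MPRAnalyze-style downstream modelling
#'
#' Writes the wide DNA and RNA count matrices plus a column annotation,
#' in the layout MPRAnalyze expects: one row per oligo (with at least
#' one mapped barcode), one column per (replicate, barcode-slot) pair.
#' Within an oligo, barcodes are ordered lexicographically into slots
#' `1..B`; the slot-to-barcode assignment is identical across DNA, RNA
#' and all replicates. Raw (unnormalized) counts are written; a barcode
#' undetected in a sample is 0, or `NA` with `na_missing = TRUE`.
#' Columns are named `<replicate>_bc<slot>`.
#'
#' @param map The `barcode_map` all tables were counted against.
#' @param dna_tables,rna_tables Lists of `barcode_counts`, one per
#'   replicate, in matching replicate order.
#' @param outdir Output directory.
#' @param dna_ids,rna_ids Replicate labels (default the tables'
#'   `sample_id`s).
#' @param na_missing Write undetected barcodes as `NA` instead of 0.
#' @return Invisibly, list with `dna`, `rna`, `annotation` file paths
#'   and the in-memory matrices.
#' @export
export_mpranalyze <- function(map, dna_tables, rna_tables, outdir = ".",
                              dna_ids = NULL, rna_ids = NULL,
                              na_missing = FALSE) {
    if (length(dna_tables) == 0L || length(rna_tables) == 0L)
        stop("need at least one DNA and one RNA replicate")
    asg <- map$assignments
    if (nrow(asg) == 0L) stop("barcode map is empty")
    if (is.null(dna_ids))
        dna_ids <- vapply(dna_tables, `[[`, "", "sample_id")
    if (is.null(rna_ids))
        rna_ids <- vapply(rna_tables, `[[`, "", "sample_id")

    # deterministic slot layout: oligos sorted, barcodes lexicographic
    asg <- asg[order(asg$oligo_id, asg$barcode), , drop = FALSE]
    oligos <- unique(asg$oligo_id)
    slot <- stats::ave(seq_len(nrow(asg)), asg$oligo_id,
                       FUN = seq_along)
    b_max <- max(slot)

    fill <- function(tables, ids) {
        mat <- matrix(if (na_missing) NA_integer_ else 0L,
                      nrow = length(oligos), ncol = b_max * length(tables),
                      dimnames = list(oligos, paste0(
                          rep(ids, each = b_max), "_bc",
                          rep(seq_len(b_max), length(tables)))))
        for (r in seq_along(tables)) {
            cnt <- tables[[r]]$counts
            v <- cnt$count[match(asg$barcode, cnt$barcode)]
            if (!na_missing) v[is.na(v)] <- 0L
            col <- (r - 1L) * b_max + slot
            mat[cbind(match(asg$oligo_id, oligos), col)] <- v
        }
        mat
    }
    dna_mat <- fill(dna_tables, dna_ids)
    rna_mat <- fill(rna_tables, rna_ids)

    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_mat <- function(mat, path) {
        df <- data.frame(oligo_id = rownames(mat), mat, check.names = FALSE,
                         stringsAsFactors = FALSE)
        write_table(df, path)
        path
    }
    dna_path <- write_mat(dna_mat, file.path(outdir, "dna_counts.tsv"))
    rna_path <- write_mat(rna_mat, file.path(outdir, "rna_counts.tsv"))
    ann <- rbind(
        data.frame(column = colnames(dna_mat), assay = "dna",
                   replicate = rep(dna_ids, each = b_max),
                   barcode_slot = rep(seq_len(b_max), length(dna_ids)),
                   stringsAsFactors = FALSE),
        data.frame(column = colnames(rna_mat), assay = "rna",
                   replicate = rep(rna_ids, each = b_max),
                   barcode_slot = rep(seq_len(b_max), length(rna_ids)),
                   stringsAsFactors = FALSE))
    ann_path <- file.path(outdir, "col_annotation.tsv")
    write_table(ann, ann_path)
    invisible(list(dna = dna_path, rna = rna_path, annotation = ann_path,
                   dna_matrix = dna_mat, rna_matrix = rna_mat))
}
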