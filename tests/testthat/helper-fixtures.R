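# Shared fixture builders. Everything is generated in code; no files
# ship with the tests.

as_lib <- function(x) structure(x, class = "oligo_library")

write_tmp_fasta <- function(seqs, gz = FALSE) {
    path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
    lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
    con <- if (gz) gzfile(path, "wt") else file(path, "wt")
    writeLines(lines, con)
    close(con)
    path
}

write_tmp_fastq <- function(ids, seqs, quals = NULL, gz = FALSE) {
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
    path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
    lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
    con <- if (gz) gzfile(path, "wt") else file(path, "wt")
    writeLines(lines, con)
    close(con)
    path
}

# barcode_map object built through the public path: synthesizes
# error-free fragments (insert + flank + barcode) and runs
# build_barcode_map with permissive thresholds.
make_map <- function(barcodes, oligo_ids, lib,
                     rs = read_structure(barcode_len = nchar(barcodes[1]),
                                         barcode_flank_up = "GGC")) {
    frags <- data.frame(sequence = paste0(unclass(lib)[oligo_ids], "GGC",
                                          barcodes),
                        stringsAsFactors = FALSE)
    build_barcode_map(frags, lib, rs, min_support = 1L,
                      purity_threshold = 0.5)
}

# tiny two-oligo world reused by counting/activity/export tests:
# O1 has barcodes AAAAAA, CCCCCC, GGGGGG; O2 has TTTTTT
tiny_world <- function() {
    lib <- as_lib(c(O1 = "ACGTACGTAC", O2 = "TGCATGCATG"))
    map <- make_map(c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"),
                    c("O1", "O1", "O1", "O2"), lib)
    list(lib = lib, map = map)
}

# independent base-R re-tally of barcode assignment used as oracle
# against build_barcode_map (no data.table, no shared code path)
oracle_tally <- function(bc, ol, min_support, purity_threshold) {
    assigned <- list()
    dropped_conflicts <- 0L
    dropped_low_support <- 0L
    for (b in unique(bc)) {
        tab <- table(ol[bc == b])
        tot <- sum(tab)
        mx <- max(tab)
        if (sum(tab == mx) > 1L || mx / tot < purity_threshold) {
            dropped_conflicts <- dropped_conflicts + 1L
        } else if (mx < min_support) {
            dropped_low_support <- dropped_low_support + 1L
        } else {
            assigned[[b]] <- data.frame(
                barcode = b, oligo_id = names(tab)[which.max(tab)],
                support = as.integer(mx), total = as.integer(tot),
                purity = mx / tot, stringsAsFactors = FALSE)
        }
    }
    asg <- if (length(assigned) > 0L) do.call(rbind, assigned) else
        data.frame(barcode = character(), oligo_id = character(),
                   support = integer(), total = integer(),
                   purity = numeric())
    asg <- asg[order(asg$barcode), , drop = FALSE]
    rownames(asg) <- NULL
    list(assignments = asg, dropped_conflicts = dropped_conflicts,
         dropped_low_support = dropped_low_support)
}
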