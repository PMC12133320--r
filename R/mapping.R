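#' Describe where the barcode sits in a read or merged fragment
#'
#' MPRA constructs place a short random barcode at one end of the
#' fragment, usually separated from the oligo insert by a constant
#' linker. `read_structure()` captures that layout so the same extractor
#' serves association-mapping fragments and DNA/RNA counting reads.
#'
#' @param barcode_len Barcode length in nt (>= 6).
#' @param barcode_end Which fragment end carries the barcode.
#' @param barcode_flank_up Constant sequence immediately upstream (5') of
#'   the barcode; may be "".
#' @param barcode_flank_down Constant sequence immediately downstream;
#'   may be "".
#' @param insert_trim_left,insert_trim_right Bases trimmed from the
#'   insert after removing barcode and flanks (e.g. primer arms).
#' @param barcode_revcomp Set `TRUE` when this step's reads present the
#'   barcode reverse-complemented relative to the association-mapping
#'   orientation; extracted barcodes are then flipped back so all tables
#'   share one orientation.
#' @return A `read_structure` object.
#' @export
read_structure <- function(barcode_len = 12L,
                           barcode_end = c("three_prime", "five_prime"),
                           barcode_flank_up = "",
                           barcode_flank_down = "",
                           insert_trim_left = 0L,
                           insert_trim_right = 0L,
                           barcode_revcomp = FALSE) {
    barcode_end <- match.arg(barcode_end)
    barcode_len <- as.integer(barcode_len)
    if (barcode_len < 6L) stop("barcode_len must be >= 6")
    for (fl in c(barcode_flank_up, barcode_flank_down))
        if (nzchar(fl) && grepl("[^ACGT]", fl))
            stop("flank sequences must be over {A,C,G,T}")
    if (insert_trim_left < 0L || insert_trim_right < 0L)
        stop("insert trims must be >= 0")
    structure(list(barcode_len = barcode_len,
                   barcode_end = barcode_end,
                   barcode_flank_up = toupper(barcode_flank_up),
                   barcode_flank_down = toupper(barcode_flank_down),
                   insert_trim_left = as.integer(insert_trim_left),
                   insert_trim_right = as.integer(insert_trim_right),
                   barcode_revcomp = isTRUE(barcode_revcomp)),
              class = "read_structure")
}

#' Merge one read pair by overlap consensus
#'
#' The reverse read is reverse-complemented, every candidate overlap of
#' at least `min_overlap` bases is scored, and the overlap with the
#' smallest mismatch fraction wins (ties go to the longest overlap).
#' Disagreeing overlap bases resolve to the higher-quality base, ties to
#' the forward read. Fails (returns `ok = FALSE`) when no overlap has a
#' mismatch fraction at or below `max_mismatch_frac`.
#'
#' @param r1,r2 Lists (or one-row data.frames) with `sequence` and
#'   optionally `quality`; `r1` is the forward read.
#' @param min_overlap Minimum admissible overlap, nt.
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return List with `sequence`, `quality`, `overlap_len`, `ok`.
#' @export
merge_pair <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1) {
    res <- merge_pairs(r1$sequence, r2$sequence,
                       q1 = if (!is.null(r1$quality)) r1$quality,
                       q2 = if (!is.null(r2$quality)) r2$quality,
                       min_overlap = min_overlap,
                       max_mismatch_frac = max_mismatch_frac)
    list(sequence = res$sequence[1], quality = res$quality[1],
         overlap_len = res$overlap_len[1], ok = res$ok[1])
}

#' Merge many read pairs (vectorized)
#'
#' @param s1,s2 Character vectors of forward / reverse read sequences.
#' @param q1,q2 Optional matching Phred quality strings.
#' @inheritParams merge_pair
#' @return data.frame with columns `sequence`, `quality`, `overlap_len`,
#'   `ok`; failed merges have `NA` sequence.
#' @export
merge_pairs <- function(s1, s2, q1 = NULL, q2 = NULL,
                        min_overlap = 10L, max_mismatch_frac = 0.1) {
    if (is.null(q1) || is.null(q2)) {
        q1 <- character(0); q2 <- character(0)
    }
    res <- merge_pairs_cpp(as.character(s1), as.character(q1),
                           as.character(s2), as.character(q2),
                           as.integer(min_overlap), max_mismatch_frac)
    data.frame(sequence = res$sequence, quality = res$quality,
               overlap_len = res$overlap_len, ok = res$ok,
               stringsAsFactors = FALSE)
}

#' Load externally merged fragments
#'
#' Adapter for pipelines that merged read pairs with an external tool
#' (e.g. FLASH2's extended-fragment FASTQ). Overlap lengths are unknown
#' and reported as 0.
#'
#' @param path FASTQ of merged fragments (plain or gzip).
#' @return A [fastq_stream()] over the fragments.
#' @export
load_premerged <- function(path) fastq_stream(path)

# Vectorized barcode/insert extraction. Returns a data.frame with
# columns barcode, insert, status in
# {ok, no_flank, short, N_in_barcode}. The flank search is anchored at
# the configured end but only occurrences leaving >= barcode_len bases
# for the barcode are admissible -- a flank landing by chance inside the
# random barcode must not shadow the true site.
extract_fields_ <- function(seqs, rs) {
    n <- length(seqs)
    bl <- rs$barcode_len
    len <- nchar(seqs)
    barcode <- rep(NA_character_, n)
    insert <- rep(NA_character_, n)
    status <- rep("ok", n)

    if (rs$barcode_end == "three_prime") {
        fl <- rs$barcode_flank_up
        if (nzchar(fl)) {
            head_end <- pmax(len - bl, 0L)
            loc <- stringi::stri_locate_last_fixed(
                stringi::stri_sub(seqs, 1L, head_end), fl)
            hit <- !is.na(loc[, 1L])
            if (any(!hit)) {
                anywhere <- stringi::stri_detect_fixed(seqs[!hit], fl)
                status[!hit] <- ifelse(anywhere, "short", "no_flank")
            }
            bstart <- loc[, 2L] + 1L
            barcode[hit] <- stringi::stri_sub(seqs[hit], bstart[hit],
                                              bstart[hit] + bl - 1L)
            fd <- rs$barcode_flank_down
            if (nzchar(fd)) {
                after <- stringi::stri_sub(seqs, bstart + bl,
                                           bstart + bl + nchar(fd) - 1L)
                bad <- hit & after != fd
                status[bad] <- "no_flank"
                hit <- hit & !bad
            }
            ie <- loc[, 1L] - 1L - rs$insert_trim_right
            insert[hit] <- stringi::stri_sub(seqs[hit],
                                             1L + rs$insert_trim_left, ie[hit])
        } else {
            short <- len < bl
            status[short] <- "short"
            okr <- !short
            barcode[okr] <- stringi::stri_sub(seqs[okr], len[okr] - bl + 1L,
                                              len[okr])
            insert[okr] <- stringi::stri_sub(
                seqs[okr], 1L + rs$insert_trim_left,
                len[okr] - bl - rs$insert_trim_right)
        }
    } else {  # five_prime
        fd <- rs$barcode_flank_down
        if (nzchar(fd)) {
            tail_part <- stringi::stri_sub(seqs, bl + 1L)
            loc <- stringi::stri_locate_first_fixed(tail_part, fd)
            hit <- !is.na(loc[, 1L])
            if (any(!hit)) {
                anywhere <- stringi::stri_detect_fixed(seqs[!hit], fd)
                status[!hit] <- ifelse(anywhere, "short", "no_flank")
            }
            fstart <- loc[, 1L] + bl          # flank start in full seq
            barcode[hit] <- stringi::stri_sub(seqs[hit], fstart[hit] - bl,
                                              fstart[hit] - 1L)
            fu <- rs$barcode_flank_up
            if (nzchar(fu)) {
                before <- stringi::stri_sub(seqs, fstart - bl - nchar(fu),
                                            fstart - bl - 1L)
                bad <- hit & (fstart - bl - nchar(fu) < 1L | before != fu)
                status[bad] <- "no_flank"
                hit <- hit & !bad
            }
            istart <- fstart + nchar(fd) + rs$insert_trim_left
            insert[hit] <- stringi::stri_sub(seqs[hit], istart[hit],
                                             len[hit] - rs$insert_trim_right)
        } else {
            short <- len < bl
            status[short] <- "short"
            okr <- !short
            barcode[okr] <- stringi::stri_sub(seqs[okr], 1L, bl)
            insert[okr] <- stringi::stri_sub(
                seqs[okr], bl + 1L + rs$insert_trim_left,
                len[okr] - rs$insert_trim_right)
        }
    }

    okr <- status == "ok"
    hasN <- okr & stringi::stri_detect_fixed(barcode, "N")
    status[hasN] <- "N_in_barcode"
    okr <- status == "ok"
    barcode[!okr] <- NA_character_
    insert[!okr] <- NA_character_
    if (rs$barcode_revcomp && any(okr))
        barcode[okr] <- revcomp_cpp(barcode[okr])
    data.frame(barcode = barcode, insert = insert, status = status,
               stringsAsFactors = FALSE)
}

#' Extract the barcode and oligo insert from one merged fragment
#'
#' With a non-empty flank the barcode is located by exact flank match
#' searched from the configured end (only positions leaving a full
#' barcode are considered); with empty flanks the terminal
#' `barcode_len` bases are taken. Failure categories: `no_flank`,
#' `short`, `N_in_barcode`.
#'
#' @param frag List or one-row data.frame with a `sequence` element.
#' @param rs A [read_structure()].
#' @return List with `barcode`, `insert`, `status` ("ok" on success).
#' @export
extract_barcode_and_insert <- function(frag, rs) {
    res <- extract_fields_(frag$sequence[1], rs)
    list(barcode = res$barcode[1], insert = res$insert[1],
         status = res$status[1])
}

#' Match an oligo insert against the designed library
#'
#' Exact hash lookup first; if that misses and `max_mismatches > 0`, the
#' unique library sequence of equal length within Hamming distance
#' `max_mismatches` is returned. Ambiguity (two or more oligos at the
#' minimal distance, or duplicated library sequences on an exact hit)
#' yields `NA`.
#'
#' @param insert DNA string.
#' @param lib An `oligo_library`.
#' @param max_mismatches Maximum Hamming distance (0 = exact only).
#' @return Oligo id, or `NA_character_`.
#' @export
match_insert <- function(insert, lib, max_mismatches = 0L) {
    match_inserts(insert, lib, max_mismatches)[1]
}

#' @rdname match_insert
#' @param inserts Character vector of insert sequences.
#' @export
match_inserts <- function(inserts, lib, max_mismatches = 0L) {
    if (length(lib) == 0L) stop("oligo library is empty")
    seqs <- unname(unclass(lib))
    ids <- names(lib)
    dup_seqs <- unique(seqs[duplicated(seqs)])
    idx <- match(inserts, seqs)
    out <- ids[idx]
    if (length(dup_seqs) > 0L)
        out[!is.na(idx) & inserts %in% dup_seqs] <- NA_character_
    if (max_mismatches > 0L) {
        miss <- which(is.na(out) & !is.na(inserts) &
                          !(inserts %in% dup_seqs))
        if (length(miss) > 0L) {
            hidx <- hamming_match_cpp(inserts[miss], seqs,
                                      as.integer(max_mismatches))
            out[miss] <- ids[hidx]
        }
    }
    out
}

#' Build the barcode-to-oligo association map (step 1)
#'
#' Tallies (barcode, oligo) read support over merged fragments. Each
#' barcode is assigned its modal oligo iff the modal support is at least
#' `min_support` and the purity (modal support / total reads for the
#' barcode) is at least `purity_threshold`; a tie at the mode always
#' drops the barcode. Order of the fragment stream does not affect the
#' result.
#'
#' @param fragments A data.frame with a `sequence` column, or a
#'   [fastq_stream()] / [load_premerged()] stream.
#' @param lib An `oligo_library`.
#' @param rs A [read_structure()] describing the merged fragments.
#' @param min_support Minimum reads agreeing on the modal oligo.
#' @param purity_threshold Minimum modal fraction.
#' @param max_mismatches Hamming tolerance for insert matching.
#' @param merge_stats Optional list with `n_reads_processed` and
#'   `n_reads_merged` from the merging stage (filled in by
#'   [map_barcodes()]).
#' @return A `barcode_map`: list with `assignments` (data.frame:
#'   `barcode`, `oligo_id`, `support`, `total`, `purity`, sorted by
#'   barcode), read-fate counters, `dropped_conflicts`,
#'   `dropped_low_support`, and the thresholds used.
#' @export
build_barcode_map <- function(fragments, lib, rs,
                              min_support = 3L, purity_threshold = 0.75,
                              max_mismatches = 0L, merge_stats = NULL) {
    tallies <- list()
    fail <- c(no_flank = 0L, short = 0L, N_in_barcode = 0L)
    n_frag <- 0L
    n_matched <- 0L
    n_unmatched <- 0L

    consume <- function(seqs) {
        ext <- extract_fields_(seqs, rs)
        bad <- ext$status != "ok"
        if (any(bad)) {
            tb <- table(ext$status[bad])
            fail[names(tb)] <<- fail[names(tb)] + as.integer(tb)
        }
        okd <- ext[!bad, , drop = FALSE]
        if (nrow(okd) == 0L) return(invisible())
        oligo <- match_inserts(okd$insert, lib, max_mismatches)
        hit <- !is.na(oligo)
        n_unmatched <<- n_unmatched + sum(!hit)
        n_matched <<- n_matched + sum(hit)
        if (any(hit)) {
            dt <- data.table::data.table(barcode = okd$barcode[hit],
                                         oligo_id = oligo[hit])
            tallies[[length(tallies) + 1L]] <<-
                dt[, .(n = .N), by = .(barcode, oligo_id)]
        }
        invisible()
    }

    if (inherits(fragments, "fastq_stream")) {
        repeat {
            ch <- fragments$read_chunk()
            if (is.null(ch)) break
            n_frag <- n_frag + nrow(ch)
            consume(ch$sequence)
        }
    } else {
        fragments <- as.data.frame(fragments)
        n_frag <- nrow(fragments)
        if (n_frag > 0L) consume(fragments$sequence)
    }

    if (length(tallies) > 0L) {
        tab <- data.table::rbindlist(tallies)[
            , .(n = sum(n)), by = .(barcode, oligo_id)]
        per_bc <- tab[, {
            tot <- sum(n)
            mx <- max(n)
            tie <- sum(n == mx) > 1L
            .(oligo_id = oligo_id[which.max(n)], support = mx,
              total = tot, tie = tie)
        }, by = barcode]
        per_bc[, purity := support / total]
        conflict <- per_bc$tie | per_bc$purity < purity_threshold
        low <- !conflict & per_bc$support < min_support
        keep <- !conflict & !low
        assignments <- per_bc[keep, .(barcode, oligo_id, support, total, purity)]
        data.table::setorder(assignments, barcode)
        dropped_conflicts <- sum(conflict)
        dropped_low_support <- sum(low)
    } else {
        assignments <- data.table::data.table(
            barcode = character(), oligo_id = character(),
            support = integer(), total = integer(), purity = numeric())
        dropped_conflicts <- 0L
        dropped_low_support <- 0L
    }

    structure(list(
        assignments = as.data.frame(assignments),
        n_reads_processed = if (!is.null(merge_stats)) merge_stats$n_reads_processed else n_frag,
        n_reads_merged = if (!is.null(merge_stats)) merge_stats$n_reads_merged else n_frag,
        n_reads_matched = n_matched,
        n_reads_unmatched = n_unmatched,
        extraction_failures = fail,
        dropped_conflicts = as.integer(dropped_conflicts),
        dropped_low_support = as.integer(dropped_low_support),
        params = list(min_support = as.integer(min_support),
                      purity_threshold = purity_threshold,
                      max_mismatches = as.integer(max_mismatches))
    ), class = "barcode_map")
}

#' @export
print.barcode_map <- function(x, ...) {
    cat("<barcode_map> ", nrow(x$assignments), " barcodes assigned (",
        x$n_reads_matched, "/", x$n_reads_processed, " reads matched; ",
        x$dropped_conflicts, " conflict, ", x$dropped_low_support,
        " low-support barcodes dropped)\n", sep = "")
    invisible(x)
}

#' Run step 1 end to end from FASTQ
#'
#' Streams a paired-end association-mapping run (or a pre-merged
#' fragment file), merges pairs with the internal overlap merger, and
#' builds the barcode map.
#'
#' @param r1,r2 Paths to the forward/reverse FASTQ files (ignored when
#'   `premerged` is given).
#' @param lib An `oligo_library`.
#' @param rs A [read_structure()].
#' @param premerged Optional path to an externally merged fragment FASTQ.
#' @param min_overlap,max_mismatch_frac Merger settings.
#' @inheritParams build_barcode_map
#' @return A `barcode_map` (see [build_barcode_map()]).
#' @export
map_barcodes <- function(r1 = NULL, r2 = NULL, lib, rs,
                         premerged = NULL,
                         min_support = 3L, purity_threshold = 0.75,
                         max_mismatches = 0L,
                         min_overlap = 10L, max_mismatch_frac = 0.1) {
    if (!is.null(premerged)) {
        return(build_barcode_map(load_premerged(premerged), lib, rs,
                                 min_support, purity_threshold,
                                 max_mismatches))
    }
    if (is.null(r1) || is.null(r2))
        stop("either r1+r2 or premerged must be given")
    st1 <- fastq_stream(r1)
    st2 <- fastq_stream(r2)
    n_proc <- 0L
    n_merged <- 0L
    chunks <- list()
    repeat {
        c1 <- st1$read_chunk()
        c2 <- st2$read_chunk()
        if (is.null(c1) != is.null(c2))
            stop("r1 and r2 have different numbers of reads")
        if (is.null(c1)) break
        if (nrow(c1) != nrow(c2))
            stop("r1 and r2 have different numbers of reads")
        n_proc <- n_proc + nrow(c1)
        m <- merge_pairs(c1$sequence, c2$sequence, c1$quality, c2$quality,
                         min_overlap = min_overlap,
                         max_mismatch_frac = max_mismatch_frac)
        m <- m[m$ok, c("sequence", "quality"), drop = FALSE]
        n_merged <- n_merged + nrow(m)
        if (nrow(m) > 0L) chunks[[length(chunks) + 1L]] <- m
    }
    frags <- if (length(chunks) > 0L) do.call(rbind, chunks)
             else data.frame(sequence = character(), stringsAsFactors = FALSE)
    build_barcode_map(frags, lib, rs, min_support, purity_threshold,
                      max_mismatches,
                      merge_stats = list(n_reads_processed = n_proc,
                                         n_reads_merged = n_merged))
}

#' Unique barcodes associated with each designed oligo
#'
#' The central library-complexity metric of step 1: too few barcodes per
#' oligo makes activity estimates noisy, too many dilutes sequencing
#' depth downstream.
#'
#' @param map A `barcode_map`.
#' @param lib An `oligo_library`; every designed oligo appears in the
#'   output, with 0 when it captured no barcode.
#' @return Named integer vector, library order.
#' @export
barcodes_per_oligo <- function(map, lib) {
    tb <- table(factor(map$assignments$oligo_id, levels = names(lib)))
    stats::setNames(as.integer(tb), names(lib))
}
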