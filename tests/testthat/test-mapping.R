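# brute-force overlap merger used as oracle: tries every overlap length,
# picks minimal mismatch fraction (ties -> longest), no shortcuts
oracle_merge <- function(s1, s2, min_overlap, max_frac) {
    rc2 <- mpraqc::revcomp(s2)
    L1 <- nchar(s1); L2 <- nchar(rc2)
    best <- NULL
    for (o in seq.int(min_overlap, min(L1, L2))) {
        a <- strsplit(substr(s1, L1 - o + 1L, L1), "")[[1]]
        b <- strsplit(substr(rc2, 1L, o), "")[[1]]
        frac <- mean(a != b)
        if (is.null(best) || frac < best$frac - 1e-12 ||
            (abs(frac - best$frac) <= 1e-12 && o > best$o))
            best <- list(o = o, frac = frac)
    }
    if (is.null(best) || best$frac > max_frac) return(NULL)
    paste0(substr(s1, 1L, L1 - best$o), substr(rc2, 1L, L2))
}

test_that("merge_pair finds the forced overlap and full-length identity", {
    m <- merge_pair(list(sequence = "ACGTTG"), list(sequence = "TGCAAC"),
                    min_overlap = 4, max_mismatch_frac = 0)
    expect_true(m$ok)
    expect_equal(m$sequence, "ACGTTGCA")
    expect_equal(m$overlap_len, 4L)

    r1 <- "AACGTCCA"
    m2 <- merge_pair(list(sequence = r1), list(sequence = revcomp(r1)),
                     min_overlap = 4, max_mismatch_frac = 0)
    expect_equal(m2$sequence, r1)
    expect_equal(m2$overlap_len, nchar(r1))

    m3 <- merge_pair(list(sequence = "AAAA"), list(sequence = "AAAA"),
                     min_overlap = 4, max_mismatch_frac = 0)
    expect_false(m3$ok)
})

test_that("overlap disagreements resolve to the higher-quality base, ties to r1", {
    # rc2 differs from r1 at the first overlap base
    r1 <- list(sequence = "ACGTTG", quality = "IIIII!")
    r2 <- list(sequence = revcomp("ACGTTC"), quality = "IIIIII")
    m <- merge_pair(r1, r2, min_overlap = 6, max_mismatch_frac = 0.5)
    expect_equal(m$sequence, "ACGTTC")   # r2 base wins at last position
    r2_low <- list(sequence = revcomp("ACGTTC"), quality = "!IIIII")
    m2 <- merge_pair(r1, r2_low, min_overlap = 6, max_mismatch_frac = 0.5)
    expect_equal(substr(m2$sequence, 6, 6), "G")  # equal qual -> r1 base
})

test_that("vectorized merger agrees with a brute-force oracle on clean pairs", {
    set.seed(41)
    n <- 100L
    frags <- stringi::stri_rand_strings(n, 120, "[ACGT]")
    s1 <- substr(frags, 1, 75)
    s2 <- revcomp(substr(frags, 46, 120))
    res <- merge_pairs(s1, s2, min_overlap = 10, max_mismatch_frac = 0)
    expect_true(all(res$ok))
    oracle <- vapply(seq_len(n), function(i)
        oracle_merge(s1[i], s2[i], 10L, 0), character(1))
    expect_equal(res$sequence, oracle)
    expect_equal(res$sequence, frags)   # merge reconstructs the fragment
})

test_that("barcode and insert extraction inverts the construct layout", {
    rs <- read_structure(barcode_len = 6, barcode_end = "three_prime",
                         barcode_flank_up = "GGC")
    got <- extract_barcode_and_insert(list(sequence = "ACGTACGGCTTTAAA"), rs)
    expect_equal(got$status, "ok")
    expect_equal(got$insert, "ACGTAC")
    expect_equal(got$barcode, "TTTAAA")

    nbc <- extract_barcode_and_insert(list(sequence = "ACGTACGGCTTNAAA"), rs)
    expect_equal(nbc$status, "N_in_barcode")

    nofl <- extract_barcode_and_insert(list(sequence = "ACGTACTTTTTAAAA"), rs)
    expect_equal(nofl$status, "no_flank")
})

test_that("a flank landing inside the barcode does not shadow the true site", {
    rs <- read_structure(barcode_len = 12, barcode_end = "three_prime",
                         barcode_flank_up = "GGCTAA")
    bc <- "AAGGCTAAACCT"   # contains the flank at offset 3
    frag <- paste0("ACGTACGTACGT", "GGCTAA", bc)
    got <- extract_barcode_and_insert(list(sequence = frag), rs)
    expect_equal(got$status, "ok")
    expect_equal(got$barcode, bc)
    expect_equal(got$insert, "ACGTACGTACGT")
})

test_that("five-prime barcodes and positional (flankless) extraction work", {
    rs5 <- read_structure(barcode_len = 6, barcode_end = "five_prime",
                          barcode_flank_down = "GGC")
    got <- extract_barcode_and_insert(list(sequence = "TTTAAAGGCACGTAC"), rs5)
    expect_equal(got$barcode, "TTTAAA")
    expect_equal(got$insert, "ACGTAC")

    rs_pos <- read_structure(barcode_len = 6, barcode_end = "three_prime")
    got2 <- extract_barcode_and_insert(list(sequence = "ACGTACTTTAAA"), rs_pos)
    expect_equal(got2$barcode, "TTTAAA")
    expect_equal(got2$insert, "ACGTAC")

    rc <- read_structure(barcode_len = 6, barcode_end = "three_prime",
                         barcode_revcomp = TRUE)
    got3 <- extract_barcode_and_insert(list(sequence = "ACGTACTTTAAA"), rc)
    expect_equal(got3$barcode, revcomp("TTTAAA"))
})

test_that("insert matching is exact-first, Hamming-unique, ambiguity-safe", {
    lib <- as_lib(c(O1 = "ACGT"))
    expect_equal(match_insert("ACGT", lib, 0), "O1")
    expect_equal(match_insert("ACGA", lib, 1), "O1")
    expect_true(is.na(match_insert("ACGA", lib, 0)))
    lib2 <- as_lib(c(O1 = "AAAA", O2 = "AAAT"))
    expect_true(is.na(match_insert("AAAC", lib2, 1)))  # distance-1 tie
    expect_error(match_insert("AAAA", as_lib(character())))
})

test_that("barcode assignment applies support and purity rules", {
    lib <- as_lib(c(O1 = "AAACCC", O2 = "GGGTTT", O3 = "ACACAC"))
    rs <- read_structure(barcode_len = 6, barcode_flank_up = "GGC")
    mk <- function(oligo, bc, times)
        rep(paste0(unclass(lib)[oligo], "GGC", bc), times)
    frags <- data.frame(sequence = c(
        mk("O1", "AAATTT", 8), mk("O2", "AAATTT", 2),   # purity 0.8
        mk("O1", "CCCTTT", 5), mk("O2", "CCCTTT", 5),   # tie -> conflict
        mk("O1", "GGGAAA", 2)                            # low support
    ), stringsAsFactors = FALSE)
    map <- build_barcode_map(frags, lib, rs, min_support = 3,
                             purity_threshold = 0.75)
    expect_equal(map$assignments$barcode, "AAATTT")
    expect_equal(map$assignments$oligo_id, "O1")
    expect_equal(map$assignments$support, 8L)
    expect_equal(map$assignments$total, 10L)
    expect_equal(map$dropped_conflicts, 1L)
    expect_equal(map$dropped_low_support, 1L)

    # permuting the fragment stream leaves the map unchanged
    set.seed(9)
    perm <- frags[sample.int(nrow(frags)), , drop = FALSE]
    map2 <- build_barcode_map(perm, lib, rs, min_support = 3,
                              purity_threshold = 0.75)
    expect_identical(map2$assignments, map$assignments)

    # empty stream -> valid empty map
    empty <- build_barcode_map(frags[0, , drop = FALSE], lib, rs)
    expect_equal(nrow(empty$assignments), 0L)
    expect_equal(empty$n_reads_processed, 0L)
})

test_that("barcodes_per_oligo covers every designed oligo and conserves totals", {
    w <- tiny_world()
    bpo <- barcodes_per_oligo(w$map, w$lib)
    expect_equal(bpo, c(O1 = 3L, O2 = 1L))
    expect_equal(sum(bpo), nrow(w$map$assignments))
    lib3 <- as_lib(c(unclass(w$lib), O3 = "GGGGGAAAAA"))
    bpo3 <- barcodes_per_oligo(w$map, lib3)
    expect_equal(bpo3[["O3"]], 0L)
})

test_that("read-fate counters are conserved through merging and matching", {
    set.seed(5)
    lib_seqs <- stats::setNames(stringi::stri_rand_strings(20, 40, "[ACGT]"),
                                sprintf("O%02d", 1:20))
    lib <- as_lib(lib_seqs)
    rs <- read_structure(barcode_len = 8, barcode_flank_up = "GCTAGC")
    bcs <- stringi::stri_rand_strings(60, 8, "[ACGT]")
    frag <- paste0(lib_seqs[sample(20, 500, replace = TRUE)], "GCTAGC",
                   bcs[sample(60, 500, replace = TRUE)])
    r1 <- substr(frag, 1, 40)
    r2 <- revcomp(substr(frag, 15, 54))
    # corrupt some reverse reads so merging fails for them
    r2[1:25] <- strrep("A", 40)
    p1 <- write_tmp_fastq(paste0("f", 1:500), r1)
    p2 <- write_tmp_fastq(paste0("f", 1:500), r2)
    map <- map_barcodes(p1, p2, lib, rs, min_support = 1,
                        max_mismatch_frac = 0.05)
    expect_equal(map$n_reads_processed, 500L)
    expect_lte(map$n_reads_merged, 475L)
    expect_equal(map$n_reads_matched + map$n_reads_unmatched +
                     sum(map$extraction_failures), map$n_reads_merged)
})

test_that("true-pair recovery rate tracks the per-base error model", {
    # flankless structure: a read yields its true (barcode, oligo) pair
    # iff insert and barcode are both error-free, p = (1-e)^(Li+Lb)
    set.seed(31)
    e <- 0.01
    n <- 20000L
    lib_seqs <- stats::setNames(stringi::stri_rand_strings(50, 30, "[ACGT]"),
                                sprintf("O%02d", 1:50))
    lib <- as_lib(lib_seqs)
    rs <- read_structure(barcode_len = 10)
    bcs <- stringi::stri_rand_strings(200, 10, "[ACGT]")
    oligo_of_bc <- sample(names(lib_seqs), 200, replace = TRUE)
    pick <- sample.int(200, n, replace = TRUE)
    clean <- paste0(lib_seqs[oligo_of_bc[pick]], bcs[pick])
    noisy <- clean
    for (j in seq_len(nchar(clean[1]))) {
        hit <- which(runif(n) < e)
        if (length(hit)) substr(noisy[hit], j, j) <-
            sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    }
    ext <- vapply(seq_len(n), function(i) {
        g <- extract_barcode_and_insert(list(sequence = noisy[i]), rs)
        !is.na(g$barcode) && g$barcode == bcs[pick[i]] &&
            identical(match_insert(g$insert, lib), oligo_of_bc[pick[i]])
    }, logical(1))
    p_exp <- (1 - e * 3 / 4)^40   # substitution draw can restore the base
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(mean(ext) - p_exp), 3 * se)
})
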