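test_that("CPM normalization uses mapped reads only", {
    w <- tiny_world()
    ct <- barcode_counts(c("AAAAAA", "CCCCCC"), c(10L, 90L))
    nc <- normalize_counts(ct, w$map)
    expect_equal(nc$library_size, 100L)
    expect_equal(nc$values$cpm, c(1e5, 9e5))

    one <- normalize_counts(barcode_counts("AAAAAA", 7L), w$map)
    expect_equal(one$values$cpm, 1e6)

    # an unmapped barcode changes nothing downstream
    ct2 <- barcode_counts(c("AAAAAA", "CCCCCC", "AATTGG"), c(10L, 90L, 50L))
    nc2 <- normalize_counts(ct2, w$map)
    expect_equal(nc2$values[c("barcode", "cpm")],
                 nc$values[c("barcode", "cpm")])
})

test_that("activity is the ratio of summed normalized counts per oligo", {
    w <- tiny_world()
    dna <- normalize_counts(barcode_counts(c("AAAAAA", "CCCCCC"),
                                           c(25L, 75L)), w$map)
    rna <- normalize_counts(barcode_counts(c("AAAAAA", "CCCCCC"),
                                           c(25L, 75L)), w$map)
    # rna/dna CPM are equal barcode-wise -> activity exactly 1
    act1 <- compute_activity(dna, rna, w$map)
    expect_equal(act1$activity[act1$oligo_id == "O1"], 1)

    # the constructed two-barcode worked example: (4+12)/(2+6) = 2
    dna2 <- list(sample_id = "d",
                 values = data.frame(barcode = c("AAAAAA", "CCCCCC"),
                                     oligo_id = "O1", cpm = c(2, 6)),
                 library_size = 100L)
    rna2 <- list(sample_id = "r",
                 values = data.frame(barcode = c("AAAAAA", "CCCCCC"),
                                     oligo_id = "O1", cpm = c(4, 12)),
                 library_size = 100L)
    class(dna2) <- class(rna2) <- "normalized_counts"
    act2 <- compute_activity(dna2, rna2, w$map)
    expect_equal(act2$activity, 2)
    expect_equal(act2$n_barcodes_used, 2L)

    # barcode absent from RNA contributes zero to the numerator
    rna3 <- rna2
    rna3$values <- rna3$values[1, , drop = FALSE]
    act3 <- compute_activity(dna2, rna3, w$map)
    expect_equal(act3$activity, 4 / 8)
    # ... unless the zero-inclusion switch is off
    act3b <- compute_activity(dna2, rna3, w$map,
                              include_missing_rna = FALSE)
    expect_equal(act3b$activity, 4 / 2)

    # min_barcodes filter drops with a reason
    act4 <- compute_activity(dna2, rna2, w$map, min_barcodes = 3)
    expect_equal(nrow(act4), 0L)
    dropped <- attr(act4, "dropped")
    expect_equal(dropped$reason[dropped$oligo_id == "O1"],
                 "too_few_barcodes")
})

test_that("activity is scale-invariant and exact for constant ratios", {
    w <- tiny_world()
    set.seed(2)
    bcs <- c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT")
    d_raw <- sample(50:500, 4)
    r_raw <- sample(50:500, 4)
    act <- function(bc, d, r) compute_activity(
        normalize_counts(barcode_counts(bc, d), w$map),
        normalize_counts(barcode_counts(bc, r), w$map), w$map)
    a1 <- act(bcs, d_raw, r_raw)
    a2 <- act(bcs, d_raw, r_raw * 10L)
    expect_equal(a2$activity, a1$activity)

    # all barcode-level normalized RNA/DNA ratios equal to c ->
    # activity exactly c (built on the normalized scale: CPM of
    # globally scaled raw counts cancels by construction)
    dn <- normalize_counts(barcode_counts(bcs, d_raw), w$map)
    rn <- dn
    rn$values$cpm <- dn$values$cpm * 3
    a3 <- compute_activity(dn, rn, w$map)
    expect_equal(a3$activity, rep(3, nrow(a3)), tolerance = 1e-12)

    # permutation invariance in barcode order
    perm <- c(3, 1, 4, 2)
    a4 <- act(bcs[perm], d_raw[perm], r_raw[perm])
    expect_equal(a4, a1)
})

test_that("estimated activities recover simulated truth (Poisson counts)", {
    set.seed(77)
    n_ol <- 200L
    n_bc_per <- 5L
    lib <- as_lib(stats::setNames(
        stringi::stri_rand_strings(n_ol, 20, "[ACGT]"),
        sprintf("oligo_%03d", seq_len(n_ol))))
    bcs <- stringi::stri_rand_strings(n_ol * n_bc_per, 10, "[ACGT]")
    oligo_of <- rep(names(lib), each = n_bc_per)
    rs <- read_structure(barcode_len = 10, barcode_flank_up = "GGC")
    map <- make_map(bcs, oligo_of, lib, rs)
    true_act <- stats::setNames(rlnorm(n_ol, 0, log(2)), names(lib))
    mu_d <- rlnorm(length(bcs), log(200), 0.3)
    mu_r <- mu_d * true_act[oligo_of]
    d <- rpois(length(bcs), mu_d)
    r <- rpois(length(bcs), mu_r)
    keep_d <- d > 0
    dna <- normalize_counts(barcode_counts(bcs[keep_d], d[keep_d]), map)
    keep_r <- r > 0
    rna <- normalize_counts(barcode_counts(bcs[keep_r], r[keep_r]), map)
    est <- compute_activity(dna, rna, map)
    shared <- intersect(est$oligo_id, names(true_act))
    rho <- cor(log2(est$activity[match(shared, est$oligo_id)]),
               log2(true_act[shared]))
    expect_gte(rho, 0.9)
})

test_that("DNA-RNA correlation flags proportional and degenerate inputs", {
    w <- tiny_world()
    bcs <- c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT")
    dna <- normalize_counts(barcode_counts(bcs, c(10L, 20L, 40L, 80L)),
                            w$map)
    rna_prop <- normalize_counts(barcode_counts(bcs, c(30L, 60L, 120L, 240L)),
                                 w$map)
    # proportional raw counts give identical CPM -> r = 1 on log scale
    cc <- dna_rna_correlation(dna, rna_prop)
    expect_equal(cc$pearson_r, 1)
    expect_equal(cc$n_shared_barcodes, 4L)

    rna_const <- normalize_counts(barcode_counts(bcs, rep(5L, 4)), w$map)
    cc2 <- dna_rna_correlation(dna, rna_const)
    expect_true(cc2$zero_variance)
    expect_equal(cc2$pearson_r, 0)

    expect_error(dna_rna_correlation(
        dna, normalize_counts(barcode_counts(bcs[1], 5L), w$map)),
        "shared barcodes")
})

test_that("replicate comparison is symmetric with unit diagonal", {
    tab <- function(act) data.frame(
        oligo_id = paste0("O", seq_along(act)),
        n_barcodes_used = 5L, dna_sum = 1, rna_sum = act,
        activity = act, log2_activity = log2(act))
    a <- tab(c(2, 4, 8))
    b <- tab(c(4, 8, 16))
    cmp_self <- compare_replicates(list(a, a))
    expect_equal(cmp_self$pearson[1, 2], 1)
    cmp <- compare_replicates(list(a, b), ids = c("r1", "r2"))
    expect_equal(cmp$pearson["r1", "r2"], 1)   # affine on log scale
    expect_equal(cmp$spearman["r1", "r2"], 1)
    expect_equal(cmp$pearson, t(cmp$pearson))
    expect_equal(diag(cmp$pearson), c(r1 = 1, r2 = 1))

    # independent oracle: plain cor() on the shared log2 activities
    set.seed(13)
    x <- tab(rlnorm(50, 0, 1))
    y <- tab(rlnorm(50, 0, 1))
    cmp2 <- compare_replicates(list(x, y))
    expect_equal(cmp2$pearson[1, 2],
                 cor(log2(x$activity), log2(y$activity)))

    # pairs sharing too few oligos are reported as missing
    cmp3 <- compare_replicates(list(a, tab(1)[0, ]))
    expect_true(is.na(cmp3$pearson[1, 2]))
    expect_error(compare_replicates(list(a)), "at least 2")
})
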