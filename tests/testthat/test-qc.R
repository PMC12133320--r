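test_that("range evaluation uses closed boundaries and risk direction", {
    rg <- reference_range("m", low = 0.3, direction_of_risk = "below",
                          recommendation = "sequence deeper")
    expect_equal(qc_evaluate(0.5, rg)$status, "pass")
    risk <- qc_evaluate(0.2, rg)
    expect_equal(risk$status, "risk")
    expect_equal(risk$recommendation, "sequence deeper")
    expect_equal(qc_evaluate(0.3, rg)$status, "pass")  # boundary passes

    hi <- reference_range("m", high = 0.8, direction_of_risk = "above")
    expect_equal(qc_evaluate(0.9, hi)$status, "risk")
    expect_equal(qc_evaluate(0.8, hi)$status, "pass")
    # below-direction violations are ignored for an 'above' range
    expect_equal(qc_evaluate(-5, hi)$status, "pass")
    expect_error(reference_range("m", low = 2, high = 1), "low")
})

test_that("evaluation is monotone in the risk direction", {
    rg <- reference_range("m", low = 0.4, direction_of_risk = "below")
    vals <- seq(0, 1, by = 0.05)
    st <- vapply(vals, function(v) qc_evaluate(v, rg)$status, "")
    # once passing, raising the value never re-introduces risk
    expect_true(all(diff(st == "pass") >= 0))
})

test_that("each step reports its declared metric family", {
    w <- tiny_world()
    m_map <- collect_step_metrics("map", list(map = w$map, lib = w$lib),
                                  min_barcodes_qualified = 2)
    expect_setequal(vapply(m_map, `[[`, "", "name"),
                    c("frac_oligos_qualified", "median_barcodes_per_oligo",
                      "frac_reads_merged", "frac_reads_matched"))
    # O1 has 3 barcodes, O2 has 1; threshold 2 qualifies only O1
    vals <- stats::setNames(vapply(m_map, `[[`, 0, "value"),
                            vapply(m_map, `[[`, "", "name"))
    expect_equal(vals[["frac_oligos_qualified"]], 0.5)

    ct <- barcode_counts(c("AAAAAA", "CCCCCC"), c(4L, 2L))
    cov <- coverage_stats(ct, w$map, w$lib)
    m_cnt <- collect_step_metrics("dna_counts", list(coverage = cov))
    expect_setequal(vapply(m_cnt, `[[`, "", "name"),
                    c("frac_mapped_barcodes_detected", "frac_oligos_detected",
                      "mean_detection_count", "frac_reads_unmapped"))

    dna <- normalize_counts(barcode_counts(c("AAAAAA", "CCCCCC", "GGGGGG"),
                                           c(10L, 20L, 40L)), w$map)
    rna <- normalize_counts(barcode_counts(c("AAAAAA", "CCCCCC", "GGGGGG"),
                                           c(20L, 40L, 80L)), w$map)
    corr <- dna_rna_correlation(dna, rna)
    act <- compute_activity(dna, rna, w$map)
    m_act <- collect_step_metrics("activity",
                                  list(correlation = corr, activity = act,
                                       map = w$map))
    nm <- vapply(m_act, `[[`, "", "name")
    expect_setequal(nm, c("dna_rna_pearson_r", "frac_oligos_quantified"))
    # proportional DNA/RNA -> r = 1, flagged as risk (excessive correlation)
    expect_equal(m_act[[which(nm == "dna_rna_pearson_r")]]$status, "risk")

    expect_error(collect_step_metrics("step9", list()), "unknown")
})

test_that("reports carry one recommendation block per risk and a TSV twin", {
    outdir <- file.path(tempdir(), "qc_report_test")
    unlink(outdir, recursive = TRUE)
    pass_m <- qc_evaluate(0.9, reference_range(
        "metric_a", low = 0.5, direction_of_risk = "below",
        recommendation = "do A"), step = "map")
    risk_m <- qc_evaluate(0.1, reference_range(
        "metric_b", low = 0.5, direction_of_risk = "below",
        recommendation = "do B now"), step = "map")

    r0 <- render_qc_report("map", list(pass_m), outdir = outdir)
    html0 <- paste(readLines(r0$html), collapse = "\n")
    expect_false(grepl("class=\"recommendation\"", html0))

    r1 <- render_qc_report("map", list(pass_m, risk_m), outdir = outdir)
    html1 <- readLines(r1$html)
    expect_equal(sum(grepl("class=\"recommendation\"", html1)), 1L)
    expect_true(any(grepl("do B now", html1)))

    tsv <- read_table_tsv(r1$tsv)
    expect_equal(nrow(tsv), 2L)
    expect_equal(tsv$metric, c("metric_a", "metric_b"))
    expect_equal(tsv$status, c("pass", "risk"))

    # byte-identical on identical inputs
    bytes1 <- readBin(r1$tsv, "raw", file.size(r1$tsv))
    render_qc_report("map", list(pass_m, risk_m), outdir = outdir)
    bytes2 <- readBin(r1$tsv, "raw", file.size(r1$tsv))
    expect_identical(bytes1, bytes2)
})

test_that("shipped reference ranges load and cover the report metrics", {
    rg <- qc_reference_ranges()
    expect_true(all(c("frac_oligos_qualified", "median_barcodes_per_oligo",
                      "frac_mapped_barcodes_detected", "mean_detection_count",
                      "dna_rna_pearson_r") %in% names(rg)))
    expect_s3_class(rg[["dna_rna_pearson_r"]], "reference_range")
    expect_equal(rg[["dna_rna_pearson_r"]]$direction_of_risk, "above")
    expect_true(all(vapply(rg, function(r) r$low <= r$high, TRUE)))
})
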