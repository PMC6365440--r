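pairedCounts <- function(treated, control, tissue = "islets",
                         n_islets = 30L, population = "CD4") {
    n <- length(treated)
    data.frame(mouse_id = rep(seq_len(n), 2L), tissue = tissue,
               population = population,
               condition = rep(c("treated", "control"), each = n),
               count = c(treated, control),
               n_islets = if (tissue == "islets") n_islets else NA_integer_)
}

test_that("per-islet normalization divides islet rows only", {
    cc <- rbind(pairedCounts(120L, 240L, "islets", n_islets = 30L),
                pairedCounts(500L, 800L, "ILN"))
    nn <- normalizePerIslet(cc)
    expect_equal(nn$norm_count[nn$tissue == "islets"], c(4, 8))
    expect_equal(nn$norm_count[nn$tissue == "ILN"], c(500, 800))
    bad <- pairedCounts(10L, 10L, "islets", n_islets = 0L)
    expect_error(normalizePerIslet(bad), "n_islets")
})

test_that("ratio test handles null, degenerate and zero-control cases", {
    ccNull <- pairedCounts(c(10L, 20L, 30L), c(10L, 20L, 30L))
    rt <- ratioTest(ccNull, "CD4", "islets")
    expect_equal(rt$t, 0)
    expect_equal(rt$p_value, 1)

    ccDeg <- pairedCounts(c(5L, 10L, 15L, 20L), c(10L, 20L, 30L, 40L))
    rt <- ratioTest(ccDeg, "CD4", "islets")     # all ratios exactly 0.5
    expect_true(rt$degenerate)
    expect_equal(rt$mean_ratio, 0.5)
    expect_true(is.na(rt$t))

    ccZero <- pairedCounts(c(5L, 10L, 15L), c(10L, 0L, 30L))
    expect_warning(rt <- ratioTest(ccZero, "CD4", "islets"), "zero control")
    expect_equal(length(rt$ratios), 2L)
    expect_error(suppressWarnings(
        ratioTest(pairedCounts(c(1L, 2L), c(0L, 0L)), "CD4", "islets")),
        "2 complete pairs")
})

test_that("ratio test matches the one-sample t formula", {
    set.seed(5)
    tr <- rpois(9, 40); ct <- rpois(9, 80)
    rt <- ratioTest(pairedCounts(tr, ct), "CD4", "islets")
    r <- tr / ct
    tHand <- (mean(r) - 1) / (sd(r) / sqrt(length(r)))
    pHand <- 2 * pt(-abs(tHand), length(r) - 1)
    expect_equal(rt$t, tHand, tolerance = 1e-12)
    expect_equal(rt$p_value, pHand, tolerance = 1e-12)
})

test_that("percent impairment is plain arithmetic on group means", {
    cc <- pairedCounts(c(30L, 30L), c(300L, 300L))
    expect_equal(percentImpairment(cc, "CD4", "islets")$impairment_pct, 90)
    eq <- pairedCounts(c(50L, 70L), c(50L, 70L))
    expect_equal(percentImpairment(eq, "CD4", "islets")$impairment_pct, 0)
    zero <- pairedCounts(c(5L, 5L), c(0L, 0L))
    expect_error(percentImpairment(zero, "CD4", "islets"), "control mean")
})

test_that("ratio and impairment are invariant to uniform count rescaling", {
    set.seed(11)
    tr <- rpois(8, 30); ct <- rpois(8, 200)
    a <- pairedCounts(tr, ct)
    b <- pairedCounts(tr * 10L, ct * 10L)
    expect_equal(ratioTest(a, "CD4", "islets")$ratios,
                 ratioTest(b, "CD4", "islets")$ratios)
    expect_equal(percentImpairment(a, "CD4", "islets")$impairment_pct,
                 percentImpairment(b, "CD4", "islets")$impairment_pct)
})

test_that("group tests match textbook formulas and degenerate conventions", {
    x <- c(3.1, 4.2, 5.3, 6.1)
    expect_equal(groupTest(x, x, paired = TRUE)$p_value, 1)
    expect_equal(groupTest(c(1, 2, 3), c(1, 2, 3))$t, 0)

    set.seed(9)
    a <- rnorm(8); b <- rnorm(10, 0.5)
    gt <- groupTest(a, b)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
           (length(a) + length(b) - 2)
    tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(gt$t, tHand, tolerance = 1e-10)
    expect_equal(gt$df, length(a) + length(b) - 2)
    expect_equal(gt$p_value, 2 * pt(-abs(tHand), gt$df), tolerance = 1e-10)

    ap <- rnorm(6); bp <- ap + rnorm(6, 0.3)
    gp <- groupTest(ap, bp, paired = TRUE)
    dd <- ap - bp
    tPair <- mean(dd) / (sd(dd) / sqrt(6))
    expect_equal(gp$t, tPair, tolerance = 1e-10)
    expect_error(groupTest(1, 2), "n >= 2")
    expect_error(groupTest(c(1, 2, 3), c(1, 2), paired = TRUE),
                 "equal-length")
})

test_that("depletion filter includes at >= 90% depletion, boundary inclusive", {
    expect_true(depletionFilter(5, 100))
    expect_false(depletionFilter(15, 100))
    expect_true(depletionFilter(10, 100))
    expect_equal(depletionFilter(c(5, 10, 11), 100), c(TRUE, TRUE, FALSE))
    expect_error(depletionFilter(5, 0), "positive")
})

test_that("simulated depletion preserves effect direction after normalization", {
    td <- generateTraffickingCounts(countsPreset("cd11c_depletion",
                                                 seed = 13L))
    nn <- normalizePerIslet(td)
    for (pop in rownames(countsPreset("cd11c_depletion")$effect_multiplier)) {
        sub <- nn[nn$tissue == "islets" & nn$population == pop, ]
        expect_gt(mean(sub$norm_count[sub$condition == "intact"]),
                  mean(sub$norm_count[sub$condition == "depleted"]))
    }
})

test_that("impairment recovery tracks the simulated multiplier", {
    for (m in c(0.1, 0.5)) {
        imps <- vapply(1:6, function(s) {
            pre <- countsPreset("null_effect", n_mice = 40L, seed = 300L + s,
                effect_multiplier = rbind(CD4 = c(ILN = 1, PLN = 1,
                                                  blood = 1, islets = m)))
            percentImpairment(generateTraffickingCounts(pre), "CD4",
                              "islets")$impairment_pct
        }, numeric(1))
        se <- sd(imps) / sqrt(length(imps))
        expect_lt(abs(mean(imps) - (1 - m) * 100), 3 * se + 0.5)
    }
})
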