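# Replicate reconciliation, GxE classification, binning, summaries

test_that("replicate QTLs within 100 kb and same sign are averaged", {
  q1 <- mk_qtls("chrA", 100000, 0.3, lod = 8, replicate = "rep1")
  q2 <- mk_qtls("chrA", 180000, 0.5, lod = 12, replicate = "rep2")
  rec <- reconcile_replicates(q1, q2)
  expect_equal(nrow(rec), 1)
  expect_true(rec$replicated)
  expect_equal(rec$peak, 140000)
  expect_equal(rec$lod, 10)
  expect_equal(rec$delta_af, 0.4)
})

test_that("distant or opposite-sign peaks stay single-replicate", {
  q1 <- mk_qtls("chrA", 100000, 0.3)
  q2 <- mk_qtls("chrA", 250000, 0.3)
  rec <- reconcile_replicates(q1, q2)
  expect_equal(nrow(rec), 2)
  expect_false(any(rec$replicated))
  # same position, opposite sign: not a match
  q3 <- mk_qtls("chrA", 110000, -0.3)
  rec2 <- reconcile_replicates(q1, q3)
  expect_false(any(rec2$replicated))
})

test_that("greedy matching is symmetric and single-use", {
  set.seed(501)
  for (i in 1:20) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    q1 <- mk_qtls("chrA", sort(sample(seq(50000, 900000, 10000), n1)),
                  sample(c(-0.3, 0.3), n1, replace = TRUE))
    q2 <- mk_qtls("chrA", sort(sample(seq(50000, 900000, 10000), n2)),
                  sample(c(-0.3, 0.3), n2, replace = TRUE))
    r12 <- reconcile_replicates(q1, q2)
    r21 <- reconcile_replicates(q2, q1)
    expect_equal(sum(r12$replicated), sum(r21$replicated))
    expect_equal(sort(r12$peak[r12$replicated]), sort(r21$peak[r21$replicated]))
    # each input QTL is consumed at most once
    expect_equal(nrow(r12), n1 + n2 - sum(r12$replicated))
  }
})

test_that("presence/absence, sign-change and no-GxE follow the rules", {
  # replicated QTL in env A at chrVII:420 kb, nothing in env B
  a <- mk_env_set(mk_qtls("chrVII", 420000, 0.3),
                  mk_qtls("chrVII", 440000, 0.3, replicate = "rep2"))
  b_empty <- mk_env_set(mk_qtls(character(0), numeric(0), numeric(0)),
                        mk_qtls(character(0), numeric(0), numeric(0)))
  cmp <- classify_gxe(a, b_empty, "SC", "AZC", reporter = "Asn")
  expect_equal(cmp$category, "presence_absence")
  expect_equal(cmp$present_in, "SC")
  # opposite-sign peak in one replicate of env B within 100 kb: sign change
  b_opp <- mk_env_set(mk_qtls("chrVII", 450000, -0.3, environment = "AZC"),
                      mk_qtls(character(0), numeric(0), numeric(0)))
  cmp2 <- classify_gxe(a, b_opp, "SC", "AZC")
  expect_equal(cmp2$category, "sign_change")
  expect_equal(cmp2$sign_a, 1)
  expect_equal(cmp2$sign_b, -1)
  # replicated same-sign QTLs in both environments: full no-GxE, counted once
  b_same <- mk_env_set(mk_qtls("chrVII", 430000, 0.4, environment = "AZC"),
                       mk_qtls("chrVII", 410000, 0.4, environment = "AZC",
                               replicate = "rep2"))
  cmp3 <- classify_gxe(a, b_same, "SC", "AZC")
  expect_equal(cmp3$category, "no_gxe_full")
  expect_equal(nrow(cmp3), 1)
  # same-sign match in exactly one replicate of the other environment
  b_part <- mk_env_set(mk_qtls("chrVII", 430000, 0.4, environment = "AZC"),
                       mk_qtls(character(0), numeric(0), numeric(0)))
  cmp4 <- classify_gxe(a, b_part, "SC", "AZC")
  expect_equal(cmp4$category, "no_gxe_partial")
})

test_that("classification categories are exclusive and exhaustive", {
  set.seed(502)
  for (i in 1:10) {
    mk_side <- function() {
      n <- sample(2:4, 1)
      peaks <- sort(sample(seq(100000, 900000, 50000), n))
      mk_env_set(mk_qtls("chrA", peaks, sample(c(-0.3, 0.3), n, TRUE)),
                 mk_qtls("chrA", pmin(peaks + sample(c(0, 30000, 200000), n, TRUE),
                                      990000),
                         sample(c(-0.3, 0.3), n, TRUE), replicate = "rep2"))
    }
    a <- mk_side(); b <- mk_side()
    cmp <- classify_gxe(a, b, "SC", "AZC")
    n_repl <- sum(a$reconciled$replicated) + sum(b$reconciled$replicated)
    if (n_repl == 0) {
      expect_equal(nrow(cmp), 0)
    } else {
      expect_gte(nrow(cmp), 1)
      expect_true(all(cmp$category %in%
        c("presence_absence", "sign_change", "no_gxe_full", "no_gxe_partial")))
      # every comparison references at least one replicated QTL
      expect_true(all(!is.na(cmp$present_in)))
    }
  }
})

test_that("the sacCer3 genome partitions into 128 bins of 100 kb", {
  g <- saccer3_genome()
  bins <- bin_qtls(mk_qtls(character(0), numeric(0), numeric(0)), g)
  expect_equal(nrow(bins), 128)
  expect_equal(nrow(bins), sum(ceiling(g$length / 100000)))
  # invariant to QTL content
  bins2 <- bin_qtls(mk_qtls("chrI", 50000, 0.3), g)
  expect_equal(nrow(bins2), 128)
})

test_that("peaks are assigned to half-open 100-kb bins", {
  g <- saccer3_genome()
  q <- mk_qtls("chrI", c(50000, 100000), c(0.3, 0.3))
  bins <- bin_qtls(q, g)
  expect_equal(bins$n_qtls[bins$chrom == "chrI" & bins$bin_index == 0], 1)
  expect_equal(bins$n_qtls[bins$chrom == "chrI" & bins$bin_index == 1], 1)
  expect_error(bin_qtls(mk_qtls("chrI", 999999, 0.3), g), "outside")
})

test_that("GxE comparisons are binned by their available peaks", {
  g <- saccer3_genome()
  cmp <- data.frame(
    reporter = "R1", env_a = "SC", env_b = "AZC",
    category = c("presence_absence", "sign_change", "no_gxe_full"),
    chrom = "chrII",
    peak_a = c(150000, 190000, 350000), peak_b = c(NA, 230000, 360000),
    sign_a = c(1, 1, 1), sign_b = c(NA, -1, 1),
    present_in = "SC", ambiguous = FALSE, stringsAsFactors = FALSE)
  class(cmp) <- c("gxe_comparison", "data.frame")
  bins <- bin_qtls(mk_qtls(character(0), numeric(0), numeric(0)), g,
                   comparisons = cmp)
  chr2 <- bins[bins$chrom == "chrII", ]
  expect_equal(chr2$n_gxe_comparisons[chr2$bin_index == 1], 1)  # 150 kb
  expect_equal(chr2$n_gxe_comparisons[chr2$bin_index == 2], 1)  # mean 210 kb
  expect_equal(sum(chr2$n_gxe_comparisons), 2)  # no-GxE rows not counted
})

test_that("direction bias uses the exact binomial distribution", {
  expect_equal(direction_bias_test(mk_qtls("chrA", 1:10 * 10000,
                                           rep(0.3, 10)))$p_value,
               2 * 0.5^10, tolerance = 1e-12)
  expect_equal(direction_bias_test(mk_qtls("chrA", 1:10 * 10000,
                                           rep(c(0.3, -0.3), 5)))$p_value, 1)
  expect_equal(direction_bias_test(mk_qtls("chrA", 1:4 * 10000,
                                           rep(-0.3, 4)))$p_value,
               0.125, tolerance = 1e-12)
  expect_error(direction_bias_test(mk_qtls(character(0), numeric(0),
                                           numeric(0))), "no QTLs")
})

test_that("bin correlation matches rank expectations", {
  bins <- data.frame(chrom = "chrA", bin_index = 0:9, start = 0, end = 1,
                     n_qtls = 1:10, n_gxe_comparisons = (1:10) * 2)
  expect_equal(bin_gxe_correlation(bins)$rho, 1)
  bins$n_gxe_comparisons <- rev(bins$n_gxe_comparisons)
  expect_equal(bin_gxe_correlation(bins)$rho, -1)
  # empty bins are ignored
  bins$n_qtls[1:5] <- 0
  expect_equal(bin_gxe_correlation(bins)$n_bins, 5)
  bins$n_qtls <- c(1, 1, rep(0, 8))
  expect_error(bin_gxe_correlation(bins), "at least 3")
})

test_that("reference-study comparison flags presence and tests group differences", {
  cur <- mk_qtls("chrA", c(100000, 300000, 500000, 700000, 850000, 950000),
                 rep(0.3, 6))
  cur$lod <- c(10, 12, 14, 5, 6, 7)
  ref <- mk_qtls("chrA", c(110000, 310000, 400000), rep(0.3, 3))
  res <- compare_to_reference_set(cur, ref)
  expect_equal(res$presence, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(res$tests_skipped)
  # Welch oracle computed directly
  oracle <- t.test(c(10, 12, 14), c(5, 6, 7))$p.value
  expect_equal(res$p_lod, oracle, tolerance = 1e-12)
  # identical sets: all present, tests skipped
  res2 <- compare_to_reference_set(cur, cur)
  expect_true(all(res2$presence))
  expect_true(res2$tests_skipped)
  # exactly 100 kb away still counts as present
  res3 <- compare_to_reference_set(mk_qtls("chrA", 200000, 0.3),
                                   mk_qtls("chrA", 300000, 0.3))
  expect_error(res3, NA)
  expect_true(res3$presence)
})
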