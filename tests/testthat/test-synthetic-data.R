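# Segregant, pool and phenotype simulation

test_that("empty segregant set keeps the marker columns", {
  g <- two_chrom_genome()
  mm <- chrom_markers(n = 10)
  G <- simulate_segregant_genotypes(g, mm, 0)
  expect_equal(dim(G), c(0L, 10L))
  expect_equal(colnames(G), paste(mm$chrom, mm$pos, sep = ":"))
})

test_that("markers off the chromosome are rejected", {
  g <- two_chrom_genome()
  mm <- data.frame(chrom = "chrA", pos = 600000)
  expect_error(simulate_segregant_genotypes(g, mm, 5), "bounds")
})

test_that("crossover count matches the map length in Morgans", {
  # 220,000 bp at 2,200 bp/cM is exactly 1 Morgan
  g <- genome_model("chrA", 220000)
  mm <- chrom_markers("chrA", 220000, n = 20)
  set.seed(101)
  G <- simulate_segregant_genotypes(g, mm, 10000)
  xo <- attr(G, "crossovers")
  se <- sqrt(1 / 10000)  # Poisson(1) mean over 10,000 segregants
  expect_lt(abs(mean(xo) - 1), 3 * se)
})

test_that("unselected pools have allele frequency one half", {
  g <- two_chrom_genome()
  mm <- chrom_markers(n = 5)
  set.seed(102)
  G <- simulate_segregant_genotypes(g, mm, 20000)
  # binomial 99% CI half-width at n = 20,000
  ci <- qnorm(0.995) * sqrt(0.25 / 20000)
  expect_true(all(abs(colMeans(G) - 0.5) < ci))
})

test_that("genotype correlation decays with map distance and vanishes across chromosomes", {
  g <- two_chrom_genome()
  mm <- rbind(data.frame(chrom = "chrA", pos = c(1000, 10000, 200000)),
              data.frame(chrom = "chrB", pos = 50000))
  class(mm) <- c("marker_map", "data.frame")
  set.seed(103)
  G <- simulate_segregant_genotypes(g, mm, 10000)
  r_near <- cor(G[, 1], G[, 2])
  r_far <- cor(G[, 1], G[, 3])
  r_trans <- cor(G[, 1], G[, 4])
  # Haldane: corr = exp(-2d / (bp_per_cM * 100))
  expect_gt(r_near, r_far)
  expect_lt(abs(r_near - exp(-2 * 9000 / 220000)), 0.03)
  expect_lt(abs(r_trans), 3 / sqrt(10000))
})

test_that("simulation is reproducible under a fixed seed", {
  g <- two_chrom_genome()
  mm <- chrom_markers(n = 20)
  cfg <- pool_sim_config(seed = 7)
  G1 <- simulate_segregant_genotypes(g, mm, 50, cfg)
  G2 <- simulate_segregant_genotypes(g, mm, 50, cfg)
  expect_identical(G1, G2)
})

test_that("phenotypes reflect the planted architecture", {
  g <- two_chrom_genome()
  mm <- chrom_markers(n = 50)
  set.seed(104)
  G <- simulate_segregant_genotypes(g, mm, 20000)
  # no QTL: pure noise
  arch0 <- qtl_architecture(environments = "SC")
  ph0 <- assign_phenotypes(G, arch0, "SC")
  expect_lt(abs(mean(ph0)), 3 / sqrt(20000) * 1.5)
  # one locus of effect 0.5: carrier contrast
  locus <- mm$pos[25]
  arch <- qtl_architecture("chrA", locus, c("SC", "AZC"), c(0.5, -0.5))
  ph <- assign_phenotypes(G, arch, "SC")
  carrier <- G[, paste0("chrA:", locus)] == 1
  contrast <- mean(ph[carrier]) - mean(ph[!carrier])
  se <- sqrt(1 / sum(carrier) + 1 / sum(!carrier))
  expect_lt(abs(contrast - 0.5), 3 * se)
  # opposite-sign effect flips the contrast
  ph_azc <- assign_phenotypes(G, arch, "AZC")
  contrast_azc <- mean(ph_azc[carrier]) - mean(ph_azc[!carrier])
  expect_lt(contrast_azc, 0)
  expect_error(assign_phenotypes(G, arch, "YNB"), "unknown environment")
  arch_bad <- qtl_architecture("chrA", 123, "SC", 1)
  expect_error(assign_phenotypes(G, arch_bad, "SC"), "not on the marker map")
})

test_that("tail selection returns the extreme ranks", {
  set.seed(105)
  ph <- rnorm(1000)
  tails <- select_tails(ph, 0.02)
  expect_length(tails$high, 20)
  expect_length(tails$low, 20)
  expect_length(intersect(tails$high, tails$low), 0)
  expect_true(all(ph[tails$high] >= max(ph[-c(tails$high)])))
  expect_true(all(ph[tails$low] <= min(ph[-c(tails$low)])))
  # band mode: ranks 31..50 and 951..970 of the sorted phenotypes
  band <- select_tails(ph, band = c(0.03, 0.05))
  rk <- rank(ph, ties.method = "first")
  expect_setequal(rk[band$low], 31:50)
  expect_setequal(rk[band$high], 951:970)
  expect_error(select_tails(rnorm(10), 0.01), "zero cells")
})

test_that("ties at the tail cut resolve by original index", {
  ph <- rep(c(1, 2, 3), each = 4)
  tails <- select_tails(ph, 0.25)  # 3 per side from 12
  expect_equal(sort(tails$low), 1:3)
  expect_equal(sort(tails$high), 10:12)
})

test_that("pooled sequencing follows the binomial read model", {
  mm <- chrom_markers(n = 1000)
  # monomorphic RM pool without error: every read is RM
  G <- matrix(1L, nrow = 20, ncol = 1000)
  cfg <- pool_sim_config(mean_depth = 50, seq_error = 0)
  set.seed(106)
  tab <- sequence_pool(G, mm, cfg)
  expect_true(all(tab$count_BY == 0))
  # f = 0.5: mean RM fraction 0.5 across markers
  G2 <- rbind(matrix(1L, 10, 1000), matrix(0L, 10, 1000))
  tab2 <- sequence_pool(G2, mm, cfg)
  fr <- tab2$count_RM / (tab2$count_BY + tab2$count_RM)
  expect_lt(abs(mean(fr) - 0.5), 3 * sd(fr) / sqrt(1000))
  # sequencing error pulls a fixed pool toward the other allele
  cfg_err <- pool_sim_config(mean_depth = 100, seq_error = 0.01)
  tab3 <- sequence_pool(matrix(1L, 20, 1000), mm, cfg_err)
  fr3 <- tab3$count_RM / (tab3$count_BY + tab3$count_RM)
  expect_lt(abs(mean(fr3) - 0.99), 3 * sd(fr3) / sqrt(1000))
  expect_error(sequence_pool(G[0, , drop = FALSE], mm, cfg), "empty")
})

test_that("tail pools are enriched for the planted allele", {
  g <- two_chrom_genome()
  mm <- chrom_markers(n = 50)
  locus <- mm$pos[25]
  arch <- qtl_architecture("chrA", locus, "SC", 0.5)
  set.seed(107)
  G <- simulate_segregant_genotypes(g, mm, 10000)
  ph <- assign_phenotypes(G, arch, "SC")
  tails <- select_tails(ph, 0.02)
  col <- paste0("chrA:", locus)
  f_high <- mean(G[tails$high, col])
  f_low <- mean(G[tails$low, col])
  # one-sided binomial comparison at the planted locus
  p <- prop.test(c(sum(G[tails$high, col]), sum(G[tails$low, col])),
                 c(200, 200), alternative = "greater")$p.value
  expect_lt(p, 0.01)
  expect_gt(f_high, f_low)
})

test_that("conditional pool simulation preserves marginals and linkage", {
  g <- two_chrom_genome()
  mm <- chrom_markers(n = 40)
  # zero-effect architecture: sorted pools are random subsets
  arch <- qtl_architecture("chrA", mm$pos[20], "SC", 0,
                           environments = "SC")
  cfg <- pool_sim_config(n_segregants = 20000, tail_fraction = 0.1,
                         mean_depth = 5000, seq_error = 0, seed = 108)
  sim <- simulate_mapping_experiment(g, mm, arch, "SC", cfg)
  f <- sim$high$count_RM / (sim$high$count_RM + sim$high$count_BY)
  # marginal frequency 0.5 at every marker (pool of 2,000 cells, deep reads)
  expect_true(all(abs(f - 0.5) < 5 * sqrt(0.25 / 2000 + 0.25 / 5000)))
  # neighbouring markers are correlated through linkage
  expect_gt(cor(f[-1], f[-length(f)]), 0.3)
})

test_that("flow events invert to the configured activity when noiseless", {
  means <- data.frame(strain = "BY", environment = "SC", mean = 2.5)
  cfg <- flow_sim_config(means, replicate_sd = 0, event_sd = 0,
                         gfp_sdlog = 0.2, n_events = 100)
  ev <- simulate_flow_sample(cfg, "BY", "SC")
  expect_equal(-log2(ev$rfp / ev$gfp), rep(2.5, 100), tolerance = 1e-12)
})

test_that("a planted interaction appears as a difference of differences", {
  means <- expand.grid(strain = c("BY", "RM"), environment = c("SC", "AZC"),
                       stringsAsFactors = FALSE)
  means$mean <- with(means, 2 + 0.2 * (strain == "RM") -
                       0.3 * (environment == "AZC") +
                       0.5 * (strain == "RM" & environment == "AZC"))
  cfg <- flow_sim_config(means, replicate_sd = 0, event_sd = 0.5,
                         n_events = 12000, n_replicates = 1, seed = 109)
  ev <- simulate_flow_experiment(cfg)
  act <- -log2(ev$rfp / ev$gfp)
  m <- tapply(act, paste(ev$strain, ev$environment), mean)
  dd <- (m[["RM AZC"]] - m[["RM SC"]]) - (m[["BY AZC"]] - m[["BY SC"]])
  expect_lt(abs(dd - 0.5), 3 * 0.5 * sqrt(4 / 12000))
})

test_that("bimodal forward scatter produces two density modes", {
  means <- data.frame(strain = "BY", environment = "SC", mean = 2)
  cfg <- flow_sim_config(means, fsc_mode = "bimodal", fsc_means = c(80, 120),
                         fsc_sd = 5, n_events = 5000, seed = 110)
  ev <- simulate_flow_sample(cfg, "BY", "SC")
  d <- density(ev$fsc)
  y <- d$y
  peaks <- which(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] > y[3:length(y)]) + 1
  main <- d$x[peaks[y[peaks] > 0.2 * max(y)]]
  expect_gte(length(main), 2)
  expect_lt(abs(min(main) - 80), 5)
  expect_lt(abs(max(main) - 120), 5)
})
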