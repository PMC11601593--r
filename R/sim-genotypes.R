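# Synthetic segregant pools: genotypes, phenotypes, FACS tails, pooled reads

#' Configuration for segregant-pool simulation
#'
#' Collects the parameters of the in-silico bulk-segregant experiment: the
#' size of the haploid segregant population, the FACS tail fraction, pooled
#' sequencing depth and error, the recombination map density, and phenotype
#' noise.
#'
#' @param n_segregants Number of haploid recombinant segregants in the
#'   pre-sort population.
#' @param tail_fraction Fraction of the phenotype distribution sorted into
#'   each extreme pool (default 0.02, i.e. the 2% high and low tails).
#' @param mean_depth Mean pooled sequencing depth per marker (reads); depth is
#'   Poisson-distributed around this value.
#' @param seq_error Per-read probability of reporting the other allele
#'   (symmetric flip; default 0.002).
#' @param bp_per_cM Map density in base pairs per centiMorgan (default 2200,
#'   the value used for the BY x RM cross).
#' @param noise_sd Phenotype noise standard deviation; QTL effects are
#'   expressed in units of this SD (default 1).
#' @param seed Optional integer seed applied before simulation.
#'
#' @return A `pool_sim_config` list.
#' @export
pool_sim_config <- function(n_segregants = 10000, tail_fraction = 0.02,
                            mean_depth = 100, seq_error = 0.002,
                            bp_per_cM = 2200, noise_sd = 1, seed = NULL) {
  stopifnot(n_segregants >= 0,
            tail_fraction > 0, tail_fraction <= 0.5,
            mean_depth > 0,
            seq_error >= 0, seq_error < 0.5,
            bp_per_cM > 0, noise_sd >= 0)
  structure(list(n_segregants = n_segregants, tail_fraction = tail_fraction,
                 mean_depth = mean_depth, seq_error = seq_error,
                 bp_per_cM = bp_per_cM, noise_sd = noise_sd, seed = seed),
            class = "pool_sim_config")
}

#' Planted QTL architecture
#'
#' Describes the additive effects planted in the simulated cross: each row is
#' one locus in one environment, with the phenotype shift (in phenotype-SD
#' units) conferred by the RM allele. A locus absent from an environment has
#' effect 0 there, which encodes presence/absence GxE; opposite signs across
#' environments encode sign-change GxE.
#'
#' @param chrom,pos,environment,effect Vectors (recycled to common length)
#'   giving locus position and per-environment additive effect.
#' @param environments Character vector of all environment labels the
#'   architecture is defined for (defaults to the labels present in
#'   `environment`). Phenotype assignment rejects labels outside this set.
#'
#' @return A `qtl_architecture` data frame with columns `chrom`, `pos`,
#'   `environment`, `effect`.
#' @export
qtl_architecture <- function(chrom = character(), pos = numeric(),
                             environment = character(), effect = numeric(),
                             environments = NULL) {
  a <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  environment = as.character(environment),
                  effect = as.numeric(effect), stringsAsFactors = FALSE)
  if (is.null(environments)) environments <- unique(a$environment)
  structure(a, environments = as.character(environments),
            class = c("qtl_architecture", "data.frame"))
}

#' Simulate recombinant haploid segregant genotypes
#'
#' Each segregant chromosome starts with a fair-coin parental allele;
#' crossover breakpoints are drawn as a Poisson process with rate one Morgan
#' per `bp_per_cM * 100` bp (no interference), and the allele alternates at
#' each breakpoint. This reproduces Haldane's map function for the
#' recombination fraction between any two markers.
#'
#' @param genome A [genome_model()].
#' @param markers A `marker_map` covered by `genome`.
#' @param n Number of segregants (`>= 0`).
#' @param cfg A [pool_sim_config()]; `bp_per_cM` sets the crossover rate and
#'   `seed`, if non-NULL, is applied first.
#'
#' @return Integer matrix `n x n_markers` with entries 0 (BY allele) and
#'   1 (RM allele); columns named `chrom:pos`. Attribute `crossovers` holds
#'   the genome-wide crossover count per segregant.
#' @export
simulate_segregant_genotypes <- function(genome, markers, n, cfg = pool_sim_config()) {
  validate_marker_map(markers, genome)
  stopifnot(n >= 0, nrow(markers) > 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  morgan_bp <- cfg$bp_per_cM * 100
  cols <- paste(markers$chrom, markers$pos, sep = ":")
  G <- matrix(0L, nrow = n, ncol = nrow(markers), dimnames = list(NULL, cols))
  xo <- integer(n)
  attr(G, "crossovers") <- xo
  if (n == 0) return(G)
  len <- stats::setNames(genome$length, genome$chrom)
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    pos <- markers$pos[idx]
    # Poisson crossover counts in the disjoint intervals
    # (0,p1], (p1,p2], ..., (pM, L]; only the parity up to each marker
    # matters for genotypes, the final interval only for crossover totals.
    bounds <- c(0, pos, len[[ch]])
    lambda <- diff(bounds) / morgan_bp
    m <- length(lambda)
    C <- matrix(stats::rpois(n * m, rep(lambda, each = n)), nrow = n)
    start <- stats::rbinom(n, 1L, 0.5)
    parity <- start
    for (j in seq_along(pos)) {
      parity <- parity + C[, j]
      G[, idx[j]] <- parity %% 2L
    }
    xo <- xo + as.integer(rowSums(C))
  }
  attr(G, "crossovers") <- xo
  G
}

#' Assign phenotypes from a planted QTL architecture
#'
#' Phenotype = sum of the environment's additive effects over RM-carried loci
#' plus Gaussian noise with SD `cfg$noise_sd`.
#'
#' @param genotypes Genotype matrix from [simulate_segregant_genotypes()].
#' @param arch A [qtl_architecture()]; all loci must sit on the marker map
#'   (i.e. match a genotype column).
#' @param environment Environment label; must belong to the architecture's
#'   declared environment set.
#' @param cfg A [pool_sim_config()].
#'
#' @return Numeric phenotype vector of length `nrow(genotypes)`.
#' @export
assign_phenotypes <- function(genotypes, arch, environment, cfg = pool_sim_config()) {
  stopifnot(inherits(arch, "qtl_architecture"))
  envs <- attr(arch, "environments")
  if (!environment %in% envs)
    stop("unknown environment label: ", environment)
  eff <- arch[arch$environment == environment, , drop = FALSE]
  n <- nrow(genotypes)
  phen <- stats::rnorm(n, 0, cfg$noise_sd)
  if (nrow(eff)) {
    key <- paste(eff$chrom, eff$pos, sep = ":")
    miss <- setdiff(key, colnames(genotypes))
    if (length(miss))
      stop("architecture loci not on the marker map: ",
           paste(miss, collapse = ", "))
    phen <- phen + as.numeric(genotypes[, key, drop = FALSE] %*% eff$effect)
  }
  phen
}

#' Select FACS tail pools from a phenotype distribution
#'
#' Emulates sorting the extreme tails of the reporter distribution: the
#' default mode takes the `floor(n * tail_fraction)` largest and smallest
#' phenotypes. A band mode `(lo_q, hi_q)` instead takes the cells occupying
#' that quantile band on each side (e.g. the 3-5% area of the distribution,
#' the fallback used when the outermost tail cannot be re-collected).
#'
#' @param phenotypes Numeric vector.
#' @param tail_fraction Tail proportion in (0, 0.5].
#' @param band Optional numeric `c(lo_q, hi_q)` with
#'   `0 < lo_q < hi_q <= 0.5`; overrides `tail_fraction`.
#'
#' @return List with integer index vectors `high` and `low` (disjoint, equal
#'   size). Ties at a cut are resolved by original index, ascending.
#' @export
select_tails <- function(phenotypes, tail_fraction = 0.02, band = NULL) {
  n <- length(phenotypes)
  ord <- order(phenotypes, seq_len(n))  # ascending, stable in input index
  if (is.null(band)) {
    stopifnot(tail_fraction > 0, tail_fraction <= 0.5)
    k <- floor(n * tail_fraction)
    if (k == 0) stop("tail_fraction selects zero cells")
    low <- ord[seq_len(k)]
    high <- ord[seq.int(n - k + 1L, n)]
  } else {
    stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2], band[2] <= 0.5)
    lo_rank <- floor(n * band[1])
    hi_rank <- floor(n * band[2])
    if (hi_rank <= lo_rank) stop("band selects zero cells")
    low <- ord[seq.int(lo_rank + 1L, hi_rank)]
    high <- ord[seq.int(n - hi_rank + 1L, n - lo_rank)]
  }
  list(high = high, low = low)
}

#' Sequence a sorted pool at the marker map
#'
#' Per marker, read depth is Poisson around `cfg$mean_depth` and the RM read
#' count is binomial with success probability `f*(1-e) + (1-f)*e`, where `f`
#' is the RM allele frequency among the pooled cells and `e` the symmetric
#' sequencing error.
#'
#' @param pool_genotypes Genotype matrix restricted to the pooled cells
#'   (rows); columns must align with `markers`.
#' @param markers The `marker_map` the columns correspond to.
#' @param cfg A [pool_sim_config()].
#' @param sample_id Sample label stored in the output table.
#'
#' @return An `allele_count_table`: data frame with columns `chrom`, `pos`,
#'   `count_BY`, `count_RM`, `sample`.
#' @export
sequence_pool <- function(pool_genotypes, markers, cfg = pool_sim_config(),
                          sample_id = "pool") {
  if (nrow(pool_genotypes) == 0) stop("pool is empty")
  stopifnot(ncol(pool_genotypes) == nrow(markers))
  f <- colMeans(pool_genotypes)
  m <- length(f)
  depth <- stats::rpois(m, cfg$mean_depth)
  p <- f * (1 - cfg$seq_error) + (1 - f) * cfg$seq_error
  count_rm <- stats::rbinom(m, depth, p)
  allele_count_table(chrom = markers$chrom, pos = markers$pos,
                     count_BY = depth - count_rm, count_RM = count_rm,
                     sample = sample_id)
}

#' Additive effect producing a target pool allele-frequency divergence
#'
#' Solves for the per-locus additive effect (in phenotype-SD units) such that
#' selecting the `tail_fraction` extremes of the phenotype yields an expected
#' RM allele-frequency difference of `target_delta_af` between the high and
#' low pools at the locus. Accounts for the phenotypic variance contributed
#' by `n_loci - 1` other loci of equal effect.
#'
#' @param target_delta_af Desired expected high-minus-low RM frequency
#'   difference, in (0, 1).
#' @param tail_fraction Sorted tail proportion.
#' @param n_loci Number of equal-effect loci in the architecture.
#' @param noise_sd Phenotype noise SD.
#'
#' @return The additive effect size (positive scalar).
#' @export
tail_effect_for_delta_af <- function(target_delta_af, tail_fraction = 0.02,
                                     n_loci = 1, noise_sd = 1) {
  stopifnot(target_delta_af > 0, target_delta_af < 1)
  expected_delta <- function(a) {
    sigma_b <- sqrt(noise_sd^2 + a^2 * (n_loci - 1) / 4)
    # phenotype is a 50:50 mixture N(0, sb^2) and N(a, sb^2) wrt the focal
    # locus; find the upper-tail cut t with mass tail_fraction
    t_hi <- stats::uniroot(function(t) {
      0.5 * (stats::pnorm(t, 0, sigma_b, lower.tail = FALSE) +
             stats::pnorm(t, a, sigma_b, lower.tail = FALSE)) - tail_fraction
    }, interval = c(-10 * sigma_b, a + 10 * sigma_b))$root
    f_high <- 0.5 * stats::pnorm(t_hi, a, sigma_b, lower.tail = FALSE) / tail_fraction
    # low tail is the mirror image
    t_lo <- stats::uniroot(function(t) {
      0.5 * (stats::pnorm(t, 0, sigma_b) + stats::pnorm(t, a, sigma_b)) - tail_fraction
    }, interval = c(-10 * sigma_b, a + 10 * sigma_b))$root
    f_low <- 0.5 * stats::pnorm(t_lo, a, sigma_b) / tail_fraction
    f_high - f_low
  }
  stats::uniroot(function(a) expected_delta(a) - target_delta_af,
                 interval = c(1e-4, 10), tol = 1e-7)$root
}

# Conditional genotype simulation for the members of a sorted pool: alleles
# along a chromosome form a stationary two-state Markov chain (Haldane), so
# conditional on the allele at a single anchor locus the left and right arms
# can be simulated outward independently. Selection acts only through the
# anchor alleles (+ independent noise), so the conditional law of the other
# markers given the anchors is unchanged by selection.
.conditional_pool_genotypes <- function(markers, anchors, anchor_alleles,
                                        bp_per_cM) {
  morgan_bp <- bp_per_cM * 100
  n <- if (is.matrix(anchor_alleles)) nrow(anchor_alleles) else length(anchor_alleles)
  G <- matrix(0L, nrow = n, ncol = nrow(markers))
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    pos <- markers$pos[idx]
    a_here <- which(anchors$chrom == ch)
    if (length(a_here) == 0) {
      # no planted locus: unconditional stationary chain
      state <- stats::rbinom(n, 1L, 0.5)
      G[, idx[1]] <- state
      if (length(pos) > 1) {
        r <- (1 - exp(-2 * diff(pos) / morgan_bp)) / 2
        for (j in 2:length(pos)) {
          flip <- stats::rbinom(n, 1L, r[j - 1])
          state <- (state + flip) %% 2L
          G[, idx[j]] <- state
        }
      }
    } else {
      if (length(a_here) > 1)
        stop("conditional simulation supports at most one planted locus per chromosome")
      a_pos <- anchors$pos[a_here]
      j0 <- which(pos == a_pos)
      if (length(j0) != 1)
        stop("planted locus not on the marker map: ", ch, ":", a_pos)
      anchor <- if (is.matrix(anchor_alleles)) anchor_alleles[, a_here] else anchor_alleles
      G[, idx[j0]] <- anchor
      if (j0 < length(pos)) {
        state <- anchor
        r <- (1 - exp(-2 * diff(pos[j0:length(pos)]) / morgan_bp)) / 2
        for (j in (j0 + 1):length(pos)) {
          flip <- stats::rbinom(n, 1L, r[j - j0])
          state <- (state + flip) %% 2L
          G[, idx[j]] <- state
        }
      }
      if (j0 > 1) {
        state <- anchor
        r <- (1 - exp(-2 * diff(pos[1:j0]) / morgan_bp)) / 2
        for (j in (j0 - 1):1) {
          flip <- stats::rbinom(n, 1L, r[j])
          state <- (state + flip) %% 2L
          G[, idx[j]] <- state
        }
      }
    }
  }
  colnames(G) <- paste(markers$chrom, markers$pos, sep = ":")
  G
}

#' Simulate one complete bulk-segregant mapping experiment
#'
#' Generates a segregant population, assigns phenotypes under a planted
#' architecture, sorts the high and low tails, and sequences both pools.
#' When every planted locus sits on its own chromosome (the usual design),
#' a conditional simulation path draws full genotypes only for the sorted
#' cells, conditional on their planted-locus alleles; this is exact (the
#' allele process is Markov along the chromosome and selection acts only
#' through the planted loci) and much faster than materialising the whole
#' population's genotypes.
#'
#' @param genome A [genome_model()].
#' @param markers A `marker_map`.
#' @param arch A [qtl_architecture()].
#' @param environment Environment label to simulate.
#' @param cfg A [pool_sim_config()].
#' @param sample_prefix Prefix for the two sample ids (`<prefix>_high`,
#'   `<prefix>_low`).
#' @param fast Use the conditional path when possible (default TRUE).
#'
#' @return List with `high` and `low` `allele_count_table`s, `pool_cells`
#'   (cells per pool), and `truth` (the architecture rows active in this
#'   environment).
#' @export
simulate_mapping_experiment <- function(genome, markers, arch, environment,
                                        cfg = pool_sim_config(),
                                        sample_prefix = "pool", fast = TRUE) {
  stopifnot(inherits(arch, "qtl_architecture"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_segregants
  eff <- arch[arch$environment == environment, , drop = FALSE]
  loci <- unique(arch[, c("chrom", "pos")])
  one_per_chrom <- !anyDuplicated(loci$chrom)
  if (fast && one_per_chrom) {
    # planted-locus alleles for the whole population: loci on distinct
    # chromosomes are independent fair coins
    A <- matrix(stats::rbinom(n * nrow(loci), 1L, 0.5), nrow = n)
    key <- paste(loci$chrom, loci$pos, sep = ":")
    phen <- stats::rnorm(n, 0, cfg$noise_sd)
    if (nrow(eff)) {
      e_vec <- stats::setNames(eff$effect, paste(eff$chrom, eff$pos, sep = ":"))
      phen <- phen + as.numeric(A[, match(names(e_vec), key), drop = FALSE] %*% e_vec)
    }
    tails <- select_tails(phen, cfg$tail_fraction)
    g_high <- .conditional_pool_genotypes(markers, loci,
                                          A[tails$high, , drop = FALSE],
                                          cfg$bp_per_cM)
    g_low <- .conditional_pool_genotypes(markers, loci,
                                         A[tails$low, , drop = FALSE],
                                         cfg$bp_per_cM)
  } else {
    cfg_noseed <- cfg; cfg_noseed$seed <- NULL
    G <- simulate_segregant_genotypes(genome, markers, n, cfg_noseed)
    phen <- assign_phenotypes(G, arch, environment, cfg_noseed)
    tails <- select_tails(phen, cfg$tail_fraction)
    g_high <- G[tails$high, , drop = FALSE]
    g_low <- G[tails$low, , drop = FALSE]
  }
  list(
    high = sequence_pool(g_high, markers, cfg, paste0(sample_prefix, "_high")),
    low = sequence_pool(g_low, markers, cfg, paste0(sample_prefix, "_low")),
    pool_cells = length(tails$high),
    truth = eff
  )
}
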