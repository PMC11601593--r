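# LOD scan contrasting high and low pools; QTL calling

#' Mapping parameters
#'
#' Parameters of the pooled-sequencing QTL scan: the track resolution, the
#' recombination map density, the effective pool size capping the information
#' a sequenced pool carries about its allele frequency (set by the number of
#' sorted cells, not read depth), the kernel half-width over which marker
#' counts are shared, the LOD calling threshold, and the support-interval
#' drop.
#'
#' @param bin_size Track bin size in bp (default 100).
#' @param bp_per_cM Map density (default 2200).
#' @param effective_pool_size Information cap `N`; local read counts `n` are
#'   shrunk to `n* = n N / (n + N)`. Use `Inf` to disable (default 1000).
#' @param kernel_halfwidth Tricube kernel half-width in bp (default 20000,
#'   about 9 cM at the default map density); `0` evaluates the single-marker
#'   statistic at each marker instead of a binned track.
#' @param lod_threshold QTL calling threshold (default 4.5).
#' @param ci_drop LOD drop defining the support interval (default 2).
#'
#' @return A `mapping_params` list.
#' @export
mapping_params <- function(bin_size = 100, bp_per_cM = 2200,
                           effective_pool_size = 1000,
                           kernel_halfwidth = 20000,
                           lod_threshold = 4.5, ci_drop = 2.0) {
  stopifnot(bin_size > 0, bp_per_cM > 0, effective_pool_size > 0,
            kernel_halfwidth >= 0, lod_threshold > ci_drop, ci_drop >= 0)
  structure(list(bin_size = bin_size, bp_per_cM = bp_per_cM,
                 effective_pool_size = effective_pool_size,
                 kernel_halfwidth = kernel_halfwidth,
                 lod_threshold = lod_threshold, ci_drop = ci_drop),
            class = "mapping_params")
}

# effective-depth cap: n* = n N / (n + N); counts rescaled proportionally
.cap_counts <- function(k, n, N) {
  if (!is.finite(N)) return(list(k = k, n = n))
  n_star <- n * N / (n + N)
  scale <- ifelse(n > 0, n_star / n, 0)
  list(k = k * scale, n = n_star)
}

# binomial likelihood-ratio LOD from (possibly fractional) local counts
.lod_from_counts <- function(kh, nh, kl, nl) {
  ph <- ifelse(nh > 0, kh / nh, 0.5)
  pl <- ifelse(nl > 0, kl / nl, 0.5)
  p0 <- ifelse(nh + nl > 0, (kh + kl) / (nh + nl), 0.5)
  lod <- (.binom_loglik(kh, nh, ph) + .binom_loglik(kl, nl, pl) -
          .binom_loglik(kh, nh, p0) - .binom_loglik(kl, nl, p0)) / log(10)
  lod[nh <= 0 | nl <= 0] <- 0
  pmax(lod, 0)
}

#' LOD scan contrasting the high and low pools
#'
#' At each 100-bp bin, marker read counts within the kernel half-width are
#' aggregated with tricube weights on genomic distance, shrunk to the
#' effective depth `n* = n N / (n + N)` so that information saturates at the
#' effective pool size, and scored with the binomial log-likelihood ratio of
#' a two-frequency model (pools differ) against a shared-frequency model,
#' expressed in log10 units (LOD). With `kernel_halfwidth = 0` the scan
#' degenerates to the closed-form single-marker statistic evaluated at each
#' marker.
#'
#' @param high,low [allele_count_table()]s for the two pools (already
#'   frequency-filtered); markers are matched on `chrom` + `pos`.
#' @param params A [mapping_params()].
#' @param genome Optional [genome_model()]; when given, the track spans each
#'   full chromosome, otherwise the marker extent.
#'
#' @return A `lod_track`: data frame `chrom`, `pos` (bin midpoint or marker
#'   position), `lod`.
#' @export
compute_lod_scan <- function(high, low, params = mapping_params(),
                             genome = NULL) {
  j <- merge(high[, c("chrom", "pos", "count_BY", "count_RM")],
             low[, c("chrom", "pos", "count_BY", "count_RM")],
             by = c("chrom", "pos"), suffixes = c("_h", "_l"), sort = FALSE)
  if (nrow(j) == 0) {
    out <- data.frame(chrom = character(), pos = numeric(), lod = numeric())
    class(out) <- c("lod_track", "data.frame")
    return(out)
  }
  chrom_order <- unique(high$chrom)
  j <- j[order(match(j$chrom, chrom_order), j$pos), , drop = FALSE]
  N <- params$effective_pool_size
  res <- lapply(intersect(chrom_order, unique(j$chrom)), function(ch) {
    m <- j[j$chrom == ch, , drop = FALSE]
    kh_m <- m$count_RM_h; nh_m <- m$count_RM_h + m$count_BY_h
    kl_m <- m$count_RM_l; nl_m <- m$count_RM_l + m$count_BY_l
    if (params$kernel_halfwidth <= 0) {
      pos <- m$pos
      kh <- kh_m; nh <- nh_m; kl <- kl_m; nl <- nl_m
    } else {
      L <- if (!is.null(genome)) genome$length[genome$chrom == ch] else max(m$pos)
      pos <- seq(params$bin_size / 2, L, by = params$bin_size)
      hw <- params$kernel_halfwidth
      # banded aggregation: only markers within the kernel support contribute
      lo <- findInterval(pos - hw, m$pos) + 1L
      hi <- findInterval(pos + hw, m$pos)
      K <- max(1L, max(hi - lo + 1L))
      idx <- outer(lo, 0:(K - 1L), "+")
      valid <- idx <= hi  # hi recycles down columns (rows = bins)
      idx_c <- pmin(pmax(idx, 1L), nrow(m))
      W <- .tricube(m$pos[idx_c] - pos, hw) * valid
      dim(W) <- dim(idx)
      kh <- rowSums(W * kh_m[idx_c]); nh <- rowSums(W * nh_m[idx_c])
      kl <- rowSums(W * kl_m[idx_c]); nl <- rowSums(W * nl_m[idx_c])
    }
    ch_cap <- .cap_counts(kh, nh, N)
    cl_cap <- .cap_counts(kl, nl, N)
    data.frame(chrom = ch, pos = pos,
               lod = .lod_from_counts(ch_cap$k, ch_cap$n, cl_cap$k, cl_cap$n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("lod_track", "data.frame")
  out
}

#' Call QTLs from a LOD track
#'
#' Each maximal contiguous run of bins at or above the LOD threshold yields
#' one QTL. The peak is the bin of maximal LOD (leftmost on ties); the
#' support interval extends from the peak in both directions up to, but not
#' including, the first bin whose LOD falls more than `ci_drop` below the
#' peak, clipped at the track ends. The effect size is the smoothed
#' allele-frequency difference at the marker nearest the peak.
#'
#' @param lod A `lod_track` from [compute_lod_scan()].
#' @param delta A `delta_af_track` from [compute_delta_af()] (may be NULL;
#'   the effect is then `NA` and flagged).
#' @param params A [mapping_params()].
#' @param reporter,environment,replicate Metadata attached to each call.
#'
#' @return A `qtl_table`: data frame `chrom`, `peak`, `ci_lo`, `ci_hi`,
#'   `lod`, `delta_af`, `reporter`, `environment`, `replicate`.
#' @export
call_qtls <- function(lod, delta = NULL, params = mapping_params(),
                      reporter = NA_character_, environment = NA_character_,
                      replicate = NA_character_) {
  rows <- list()
  for (ch in unique(lod$chrom)) {
    tr <- lod[lod$chrom == ch, , drop = FALSE]
    above <- tr$lod >= params$lod_threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      seg <- starts[i]:ends[i]
      peak_i <- seg[which.max(tr$lod[seg])]  # which.max is leftmost on ties
      peak_lod <- tr$lod[peak_i]
      floor_lod <- peak_lod - params$ci_drop
      lo_i <- peak_i
      while (lo_i > 1 && tr$lod[lo_i - 1] >= floor_lod) lo_i <- lo_i - 1
      hi_i <- peak_i
      while (hi_i < nrow(tr) && tr$lod[hi_i + 1] >= floor_lod) hi_i <- hi_i + 1
      d_af <- NA_real_
      if (!is.null(delta)) {
        dm <- delta[delta$chrom == ch, , drop = FALSE]
        if (nrow(dm))
          d_af <- dm$delta_af[which.min(abs(dm$pos - tr$pos[peak_i]))]
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, peak = tr$pos[peak_i],
        ci_lo = tr$pos[lo_i], ci_hi = tr$pos[hi_i],
        lod = peak_lod, delta_af = d_af,
        reporter = reporter, environment = environment,
        replicate = replicate, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), peak = numeric(), ci_lo = numeric(),
               ci_hi = numeric(), lod = numeric(), delta_af = numeric(),
               reporter = character(), environment = character(),
               replicate = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

#' Map one biological replicate end to end
#'
#' Composition of the per-replicate stages: frequency filtering of both pool
#' count tables, loess smoothing, the allele-frequency difference track, the
#' LOD scan, and QTL calling, concatenated across chromosomes.
#'
#' @param high,low [allele_count_table()]s for the two pools.
#' @param params A [mapping_params()].
#' @param genome Optional [genome_model()] for full-chromosome tracks.
#' @param bandwidth_bp Smoothing bandwidth passed to [smooth_frequency()].
#' @param af_lo,af_hi Frequency-filter bounds.
#' @param reporter,environment,replicate Metadata for the QTL table.
#'
#' @return List with `lod` (lod_track), `delta` (delta_af_track), `qtls`
#'   (qtl_table), and the filtered `high`/`low` tables.
#' @export
map_replicate <- function(high, low, params = mapping_params(), genome = NULL,
                          bandwidth_bp = 40000, af_lo = 0.1, af_hi = 0.9,
                          reporter = NA_character_,
                          environment = NA_character_,
                          replicate = NA_character_) {
  high_f <- filter_extreme_frequencies(high, af_lo, af_hi)
  low_f <- filter_extreme_frequencies(low, af_lo, af_hi)
  delta <- compute_delta_af(smooth_frequency(high_f, bandwidth_bp),
                            smooth_frequency(low_f, bandwidth_bp))
  lod <- compute_lod_scan(high_f, low_f, params, genome)
  qtls <- call_qtls(lod, delta, params, reporter, environment, replicate)
  list(lod = lod, delta = delta, qtls = qtls, high = high_f, low = low_f)
}
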