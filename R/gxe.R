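# Replicate reconciliation and QTL-level GxE classification

.MATCH_RADIUS <- 100000

#' Reconcile QTLs across two biological replicates
#'
#' QTLs present in both replicates are pairs on the same chromosome with
#' peaks within 100 kb and the same allele-frequency-difference sign.
#' Matching is greedy by peak distance (nearest pairs first, leftmost on
#' ties), each QTL used at most once, which makes the result symmetric in
#' replicate order. Matched pairs are averaged (peak, support interval, LOD,
#' delta AF) and flagged `replicated`; unmatched QTLs pass through unaveraged.
#'
#' @param qtls_rep1,qtls_rep2 `qtl_table`s from the two replicates of one
#'   reporter-by-environment experiment.
#' @param radius Matching radius in bp (default 100000).
#'
#' @return A `reconciled_qtl` data frame: the `qtl_table` columns plus
#'   `replicated` (logical).
#' @export
reconcile_replicates <- function(qtls_rep1, qtls_rep2, radius = .MATCH_RADIUS) {
  q1 <- as.data.frame(qtls_rep1); q2 <- as.data.frame(qtls_rep2)
  cand <- list()
  for (i in seq_len(nrow(q1))) for (j in seq_len(nrow(q2))) {
    if (q1$chrom[i] == q2$chrom[j] &&
        abs(q1$peak[i] - q2$peak[j]) <= radius &&
        sign(q1$delta_af[i]) == sign(q2$delta_af[j])) {
      cand[[length(cand) + 1]] <- c(i = i, j = j,
                                    d = abs(q1$peak[i] - q2$peak[j]),
                                    pos = min(q1$peak[i], q2$peak[j]))
    }
  }
  used1 <- logical(nrow(q1)); used2 <- logical(nrow(q2))
  pairs <- list()
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, "d"], cm[, "pos"]), , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (!used1[i] && !used2[j]) {
        used1[i] <- TRUE; used2[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  rows <- list()
  for (p in pairs) {
    a <- q1[p[1], ]; b <- q2[p[2], ]
    rows[[length(rows) + 1]] <- data.frame(
      chrom = a$chrom, peak = (a$peak + b$peak) / 2,
      ci_lo = (a$ci_lo + b$ci_lo) / 2, ci_hi = (a$ci_hi + b$ci_hi) / 2,
      lod = (a$lod + b$lod) / 2, delta_af = (a$delta_af + b$delta_af) / 2,
      reporter = a$reporter, environment = a$environment,
      replicate = "both", replicated = TRUE, stringsAsFactors = FALSE)
  }
  singles <- rbind(q1[!used1, , drop = FALSE], q2[!used2, , drop = FALSE])
  if (nrow(singles)) {
    singles$replicated <- FALSE
    rows[[length(rows) + 1]] <- singles
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    s <- q1[0, , drop = FALSE]; s$replicated <- logical(0); s
  }
  out <- out[order(match(out$chrom, unique(out$chrom)), out$peak), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reconciled_qtl", "data.frame")
  out
}

# nearest peak (bp distance) among rows of tab on the same chromosome
.peaks_within <- function(tab, chrom, peak, radius) {
  i <- which(tab$chrom == chrom & abs(tab$peak - peak) <= radius)
  i[order(abs(tab$peak[i] - peak))]
}

#' Classify QTL-level GxE between two environments
#'
#' For one reporter, compares the loci mapped in two environments and
#' classifies each replicated QTL:
#' \describe{
#'   \item{presence_absence}{detected in both replicates of one environment,
#'     with no QTL peak within 100 kb in either replicate of the other.}
#'   \item{sign_change}{a peak within 100 kb exists in at least one replicate
#'     of the other environment with the opposite delta-AF sign (flagged
#'     ambiguous when a same-sign peak is also within the radius).}
#'   \item{no_gxe_full}{a same-sign replicated QTL within 100 kb in the other
#'     environment.}
#'   \item{no_gxe_partial}{a same-sign peak in exactly one replicate of the
#'     other environment.}
#' }
#' Cross-environment pairs in which both sides are replicated are counted
#' once.
#'
#' @param env_a,env_b Lists with elements `rep1`, `rep2` (`qtl_table`s) and
#'   `reconciled` (from [reconcile_replicates()]) for the two environments.
#' @param env_a_label,env_b_label Environment names used in the output.
#' @param reporter Reporter label.
#' @param radius Matching radius in bp.
#'
#' @return A `gxe_comparison` data frame: `reporter`, `env_a`, `env_b`,
#'   `category`, `chrom`, `peak_a`, `peak_b`, `sign_a`, `sign_b`,
#'   `present_in` (environment holding the replicated QTL), `ambiguous`.
#' @export
classify_gxe <- function(env_a, env_b, env_a_label, env_b_label,
                         reporter = NA_character_, radius = .MATCH_RADIUS) {
  classify_side <- function(from, to, from_label, to_label, swap) {
    rec <- from$reconciled
    rec <- rec[rec$replicated, , drop = FALSE]
    to_rep_all <- rbind(as.data.frame(to$rep1), as.data.frame(to$rep2))
    to_rec <- to$reconciled[to$reconciled$replicated, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(rec))) {
      ch <- rec$chrom[i]; pk <- rec$peak[i]; sgn <- sign(rec$delta_af[i])
      near1 <- .peaks_within(as.data.frame(to$rep1), ch, pk, radius)
      near2 <- .peaks_within(as.data.frame(to$rep2), ch, pk, radius)
      near_any <- c(sign(to$rep1$delta_af[near1]), sign(to$rep2$delta_af[near2]))
      if (length(near_any) == 0) {
        category <- "presence_absence"; peak_b <- NA_real_; sign_b <- NA_real_
        partner_rec <- NA_integer_
      } else if (any(near_any == -sgn)) {
        category <- "sign_change"
        opp <- c(to$rep1$peak[near1], to$rep2$peak[near2])[near_any == -sgn]
        peak_b <- opp[1]; sign_b <- -sgn
        near_rec <- .peaks_within(to_rec, ch, pk, radius)
        partner_rec <- if (length(near_rec) &&
                           any(sign(to_rec$delta_af[near_rec]) == -sgn))
          near_rec[sign(to_rec$delta_af[near_rec]) == -sgn][1] else NA_integer_
      } else {
        near_rec <- .peaks_within(to_rec, ch, pk, radius)
        same_rec <- near_rec[sign(to_rec$delta_af[near_rec]) == sgn]
        if (length(same_rec)) {
          category <- "no_gxe_full"
          peak_b <- to_rec$peak[same_rec[1]]; sign_b <- sgn
          partner_rec <- same_rec[1]
        } else {
          category <- "no_gxe_partial"
          peak_b <- c(to$rep1$peak[near1], to$rep2$peak[near2])[1]
          sign_b <- sgn
          partner_rec <- NA_integer_
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        reporter = reporter,
        env_a = if (swap) to_label else from_label,
        env_b = if (swap) from_label else to_label,
        category = category, chrom = ch,
        peak_a = if (swap) peak_b else pk,
        peak_b = if (swap) pk else peak_b,
        sign_a = if (swap) sign_b else sgn,
        sign_b = if (swap) sgn else sign_b,
        present_in = from_label,
        ambiguous = category == "sign_change" && any(near_any == sgn),
        partner_rec = partner_rec, self_rec = i,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  side_a <- classify_side(env_a, env_b, env_a_label, env_b_label, swap = FALSE)
  side_b <- classify_side(env_b, env_a, env_b_label, env_a_label, swap = TRUE)
  # drop duplicates: pairs where both sides are replicated appear once from
  # each side; keep the env_a-side record
  if (!is.null(side_b)) {
    dup <- !is.na(side_b$partner_rec) &
      side_b$category %in% c("no_gxe_full", "sign_change")
    if (!is.null(side_a)) {
      keys_a <- paste(side_a$category, side_a$chrom, side_a$self_rec,
                      side_a$partner_rec)
      keys_b <- paste(side_b$category, side_b$chrom, side_b$partner_rec,
                      side_b$self_rec)
      dup <- dup & keys_b %in% keys_a
    } else dup <- rep(FALSE, nrow(side_b))
    side_b <- side_b[!dup, , drop = FALSE]
  }
  out <- rbind(side_a, side_b)
  if (is.null(out))
    out <- data.frame(reporter = character(), env_a = character(),
                      env_b = character(), category = character(),
                      chrom = character(), peak_a = numeric(),
                      peak_b = numeric(), sign_a = numeric(),
                      sign_b = numeric(), present_in = character(),
                      ambiguous = logical(), partner_rec = integer(),
                      self_rec = integer(), stringsAsFactors = FALSE)
  out$self_rec <- NULL
  out$partner_rec <- NULL
  rownames(out) <- NULL
  class(out) <- c("gxe_comparison", "data.frame")
  out
}

#' Count QTLs or GxE comparisons in consecutive 100-kb genomic bins
#'
#' Bins are half-open intervals `[k*bin_size, (k+1)*bin_size)` laid from
#' position 0 along each chromosome (the last bin is truncated at the
#' chromosome end); for the sacCer3 genome at 100 kb this yields exactly 128
#' bins. QTLs are assigned by their (averaged) peak; GxE comparisons by the
#' peak of their replicated QTL, sign-change pairs by the mean of the two
#' peaks.
#'
#' @param qtls A `reconciled_qtl` (or `qtl_table`) whose peaks fall inside
#'   the genome.
#' @param genome A [genome_model()].
#' @param bin_size Bin width in bp (default 100000).
#' @param comparisons Optional `gxe_comparison` table; its GxE rows
#'   (presence/absence and sign change) are counted into `n_gxe_comparisons`.
#'
#' @return A `bin_counts` data frame: `chrom`, `bin_index` (0-based within
#'   chromosome), `start`, `end`, `n_qtls`, `n_gxe_comparisons`.
#' @export
bin_qtls <- function(qtls, genome, bin_size = 100000, comparisons = NULL) {
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    n_bin <- ceiling(genome$length[i] / bin_size)
    idx <- seq_len(n_bin) - 1L
    data.frame(chrom = genome$chrom[i], bin_index = idx,
               start = idx * bin_size,
               end = pmin((idx + 1) * bin_size, genome$length[i]),
               stringsAsFactors = FALSE)
  }))
  assign_bin <- function(chrom, peak) {
    len <- genome$length[match(chrom, genome$chrom)]
    if (any(is.na(len)) || any(peak < 0 | peak > len))
      stop("peak outside genome bounds")
    paste(chrom, floor(peak / bin_size), sep = "|")
  }
  key <- paste(bins$chrom, bins$bin_index, sep = "|")
  n_qtls <- integer(nrow(bins))
  if (nrow(qtls)) {
    tab <- table(assign_bin(qtls$chrom, qtls$peak))
    n_qtls[match(names(tab), key)] <- as.integer(tab)
  }
  n_gxe <- integer(nrow(bins))
  if (!is.null(comparisons) && nrow(comparisons)) {
    gx <- comparisons[comparisons$category %in%
                        c("presence_absence", "sign_change"), , drop = FALSE]
    if (nrow(gx)) {
      pk <- ifelse(gx$category == "sign_change",
                   rowMeans(cbind(gx$peak_a, gx$peak_b)),
                   ifelse(is.na(gx$peak_a), gx$peak_b, gx$peak_a))
      # presence/absence: use the peak from the environment where the QTL
      # is present (the only one available)
      pa <- gx$category == "presence_absence"
      pk[pa] <- ifelse(is.na(gx$peak_a[pa]), gx$peak_b[pa], gx$peak_a[pa])
      tab <- table(assign_bin(gx$chrom, pk))
      n_gxe[match(names(tab), key)] <- as.integer(tab)
    }
  }
  out <- cbind(bins, n_qtls = n_qtls, n_gxe_comparisons = n_gxe)
  rownames(out) <- NULL
  class(out) <- c("bin_counts", "data.frame")
  out
}

#' Exact binomial test for RM-direction bias
#'
#' Tests whether the RM allele increases activity (positive delta AF) more
#' often than expected by chance among the supplied QTLs.
#'
#' @param qtls A `reconciled_qtl` or `qtl_table` with `delta_af`.
#' @param subset Optional logical vector selecting QTLs to include.
#'
#' @return List with `n_rm_up`, `n`, and the two-sided exact binomial
#'   `p_value` against 0.5.
#' @export
direction_bias_test <- function(qtls, subset = NULL) {
  d <- qtls$delta_af
  if (!is.null(subset)) d <- d[subset]
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no QTLs to test")
  n_up <- sum(d > 0)
  list(n_rm_up = n_up, n = length(d),
       p_value = stats::binom.test(n_up, length(d), 0.5)$p.value)
}

#' Spearman correlation of QTL and GxE counts across occupied bins
#'
#' Restricted to bins containing at least one QTL; correlates the number of
#' QTL peaks with the number of GxE comparisons per bin (tie-corrected
#' normal-approximation p-value).
#'
#' @param bins A `bin_counts` from [bin_qtls()].
#' @return List with `rho`, `p_value`, and `n_bins` used.
#' @export
bin_gxe_correlation <- function(bins) {
  occ <- bins[bins$n_qtls >= 1, , drop = FALSE]
  if (nrow(occ) < 3) stop("need at least 3 occupied bins")
  ct <- suppressWarnings(
    stats::cor.test(occ$n_qtls, occ$n_gxe_comparisons,
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_bins = nrow(occ))
}

#' Compare the current QTL set to a reference study
#'
#' Flags each current QTL as present in the reference when any reference
#' peak lies within 100 kb on the same chromosome (in at least one reference
#' replicate), then compares the LOD scores and absolute effect sizes of
#' present versus absent QTLs with Welch t-tests. Tests are skipped (NA,
#' with a flag) when either group has fewer than two members.
#'
#' @param current A `reconciled_qtl` table (e.g. QTLs replicated in the
#'   current study).
#' @param reference Replicate-level `qtl_table` from the reference study.
#' @param radius Matching radius in bp.
#'
#' @return List with `presence` (logical per current QTL), `p_lod`,
#'   `p_abs_delta_af`, and `tests_skipped`.
#' @export
compare_to_reference_set <- function(current, reference, radius = .MATCH_RADIUS) {
  if (nrow(current) == 0 || nrow(reference) == 0)
    stop("both QTL sets must be nonempty")
  present <- vapply(seq_len(nrow(current)), function(i) {
    length(.peaks_within(reference, current$chrom[i], current$peak[i],
                         radius)) > 0
  }, logical(1))
  skipped <- sum(present) < 2 || sum(!present) < 2
  p_lod <- p_daf <- NA_real_
  if (!skipped) {
    safe_t <- function(x, y) tryCatch(stats::t.test(x, y)$p.value,
                                      error = function(e) NA_real_)
    p_lod <- safe_t(current$lod[present], current$lod[!present])
    p_daf <- safe_t(abs(current$delta_af[present]),
                    abs(current$delta_af[!present]))
  }
  list(presence = present, p_lod = p_lod, p_abs_delta_af = p_daf,
       tests_skipped = skipped)
}
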