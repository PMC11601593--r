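# Flow-cytometry analysis: gating, UPS activity, GxE tests

.sample_key <- function(events) {
  paste(events$strain, events$reporter, events$environment, events$replicate,
        sep = "|")
}

# valley position between the two dominant modes of a kernel density; NULL
# when the density has fewer than two modes
.density_valley <- function(x) {
  d <- stats::density(x)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                       y[2:(length(y) - 1)] > y[3:length(y)], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2) return(NULL)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- top2[1]:top2[2]
  d$x[between[which.min(y[between])]]
}

#' Gate events on forward scatter
#'
#' Keeps, within each sample, the events whose FSC lies within
#' `median * (1 +/- window)` (a proxy for cell size that removes debris and
#' aggregates). In `lower_peak` mode the sample is first restricted to the
#' lower-FSC mode of a two-component density (cut at the valley between the
#' two dominant modes), the behaviour used for bimodal samples such as
#' incompletely budded cells in low nitrogen; the median window is then
#' applied within that mode.
#'
#' @param events A `flow_event_table` (one or more samples).
#' @param window Half-width of the relative FSC window (default 0.10).
#' @param mode `"unimodal"` or `"lower_peak"`.
#'
#' @return The gated `flow_event_table` (a subset of the input rows).
#'   Errors if a sample loses all its events.
#' @export
gate_fsc <- function(events, window = 0.10, mode = c("unimodal", "lower_peak")) {
  mode <- match.arg(mode)
  if (nrow(events) == 0) stop("no events to gate")
  keys <- .sample_key(events)
  keep <- logical(nrow(events))
  for (k in unique(keys)) {
    i <- which(keys == k)
    fsc <- events$fsc[i]
    sel <- rep(TRUE, length(i))
    if (mode == "lower_peak") {
      valley <- .density_valley(fsc)
      if (!is.null(valley)) sel <- fsc <= valley
    }
    med <- stats::median(fsc[sel])
    sel <- sel & fsc >= med * (1 - window) & fsc <= med * (1 + window)
    if (!any(sel)) stop("all events gated out for sample ", k)
    keep[i[sel]] <- TRUE
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-event raw UPS activity
#'
#' `activity_raw = -log2(rfp / gfp)`; the TFT's RFP/GFP ratio is inversely
#' related to the reporter's degradation rate, so higher values mean higher
#' UPS activity. Events with nonpositive RFP or GFP, for which the ratio is
#' undefined, are dropped and counted in the `n_dropped` attribute.
#'
#' @param events A `flow_event_table`.
#' @return The events with an added `activity_raw` column; attribute
#'   `n_dropped` counts removed events.
#' @export
compute_activity <- function(events) {
  ok <- events$gfp > 0 & events$rfp > 0
  out <- events[ok, , drop = FALSE]
  out$activity_raw <- -log2(out$rfp / out$gfp)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Time-detrend activity within each sample
#'
#' UPS activity can drift over the acquisition window; the time-corrected
#' activity is the residual of a per-sample loess regression of raw activity
#' on acquisition time, re-centered on the sample's mean raw activity so
#' samples remain comparable on the original scale. Samples with fewer than
#' `min_events` events, or with degenerate (constant) time, are mean-centered
#' only and flagged.
#'
#' @param events Output of [compute_activity()] (needs `activity_raw`).
#' @param span Loess span (default 0.75, degree 1).
#' @param min_events Minimum events for loess fitting (default 50).
#' @param recenter Add back each sample's mean raw activity so that the
#'   corrected values keep their location (default TRUE).
#'
#' @return An `activity_table`: the events with an `activity` column;
#'   attribute `flagged_samples` lists pass-through samples.
#' @export
detrend_activity <- function(events, span = 0.75, min_events = 50,
                             recenter = TRUE) {
  stopifnot("activity_raw" %in% names(events))
  keys <- .sample_key(events)
  activity <- numeric(nrow(events))
  flagged <- character(0)
  for (k in unique(keys)) {
    i <- which(keys == k)
    y <- events$activity_raw[i]
    t <- events$time[i]
    if (length(i) < min_events || length(unique(t)) < 2) {
      res <- y - mean(y)
      flagged <- c(flagged, k)
    } else {
      fit <- stats::loess(y ~ t, span = span, degree = 1)
      res <- stats::residuals(fit)
      res <- res - mean(res)
    }
    activity[i] <- res + if (recenter) mean(y) else 0
  }
  out <- events
  out$activity <- activity
  attr(out, "flagged_samples") <- flagged
  class(out) <- c("activity_table", class(events)[!class(events) %in% "activity_table"])
  out
}

#' Exclude reporter-by-environment groups with GFP below the negative control
#'
#' A reporter-by-environment group is excluded when any of its replicates has
#' a median GFP strictly below the median GFP of the negative control (a
#' strain with no reporter): low GFP means the reporter signal is not
#' distinguishable from background, and the whole group (all replicates) is
#' removed.
#'
#' @param events A `flow_event_table` of reporter samples.
#' @param control Events of the negative-control sample (nonempty).
#'
#' @return List with `retained` (events of surviving groups) and
#'   `exclusions` (data frame logging each excluded group with the offending
#'   replicate medians and the control median).
#' @export
qc_gfp_exclusion <- function(events, control) {
  if (is.null(control) || nrow(control) == 0) stop("negative control is required")
  ctrl_med <- stats::median(control$gfp)
  grp <- paste(events$reporter, events$environment, sep = "|")
  excl <- list()
  keep <- rep(TRUE, nrow(events))
  for (g in unique(grp)) {
    i <- which(grp == g)
    med_by_rep <- tapply(events$gfp[i], events$replicate[i], stats::median)
    if (any(med_by_rep < ctrl_med)) {
      keep[i] <- FALSE
      parts <- strsplit(g, "|", fixed = TRUE)[[1]]
      excl[[length(excl) + 1]] <- data.frame(
        reporter = parts[1], environment = parts[2],
        min_replicate_median_gfp = min(med_by_rep),
        control_median_gfp = ctrl_med, stringsAsFactors = FALSE)
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(reporter = character(), environment = character(),
               min_replicate_median_gfp = numeric(),
               control_median_gfp = numeric(), stringsAsFactors = FALSE)
  retained <- events[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, exclusions = exclusions)
}

.lrt_p <- function(full, reduced) {
  dev <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(reduced)))
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  stats::pchisq(pmax(dev, 0), df = df, lower.tail = FALSE)
}

#' Mixed-model test for genotype-by-environment interaction
#'
#' Fits `activity ~ strain * environment + (1 | replicate)` on per-cell
#' time-corrected activity, with the replicate random intercept coded either
#' nested within strain (default; replicate labels are made unique per
#' strain) or crossed (labels shared across strains). Each term's p-value
#' comes from a likelihood-ratio test of maximum-likelihood fits with and
#' without the term (the interaction against the additive model; each main
#' effect against the additive model without it). The interaction flag uses
#' a Bonferroni threshold `alpha / m`.
#'
#' @param activity An `activity_table` restricted to one reporter, two
#'   strains, and two environments (the baseline and one other).
#' @param baseline Baseline environment label (default `"SC"`).
#' @param m Size of the test family for Bonferroni correction.
#' @param alpha Family-wise error rate (default 0.05).
#' @param coding `"nested"` or `"crossed"` replicate coding.
#' @param tests Which terms to test (subset of
#'   `c("strain", "environment", "interaction")`).
#'
#' @return A `gxe_test_result` data frame with one row: `reporter`,
#'   `environment`, `p_strain`, `p_environment`, `p_interaction`,
#'   `threshold`, `significant_interaction`, `m`, plus a `singular` flag.
#' @export
test_gxe <- function(activity, baseline = "SC", m = 40, alpha = 0.05,
                     coding = c("nested", "crossed"),
                     tests = c("strain", "environment", "interaction")) {
  coding <- match.arg(coding)
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot("activity" %in% names(activity))
  envs <- unique(activity$environment)
  strains <- unique(activity$strain)
  if (length(envs) != 2 || !baseline %in% envs)
    stop("activity must contain the baseline and exactly one other environment")
  if (length(strains) != 2)
    stop("activity must contain exactly two strains")
  reps_per_cell <- table(activity$strain, activity$environment,
                         activity$replicate) > 0
  if (any(apply(reps_per_cell, 1:2, sum) < 2))
    stop("need >= 2 replicates in every strain-by-environment cell")
  d <- data.frame(
    activity = activity$activity,
    strain = factor(activity$strain),
    environment = stats::relevel(factor(activity$environment), ref = baseline),
    rep_group = if (coding == "nested")
      factor(paste(activity$strain, activity$replicate, sep = "."))
    else factor(activity$replicate))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit_full <- lme4::lmer(activity ~ strain * environment + (1 | rep_group),
                         data = d, REML = FALSE, control = ctrl)
  fit_add <- lme4::lmer(activity ~ strain + environment + (1 | rep_group),
                        data = d, REML = FALSE, control = ctrl)
  p_int <- p_strain <- p_env <- NA_real_
  if ("interaction" %in% tests) p_int <- .lrt_p(fit_full, fit_add)
  if ("strain" %in% tests) {
    fit_env <- lme4::lmer(activity ~ environment + (1 | rep_group),
                          data = d, REML = FALSE, control = ctrl)
    p_strain <- .lrt_p(fit_add, fit_env)
  }
  if ("environment" %in% tests) {
    fit_str <- lme4::lmer(activity ~ strain + (1 | rep_group),
                          data = d, REML = FALSE, control = ctrl)
    p_env <- .lrt_p(fit_add, fit_str)
  }
  thr <- alpha / m
  out <- data.frame(
    reporter = activity$reporter[1],
    environment = setdiff(envs, baseline),
    p_strain = p_strain, p_environment = p_env, p_interaction = p_int,
    threshold = thr,
    significant_interaction = !is.na(p_int) & p_int < thr,
    m = m, singular = lme4::isSingular(fit_full),
    stringsAsFactors = FALSE)
  class(out) <- c("gxe_test_result", "data.frame")
  out
}

#' Environment-effect sizes per strain (delta of replicate medians)
#'
#' For each strain and non-baseline environment, the effect is the median
#' over replicates of the per-replicate median activity in that environment
#' minus the same quantity in the baseline; the p-value is a two-tailed
#' Welch t-test on the replicate medians. Significance uses a Bonferroni
#' threshold `alpha / m`.
#'
#' @param activity An `activity_table` (one reporter, any environments).
#' @param baseline Baseline environment label.
#' @param m Test-family size for Bonferroni correction.
#' @param alpha Family-wise error rate.
#'
#' @return A `strain_env_effect` data frame: `strain`, `reporter`,
#'   `environment`, `delta`, `t_p`, `threshold`, `significant`.
#' @export
strain_env_deltas <- function(activity, baseline = "SC", m = 80, alpha = 0.05) {
  stopifnot("activity" %in% names(activity))
  envs <- setdiff(unique(activity$environment), baseline)
  if (!baseline %in% activity$environment)
    stop("baseline environment not present")
  rows <- list()
  for (s in unique(activity$strain)) for (e in envs) {
    a_env <- activity[activity$strain == s & activity$environment == e, ]
    a_sc <- activity[activity$strain == s & activity$environment == baseline, ]
    med_env <- tapply(a_env$activity, a_env$replicate, stats::median)
    med_sc <- tapply(a_sc$activity, a_sc$replicate, stats::median)
    if (length(med_env) < 2 || length(med_sc) < 2)
      stop("need >= 2 replicates per environment for ", s, " in ", e)
    delta <- stats::median(med_env) - stats::median(med_sc)
    p <- if (stats::sd(c(med_env, med_sc)) == 0) 1 else
      stats::t.test(med_env, med_sc)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      strain = s, reporter = activity$reporter[1], environment = e,
      delta = delta, t_p = p, threshold = alpha / m,
      significant = p < alpha / m, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("strain_env_effect", "data.frame")
  out
}
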