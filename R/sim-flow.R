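# Synthetic flow-cytometry events for TFT reporter assays

#' Configuration for flow-cytometry simulation
#'
#' The generative model for per-cell tandem-fluorescent-timer (TFT) events:
#' each sample (one strain in one environment, one replicate culture) has a
#' true UPS activity equal to a strain-by-environment mean plus a replicate
#' effect plus an acquisition-time drift plus per-event noise. GFP is
#' log-normal around a common intensity scale and RFP follows from the
#' activity through `RFP = GFP * 2^(-activity)`, so that
#' `-log2(RFP/GFP)` recovers the activity. Forward scatter is unimodal
#' Gaussian or a two-component mixture (as seen for incompletely budded
#' cells in low nitrogen).
#'
#' @param means Data frame with columns `strain`, `environment`, `mean`
#'   giving the true mean activity of every strain-by-environment cell; any
#'   GxE interaction is encoded directly in these means.
#' @param replicate_sd SD of replicate (culture/batch) effects; one effect is
#'   drawn per strain-by-replicate pair and shared across environments.
#' @param event_sd Per-event activity noise SD.
#' @param drift Drift shape over the acquisition window: `"none"`,
#'   `"linear"` (magnitude spread linearly, centered) or `"sine"`.
#' @param drift_magnitude Total drift amplitude in activity units.
#' @param n_events Events per sample.
#' @param n_replicates Replicate cultures per strain-by-environment.
#' @param gfp_scale Median GFP intensity (arbitrary units).
#' @param gfp_sdlog Log-SD of GFP intensities.
#' @param fsc_mode `"unimodal"` or `"bimodal"` forward scatter.
#' @param fsc_means FSC component mean(s); length 1 (unimodal) or 2.
#' @param fsc_sd FSC component SD.
#' @param reporter Reporter label stored with the events.
#' @param seed Optional integer seed.
#'
#' @return A `flow_sim_config` list.
#' @export
flow_sim_config <- function(means, replicate_sd = 0.1, event_sd = 0.5,
                            drift = c("none", "linear", "sine"),
                            drift_magnitude = 0, n_events = 500,
                            n_replicates = 8, gfp_scale = 1000,
                            gfp_sdlog = 0.25,
                            fsc_mode = c("unimodal", "bimodal"),
                            fsc_means = 100, fsc_sd = 5,
                            reporter = "reporter", seed = NULL) {
  drift <- match.arg(drift)
  fsc_mode <- match.arg(fsc_mode)
  stopifnot(is.data.frame(means),
            all(c("strain", "environment", "mean") %in% names(means)),
            n_events > 0, n_replicates >= 1, is.finite(drift_magnitude),
            replicate_sd >= 0, event_sd >= 0, gfp_scale > 0)
  if (fsc_mode == "bimodal" && length(fsc_means) != 2)
    stop("bimodal FSC needs two component means")
  structure(list(means = means, replicate_sd = replicate_sd,
                 event_sd = event_sd, drift = drift,
                 drift_magnitude = drift_magnitude, n_events = n_events,
                 n_replicates = n_replicates, gfp_scale = gfp_scale,
                 gfp_sdlog = gfp_sdlog, fsc_mode = fsc_mode,
                 fsc_means = fsc_means, fsc_sd = fsc_sd,
                 reporter = reporter, seed = seed),
            class = "flow_sim_config")
}

.drift_fun <- function(shape, magnitude) {
  switch(shape,
         none = function(t) rep(0, length(t)),
         linear = function(t) magnitude * (t - 0.5),
         sine = function(t) magnitude / 2 * sin(2 * pi * t))
}

#' Simulate one flow-cytometry sample
#'
#' @param cfg A [flow_sim_config()].
#' @param strain,environment Labels selecting the mean from `cfg$means`.
#' @param replicate Replicate id.
#' @param replicate_effect Activity offset of this replicate culture
#'   (default 0; [simulate_flow_experiment()] draws these).
#'
#' @return A `flow_event_table`: data frame `fsc`, `ssc`, `gfp`, `rfp`,
#'   `time` (acquisition fraction, non-decreasing), `strain`, `reporter`,
#'   `environment`, `replicate`.
#' @export
simulate_flow_sample <- function(cfg, strain, environment, replicate = "r1",
                                 replicate_effect = 0) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mu_row <- cfg$means$mean[cfg$means$strain == strain &
                           cfg$means$environment == environment]
  if (length(mu_row) != 1)
    stop("no unique mean for ", strain, " in ", environment)
  n <- cfg$n_events
  time <- seq_len(n) / n
  drift <- .drift_fun(cfg$drift, cfg$drift_magnitude)(time)
  activity <- mu_row + replicate_effect + drift +
    stats::rnorm(n, 0, cfg$event_sd)
  gfp <- stats::rlnorm(n, log(cfg$gfp_scale), cfg$gfp_sdlog)
  rfp <- gfp * 2^(-activity)
  if (cfg$fsc_mode == "unimodal") {
    fsc <- stats::rnorm(n, cfg$fsc_means[1], cfg$fsc_sd)
  } else {
    comp <- stats::rbinom(n, 1, 0.5)
    fsc <- stats::rnorm(n, cfg$fsc_means[1 + comp], cfg$fsc_sd)
  }
  ssc <- 0.6 * fsc + stats::rnorm(n, 0, cfg$fsc_sd)
  out <- data.frame(fsc = fsc, ssc = ssc, gfp = gfp, rfp = rfp, time = time,
                    strain = strain, reporter = cfg$reporter,
                    environment = environment, replicate = replicate,
                    stringsAsFactors = FALSE)
  class(out) <- c("flow_event_table", "data.frame")
  out
}

#' Simulate a full strain-by-environment flow experiment
#'
#' Generates events for every strain-by-environment combination in
#' `cfg$means` with `cfg$n_replicates` replicate cultures each. Replicate
#' effects are drawn once per strain-by-replicate pair and shared across
#' environments (a batch-like structure matching a random intercept per
#' replicate).
#'
#' @param cfg A [flow_sim_config()].
#' @return A combined `flow_event_table`.
#' @export
simulate_flow_experiment <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  strains <- unique(cfg$means$strain)
  envs <- unique(cfg$means$environment)
  rep_ids <- paste0("r", seq_len(cfg$n_replicates))
  rep_eff <- matrix(stats::rnorm(length(strains) * cfg$n_replicates,
                                 0, cfg$replicate_sd),
                    nrow = length(strains),
                    dimnames = list(strains, rep_ids))
  cfg_inner <- cfg; cfg_inner$seed <- NULL
  pieces <- list()
  for (s in strains) for (e in envs) for (r in rep_ids) {
    pieces[[length(pieces) + 1]] <-
      simulate_flow_sample(cfg_inner, s, e, r, rep_eff[s, r])
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("flow_event_table", "data.frame")
  out
}

#' Write flow events as CSV
#' @param events A `flow_event_table`.
#' @param path Output path.
#' @export
write_flow_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read flow events from CSV
#' @param path CSV with header
#'   `fsc,ssc,gfp,rfp,time,strain,reporter,environment,replicate`.
#' @return A `flow_event_table`.
#' @export
read_flow_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fsc", "ssc", "gfp", "rfp", "time", "strain", "reporter",
            "environment", "replicate")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("flow event CSV missing column(s): ", paste(miss, collapse = ", "))
  class(ev) <- c("flow_event_table", "data.frame")
  ev
}
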