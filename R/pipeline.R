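# End-to-end pipeline: simulate -> flow -> map -> classify -> report

#' Assemble a pipeline configuration
#'
#' @param genome A [genome_model()] (default [saccer3_genome()]).
#' @param n_markers Marker count for the synthetic map.
#' @param reporters Character vector of reporter names.
#' @param environments Character vector of environments; the first must be
#'   the baseline.
#' @param baseline Baseline environment label (default `"SC"`).
#' @param arch_list Named list (by reporter) of [qtl_architecture()]s.
#' @param pool_cfg A [pool_sim_config()].
#' @param flow_cfg Optional [flow_sim_config()] for the cytometry stage.
#' @param params A [mapping_params()].
#' @param n_replicates Biological replicates per reporter-by-environment
#'   mapping experiment (default 2).
#' @param m,m_prime Bonferroni family sizes for the interaction tests and the
#'   per-strain t-tests.
#' @param alpha Family-wise error rate.
#' @param seed Master seed; per-stage sub-seeds are streamed from it.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome = saccer3_genome(), n_markers = 1000,
                            reporters, environments, baseline = "SC",
                            arch_list, pool_cfg = pool_sim_config(),
                            flow_cfg = NULL, params = mapping_params(),
                            n_replicates = 2, m = 40, m_prime = 80,
                            alpha = 0.05, seed = 1) {
  stopifnot(m >= 1, m_prime >= 1, baseline %in% environments,
            all(reporters %in% names(arch_list)))
  structure(list(genome = genome, n_markers = n_markers,
                 reporters = reporters, environments = environments,
                 baseline = baseline, arch_list = arch_list,
                 pool_cfg = pool_cfg, flow_cfg = flow_cfg, params = params,
                 n_replicates = n_replicates, m = m, m_prime = m_prime,
                 alpha = alpha, seed = seed),
            class = "pipeline_config")
}

#' Demonstration pipeline configuration
#'
#' A small two-reporter, two-environment design with planted no-GxE,
#' presence/absence and sign-change loci, sized to run in seconds.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(seed = 1) {
  envs <- c("SC", "AZC")
  a <- tail_effect_for_delta_af(0.6, tail_fraction = 0.1, n_loci = 3)
  mk_arch <- function(c1, p1, c2, p2, c3, p3) qtl_architecture(
    chrom = c(c1, c1, c2, c3, c3),
    pos = c(p1, p1, p2, p3, p3),
    environment = c("SC", "AZC", "SC", "SC", "AZC"),
    effect = c(a, a, a, a, -a),
    environments = envs)
  arch_list <- list(
    Asn = mk_arch("chrIV", 500225, "chrVII", 420173, "chrXII", 650302),
    Phe = mk_arch("chrII", 400293, "chrX", 300493, "chrXIV", 500263))
  means <- expand.grid(strain = c("BY", "RM"), environment = envs,
                       stringsAsFactors = FALSE)
  means$mean <- with(means, 2 + 0.3 * (strain == "RM") -
                       0.4 * (environment == "AZC") +
                       0.5 * (strain == "RM" & environment == "AZC"))
  pipeline_config(
    genome = saccer3_genome(), n_markers = 500,
    reporters = c("Asn", "Phe"), environments = envs,
    arch_list = arch_list,
    pool_cfg = pool_sim_config(n_segregants = 2000, tail_fraction = 0.1,
                               mean_depth = 100),
    flow_cfg = flow_sim_config(means, n_events = 200, n_replicates = 4,
                               event_sd = 0.4, replicate_sd = 0.05),
    params = mapping_params(),
    m = 40, m_prime = 80, seed = seed)
}

# snap architecture loci onto the nearest marker of the map
.snap_arch <- function(arch, markers) {
  for (r in seq_len(nrow(arch))) {
    i <- which(markers$chrom == arch$chrom[r])
    if (!length(i)) stop("architecture chromosome not on marker map")
    arch$pos[r] <- markers$pos[i[which.min(abs(markers$pos[i] - arch$pos[r]))]]
  }
  arch
}

#' Run the full pipeline
#'
#' Simulates segregant pools for every reporter-by-environment-by-replicate
#' combination, maps QTLs per replicate, reconciles replicates, classifies
#' GxE against the baseline environment, bins QTLs and GxE cases genome-wide,
#' and (when a flow configuration is present) simulates and analyses the
#' cytometry experiment. All stage outputs are written under `out_dir` with
#' MD5 checksums in the run log; identical config and seed give identical
#' outputs. The effective pool size used for mapping is capped at the
#' simulated pool cell count (the cap cannot exceed the number of sorted
#' cells).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#'
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  seeds <- seed_stream(config$seed, 3 + length(config$reporters) *
                         length(config$environments) * config$n_replicates)
  markers <- uniform_marker_map(config$genome, config$n_markers)
  say("[simulate] ", nrow(markers), " markers, ",
      config$pool_cfg$n_segregants, " segregants")
  qtl_tables <- list()
  rec_tables <- list()
  si <- 3
  pool_cells <- NA_integer_
  for (rep_name in config$reporters) {
    arch <- .snap_arch(config$arch_list[[rep_name]], markers)
    for (env in config$environments) {
      reps <- list()
      for (r in seq_len(config$n_replicates)) {
        si <- si + 1
        cfg <- config$pool_cfg
        cfg$seed <- seeds[si]
        sim <- simulate_mapping_experiment(
          config$genome, markers, arch, env, cfg,
          sample_prefix = paste(rep_name, env, paste0("rep", r), sep = "_"))
        pool_cells <- sim$pool_cells
        prm <- config$params
        prm$effective_pool_size <- min(prm$effective_pool_size, sim$pool_cells)
        mapped <- map_replicate(sim$high, sim$low, prm, config$genome,
                                reporter = rep_name, environment = env,
                                replicate = paste0("rep", r))
        tag <- paste(rep_name, env, paste0("rep", r), sep = "_")
        write_allele_counts_tsv(sim$high,
                                file.path(out_dir, paste0(tag, "_high.tsv")))
        write_allele_counts_tsv(sim$low,
                                file.path(out_dir, paste0(tag, "_low.tsv")))
        write_bedgraph(mapped$lod, "lod",
                       file.path(out_dir, paste0(tag, "_lod.bedgraph")))
        write_bedgraph(mapped$delta, "delta_af",
                       file.path(out_dir, paste0(tag, "_delta_af.bedgraph")))
        reps[[r]] <- mapped$qtls
      }
      rec <- reconcile_replicates(reps[[1]], reps[[2]])
      key <- paste(rep_name, env, sep = "|")
      qtl_tables[[key]] <- list(rep1 = reps[[1]], rep2 = reps[[2]],
                                reconciled = rec)
      rec_tables[[key]] <- rec
      say("[map] ", key, ": ", sum(rec$replicated), " replicated QTLs (",
          nrow(rec), " total)")
    }
  }
  all_qtls <- do.call(rbind, lapply(names(qtl_tables), function(k) {
    cbind(qtl_tables[[k]]$reconciled)
  }))
  utils::write.table(all_qtls, file.path(out_dir, "qtls_reconciled.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comparisons <- list()
  for (rep_name in config$reporters) {
    for (env in setdiff(config$environments, config$baseline)) {
      cmp <- classify_gxe(qtl_tables[[paste(rep_name, config$baseline, sep = "|")]],
                          qtl_tables[[paste(rep_name, env, sep = "|")]],
                          config$baseline, env, reporter = rep_name)
      comparisons[[length(comparisons) + 1]] <- cmp
    }
  }
  comparisons <- do.call(rbind, comparisons)
  utils::write.table(comparisons, file.path(out_dir, "gxe_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  replicated <- all_qtls[all_qtls$replicated, , drop = FALSE]
  bins <- bin_qtls(replicated, config$genome, comparisons = comparisons)
  utils::write.table(bins, file.path(out_dir, "bin_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  direction <- if (nrow(replicated)) direction_bias_test(replicated) else NULL
  correlation <- if (sum(bins$n_qtls >= 1) >= 3) bin_gxe_correlation(bins) else NULL
  flow_summary <- NULL
  if (!is.null(config$flow_cfg)) {
    say("[flow] simulating cytometry experiment")
    fcfg <- config$flow_cfg
    fcfg$seed <- seeds[2]
    events <- simulate_flow_experiment(fcfg)
    write_flow_events_csv(events, file.path(out_dir, "flow_events.csv"))
    act <- detrend_activity(compute_activity(gate_fsc(events)))
    gxe_rows <- list()
    eff_rows <- list()
    for (env in setdiff(config$environments, config$baseline)) {
      sub <- act[act$environment %in% c(config$baseline, env), , drop = FALSE]
      gxe_rows[[length(gxe_rows) + 1]] <-
        test_gxe(sub, config$baseline, m = config$m, alpha = config$alpha)
    }
    eff_rows[[1]] <- strain_env_deltas(act, config$baseline,
                                       m = config$m_prime,
                                       alpha = config$alpha)
    gxe_tab <- do.call(rbind, gxe_rows)
    eff_tab <- do.call(rbind, eff_rows)
    utils::write.table(gxe_tab, file.path(out_dir, "flow_gxe_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(eff_tab, file.path(out_dir, "flow_env_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    flow_summary <- list(
      n_gxe_tests = nrow(gxe_tab),
      n_significant_interactions = sum(gxe_tab$significant_interaction),
      interaction_threshold = config$alpha / config$m,
      t_test_threshold = config$alpha / config$m_prime)
  }
  qtl_counts <- lapply(rec_tables, function(r)
    list(replicated = sum(r$replicated), total = nrow(r)))
  summary <- list(
    seed = config$seed,
    pool_cells = pool_cells,
    qtl_counts = qtl_counts,
    n_replicated_qtls = nrow(replicated),
    gxe_category_counts = as.list(table(comparisons$category)),
    n_comparisons = nrow(comparisons),
    total_bins = nrow(bins),
    occupied_bins = sum(bins$n_qtls >= 1),
    direction_bias = direction,
    bin_correlation = correlation,
    flow = flow_summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "run.log"))
  sums <- tools::md5sum(files)
  log_lines <- c(log_lines, paste(unname(sums), basename(names(sums))))
  writeLines(log_lines, log_path)
  invisible(summary)
}

#' Validate pipeline input files
#'
#' Schema checks for the TSV/CSV/VCF dialects the pipeline reads; fails fast
#' with an itemised report rather than downstream errors.
#'
#' @param paths Character vector of file paths.
#' @param formats Matching vector of formats (`"counts_tsv"`, `"vcf"`,
#'   `"flow_csv"`); guessed from extensions when missing.
#'
#' @return Data frame `path`, `format`, `ok`, `n_records`, `message`.
#' @export
validate_inputs <- function(paths, formats = NULL) {
  if (is.null(formats)) {
    formats <- ifelse(grepl("\\.vcf(\\.gz)?$", paths), "vcf",
                      ifelse(grepl("\\.csv$", paths), "flow_csv", "counts_tsv"))
  }
  check_one <- function(path, format) {
    if (!file.exists(path))
      return(list(ok = FALSE, n = 0L, msg = "file not found"))
    res <- tryCatch({
      if (format == "counts_tsv") {
        tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        need <- c("chrom", "pos", "count_BY", "count_RM", "sample")
        miss <- setdiff(need, names(tab))
        if (length(miss))
          list(ok = FALSE, n = nrow(tab),
               msg = paste("missing column(s):", paste(miss, collapse = ", ")))
        else if (any(tab$count_BY < 0 | tab$count_RM < 0))
          list(ok = FALSE, n = nrow(tab), msg = "negative counts")
        else list(ok = TRUE, n = nrow(tab), msg = "")
      } else if (format == "vcf") {
        hdr <- readLines(path, n = 200)
        if (!any(grepl("^##FORMAT=<ID=AD", hdr)))
          list(ok = FALSE, n = 0L, msg = "VCF lacks an AD FORMAT field")
        else {
          v <- vcfR::read.vcfR(path, verbose = FALSE)
          list(ok = TRUE, n = nrow(v@fix), msg = "")
        }
      } else {
        ev <- utils::read.csv(path, stringsAsFactors = FALSE, nrows = 5)
        need <- c("fsc", "ssc", "gfp", "rfp", "time", "strain", "reporter",
                  "environment", "replicate")
        miss <- setdiff(need, names(ev))
        if (length(miss))
          list(ok = FALSE, n = nrow(ev),
               msg = paste("missing column(s):", paste(miss, collapse = ", ")))
        else list(ok = TRUE,
                  n = length(utils::count.fields(path, sep = ",")) - 1L,
                  msg = "")
      }
    }, error = function(e) list(ok = FALSE, n = 0L, msg = conditionMessage(e)))
    res
  }
  rows <- Map(check_one, paths, formats)
  data.frame(path = paths, format = formats,
             ok = vapply(rows, `[[`, logical(1), "ok"),
             n_records = vapply(rows, function(r) as.integer(r$n), integer(1)),
             message = vapply(rows, `[[`, character(1), "msg"),
             stringsAsFactors = FALSE, row.names = NULL)
}
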