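# Orchestration: simulate -> analyze -> report.  Every analysis parameter
# lives in the pipeline config with its study default; subjects are
# analyzed strictly separately and never pooled or averaged anywhere in
# the outputs.

#' Pipeline configuration
#'
#' @param subjects list of per-subject lists with `subject_id` and
#'   `body_weight_kg` (defaults: the two-subject design, 5.8 and 7.5 kg).
#' @param tablet_doses_mg tablet dose list (mg).
#' @param sessions_per_dose_block,flank_placebo_count schedule parameters.
#' @param n_neurons,n_electrodes simulated ensemble size.
#' @param trials_mean,trials_sd per-session trial count distribution.
#' @param n_trials optional fixed trial count (overrides the distribution;
#'   used by scaled-down test scenarios).
#' @param hit_prob baseline hit probability (scalar or named by label).
#' @param loading_sd,independent_noise_scale generator noise structure.
#' @param alpha_selectivity selectivity threshold (0.01).
#' @param alpha behavioral/metric test level (0.05).
#' @param sdf_sigma_ms SDF kernel SD (30 ms).
#' @param fano_convention `"cv"` (SD/mean) or `"var_over_mean"`.
#' @param min_trials_per_condition inclusion threshold for noise
#'   correlations (10).
#' @param folds cross-validation folds (5).
#' @param n_perm permutations for decoding nulls (1000).
#' @param decode_null run the permutation null per session in the batch
#'   pipeline (default `FALSE`: the null is expensive and the dose
#'   comparisons do not require it; use [permutation_null()] directly).
#' @param hit_only_decoding restrict decoding to hit trials (`TRUE`).
#' @param hit_rate_denominator `"all"`: every non-hit outcome is a miss.
#' @param dose_fx optional [dose_effect_spec()] injected into the
#'   generator (default `NULL` = null study).
#' @param seed master seed.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(subjects = list(
                              list(subject_id = "F", body_weight_kg = 5.8),
                              list(subject_id = "JL", body_weight_kg = 7.5)),
                            tablet_doses_mg = c(2.5, 5, 6.25, 7.5, 10),
                            sessions_per_dose_block = 3,
                            flank_placebo_count = 2,
                            n_neurons = 48, n_electrodes = 32,
                            trials_mean = 817, trials_sd = 93,
                            n_trials = NULL,
                            hit_prob = 0.72,
                            loading_sd = 1.5,
                            independent_noise_scale = 0,
                            alpha_selectivity = 0.01,
                            alpha = 0.05,
                            sdf_sigma_ms = 30,
                            fano_convention = "cv",
                            min_trials_per_condition = 10,
                            folds = 5,
                            n_perm = 1000,
                            decode_null = FALSE,
                            hit_only_decoding = TRUE,
                            hit_rate_denominator = "all",
                            dose_fx = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

subject_seed <- function(cfg, s_idx) derive_seed(cfg$seed, 100000L * s_idx)

#' Simulate all sessions of the configured study
#'
#' One independent ensemble per subject; seeds follow the substream
#' policy, so the same config and seed reproduce the study bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return named list (by subject id) of lists of `session_record`s.
#' @export
simulate_configured_study <- function(config) {
  out <- list()
  for (si in seq_along(config$subjects)) {
    sub <- config$subjects[[si]]
    sc <- subject_config(sub$subject_id, sub$body_weight_kg,
                         config$tablet_doses_mg,
                         config$sessions_per_dose_block,
                         config$flank_placebo_count)
    ens <- make_ensemble(n_neurons = config$n_neurons,
                         n_electrodes = config$n_electrodes,
                         loading_sd = config$loading_sd,
                         independent_noise_scale =
                           config$independent_noise_scale,
                         seed = subject_seed(config, si))
    model <- behavior_model(hit_prob = config$hit_prob,
                            trials_mean = config$trials_mean,
                            trials_sd = config$trials_sd)
    out[[sub$subject_id]] <-
      simulate_study(sc, ens, model, config$dose_fx,
                     seed = subject_seed(config, si),
                     n_trials = config$n_trials)
  }
  out
}

pool_trials <- function(sessions, session_indices) {
  keep <- vapply(sessions, function(s)
    s$session_index %in% session_indices, logical(1))
  do.call(rbind, lapply(sessions[keep], function(s) s$trials))
}

analyze_subject <- function(sessions, schedule, config, out_dir, log) {
  epochs <- canonical_epochs()
  metric_rows <- list()
  pair_rows <- stats::setNames(vector("list", length(epochs)), names(epochs))
  decode_rows <- list()

  for (s in sessions) {
    res <- tryCatch({
      sel <- session_selectivity(s, config$alpha_selectivity, epochs)
      mt <- compute_metrics(s, sel, config$sdf_sigma_ms,
                            config$fano_convention)
      mt$subject <- s$subject_id
      mt$label <- s$label
      mt$session_index <- s$session_index
      pr <- lapply(epochs, function(ep)
        noise_correlations(s, ep, sel, config$min_trials_per_condition))
      dc <- do.call(rbind, lapply(c("cue", "attention", "saccade"),
        function(nm) {
          d <- tryCatch(
            decode_session(s, epochs[[nm]], folds = config$folds,
                           seed = derive_seed(config$seed, s$session_index),
                           hit_only = config$hit_only_decoding),
            error = function(e) NULL)
          if (is.null(d)) return(NULL)
          p_null <- NA_real_
          null_mean <- NA_real_
          if (isTRUE(config$decode_null)) {
            cm <- extract_counts(s, epochs[[nm]],
                                 outcomes = if (config$hit_only_decoding ||
                                                nm == "saccade") "hit"
                                            else NULL)
            pn <- permutation_null(cm$counts, cm$conditions,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(config$seed,
                                                      s$session_index),
                                   folds = config$folds, observed = d)
            p_null <- pn$p
            null_mean <- pn$null_mean
          }
          data.frame(session_index = s$session_index, label = s$label,
                     epoch = nm, accuracy = d$accuracy,
                     n_neurons = d$n_neurons, n_trials = d$n_trials,
                     null_mean = null_mean, p_null = p_null,
                     stringsAsFactors = FALSE)
        }))
      list(mt = mt, pr = pr, dc = dc)
    }, error = function(e) {
      log(sprintf("SESSION_FAILED: subject %s session %d: %s",
                  s$subject_id, s$session_index, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    metric_rows[[length(metric_rows) + 1]] <- res$mt
    for (nm in names(epochs))
      pair_rows[[nm]][[length(pair_rows[[nm]]) + 1]] <- res$pr[[nm]]
    decode_rows[[length(decode_rows) + 1]] <- res$dc
  }

  metrics <- do.call(rbind, metric_rows)
  decoding <- do.call(rbind, decode_rows)

  # behavior: dose pools vs flanking placebo pools
  doses <- sort(unique(schedule$dose_index[schedule$dose_index > 0]))
  beh_rows <- list()
  for (d in doses) {
    dose_tr <- pool_trials(sessions,
                           schedule$session_index[schedule$dose_index == d])
    pb_tr <- pool_trials(sessions, flanking_sessions(schedule, d))
    if (is.null(dose_tr) || is.null(pb_tr)) next
    cmp <- compare_to_matched_placebo(dose_tr, pb_tr,
                                      config$hit_rate_denominator)
    cmp$dose_index <- d
    cmp$label <- paste0("dose_", d)
    beh_rows[[length(beh_rows) + 1]] <- cmp
  }
  behavior <- do.call(rbind, beh_rows)

  # correlations: sign-split summaries and structure per epoch
  corr_summaries <- list()
  structures <- list()
  for (nm in names(epochs)) {
    pairs <- do.call(rbind, pair_rows[[nm]])
    if (is.null(pairs) || nrow(pairs) == 0) next
    for (subset in c("all", "selective")) {
      p_sub <- if (subset == "selective")
        pairs[pairs$both_selective, ] else pairs
      if (nrow(p_sub) == 0) next
      sm <- sign_split_summary(p_sub, schedule)
      sm$epoch <- nm
      sm$subset <- subset
      corr_summaries[[paste(nm, subset)]] <- sm
    }
    structures[[nm]] <- correlation_structure(pairs)
  }
  corr_summary <- do.call(rbind, corr_summaries)

  dec_change <- if (!is.null(decoding) && nrow(decoding) > 0)
    percent_change_from_flanking(decoding, schedule) else NULL

  list(metrics = metrics, behavior = behavior,
       corr_summary = corr_summary, structures = structures,
       decoding = decoding, decoding_change = dec_change)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) the sessions of every configured subject, runs
#' every analysis stage, and writes a per-subject report bundle of CSVs
#' plus a summary document.  Subjects are never pooled; the run is
#' deterministic under the configured seed, and per-session failures are
#' logged and skipped without aborting the run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for the report bundle.
#' @param sessions optional named list (by subject id) of session lists,
#'   e.g. from [simulate_configured_study()] or [read_session()]; when
#'   omitted the study is simulated from the config.
#' @return invisibly, the per-subject result lists.
#' @export
run_pipeline <- function(config, out_dir, sessions = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  if (is.null(sessions)) sessions <- simulate_configured_study(config)
  results <- list()
  all_tests <- list()

  for (si in seq_along(config$subjects)) {
    sub <- config$subjects[[si]]
    sid <- sub$subject_id
    sc <- subject_config(sid, sub$body_weight_kg, config$tablet_doses_mg,
                         config$sessions_per_dose_block,
                         config$flank_placebo_count)
    schedule <- build_schedule(sc)
    sdir <- file.path(out_dir, paste0("subject_", sid))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    res <- analyze_subject(sessions[[sid]], schedule, config, sdir, log)
    results[[sid]] <- res

    wcsv <- function(x, f) if (!is.null(x) && nrow(x) > 0)
      utils::write.csv(x, file.path(sdir, f), row.names = FALSE)
    wcsv(res$metrics, "metrics.csv")
    wcsv(res$behavior, "behavior_comparisons.csv")
    wcsv(res$corr_summary, "correlation_summary.csv")
    wcsv(res$decoding, "decoding.csv")
    if (!is.null(res$decoding_change)) {
      wcsv(res$decoding_change$summary, "decoding_change.csv")
      wcsv(res$decoding_change$anova, "decoding_anova.csv")
    }
    for (nm in names(res$structures))
      wcsv(res$structures[[nm]]$curve,
           sprintf("correlation_structure_%s.csv", nm))
    if (!is.null(res$metrics)) all_tests[[sid]] <- res$metrics
  }

  # metric dose scan: family = metrics x subjects, subjects never pooled
  scan <- NULL
  if (length(all_tests) > 0) {
    stacked <- do.call(rbind, all_tests)
    scan <- dose_effect_scan(stacked, alpha = config$alpha)
    utils::write.csv(scan$tests, file.path(out_dir, "metric_dose_scan.csv"),
                     row.names = FALSE)
    utils::write.csv(scan$group_stats,
                     file.path(out_dir, "metric_group_stats.csv"),
                     row.names = FALSE)
  }

  writeLines(render_summary(config, results, scan),
             file.path(out_dir, "summary.md"))
  if (length(log_lines) > 0)
    writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  invisible(list(results = results, scan = scan, log = log_lines))
}

render_summary <- function(config, results, scan) {
  ln <- c("# Analysis report", "",
          sprintf("Master seed: %d.  Subjects analyzed separately: %s.",
                  config$seed,
                  paste(names(results), collapse = ", ")), "")
  if (!is.null(scan)) {
    ln <- c(ln, sprintf(
      "## Metric dose scan: %d tests entered Bonferroni correction (m = %d); %d significant.",
      nrow(scan$tests), scan$m, sum(scan$tests$significant, na.rm = TRUE)), "")
  }
  for (sid in names(results)) {
    r <- results[[sid]]
    ln <- c(ln, sprintf("## Subject %s", sid))
    if (!is.null(r$behavior) && nrow(r$behavior) > 0) {
      hr <- r$behavior[r$behavior$measure == "hit_rate", ]
      ln <- c(ln, "", "Hit rate vs flanking placebo (chi-square):",
              sprintf("  %s: %.3f vs %.3f (chi2 = %.2f, p = %.3g)",
                      hr$label, hr$p_dose, hr$p_placebo, hr$chi_sq, hr$p))
    }
    if (!is.null(r$decoding) && nrow(r$decoding) > 0) {
      agg <- stats::aggregate(accuracy ~ epoch, data = r$decoding, FUN = mean)
      ln <- c(ln, "", "Mean decoding accuracy per epoch:",
              sprintf("  %s: %.1f%%", agg$epoch, 100 * agg$accuracy))
    }
    if (!is.null(r$corr_summary) && nrow(r$corr_summary) > 0) {
      pb <- r$corr_summary[r$corr_summary$label == "placebo" &
                             r$corr_summary$subset == "all", ]
      ln <- c(ln, "", "Placebo noise-correlation medians (all pairs):",
              sprintf("  %s: +%.4f / %.4f (n = %d / %d)",
                      pb$epoch, pb$median_pos, pb$median_neg,
                      pb$n_pos, pb$n_neg))
    }
    ln <- c(ln, "")
  }
  ln
}
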