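# The 19 single-neuron response metrics and the per-metric dose scan.
#
# Metric eligibility follows the epoch-selectivity rule: 1-11 are computed
# only for visually (cue-epoch) selective neurons, 12-15 only for
# attention-selective neurons, 16-19 only for saccade-selective neurons.
# All metrics are computed on correctly performed (hit) target trials, the
# trial set on which tuning itself is defined; attention metrics need a
# saccade time for their per-trial window, which hits provide.
#
# Ratio denominators below 0.1 spikes/s leave the metric undefined (NA)
# rather than clipped -- a near-silent denominator makes the ratio
# meaningless, and silent drops are worse than flagged ones.

RATIO_EPS <- 0.1  # spikes/s

METRIC_COLS <- sprintf("metric_%02d", 1:19)

#' Trial-to-trial variability ("Fano factor")
#'
#' The convention used throughout this pipeline is the coefficient of
#' variation, SD/mean, of a response sample across trials; a config switch
#' selects the conventional variance/mean instead.
#'
#' @param x numeric sample of per-trial responses.
#' @param convention `"cv"` (SD/mean, default) or `"var_over_mean"`.
#' @return the variability index, or `NA` if the mean is below 0.1.
#' @export
fano_factor <- function(x, convention = c("cv", "var_over_mean")) {
  convention <- match.arg(convention)
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m < RATIO_EPS) return(NA_real_)
  if (convention == "cv") stats::sd(x) / m else stats::var(x) / m
}

safe_ratio <- function(num, den) {
  if (is.na(num) || is.na(den) || den < RATIO_EPS) NA_real_ else num / den
}

# peak (value, time) of the column-mean of an SDF matrix; NA when no trials
avg_peak <- function(m, grid) {
  if (is.null(m) || nrow(m) == 0) return(c(NA_real_, NA_real_))
  avg <- colMeans(m)
  i <- which.max(avg)  # earliest tie wins
  c(avg[i], grid[i])
}

#' Visual-epoch metrics (1-11) for one neuron
#'
#' 1 baseline rate `[-200, 0)` ms; 2 peak of the trial-averaged SDF in
#' `[0, 200)` ms post-cue, cue in the preferred quadrant; 3 its time re cue
#' onset; 4 variability (SD/mean) of per-trial SDF values read at that
#' trial-averaged peak time; 5 ratio of peak cue response (target in RF)
#' over peak distractor response (distractor in RF); 6 the peak
#' distractor-elicited response; 7 its latency re distractor-array onset;
#' 8 variability of per-trial peaks with the peak time found per trial;
#' 9 ratio of peak response, cue preferred over cue anti-preferred; 10 the
#' anti-preferred peak; 11 its latency.
#'
#' @param session a `session_record`.
#' @param neuron neuron id.
#' @param tuning one row of the cue-epoch selectivity table.
#' @param sigma_ms SDF kernel SD (default 30).
#' @param fano_convention passed to [fano_factor()].
#' @return named numeric vector `metric_01` ... `metric_11`.
#' @export
visual_metrics <- function(session, neuron, tuning, sigma_ms = 30,
                           fano_convention = "cv") {
  out <- stats::setNames(rep(NA_real_, 11), METRIC_COLS[1:11])
  pref <- tuning$preferred_quadrant
  anti <- tuning$anti_preferred_quadrant
  if (is.na(pref) || is.na(anti)) return(out)
  tr <- session$trials
  tr <- tr[tr$trial_type == "target" & tr$outcome == "hit", ]
  if (nrow(tr) == 0) return(out)
  spt <- neuron_spikes_by_trial(session, neuron)
  grid_cue <- 0:199
  grid_dis <- CUE_MS + 0:199  # distractor array onset = cue offset (363 ms)

  # (1) baseline
  base_counts <- vapply(tr$trial_index, function(i) {
    sp <- spt[[as.character(i)]]
    if (is.null(sp)) 0L else sum(sp >= -200 & sp < 0)
  }, integer(1))
  out["metric_01"] <- mean(base_counts) / 0.2

  id_p <- tr$trial_index[tr$cue_quadrant == pref]
  id_a <- tr$trial_index[tr$cue_quadrant == anti]
  id_d <- tr$trial_index[tr$cue_quadrant != pref]  # distractor in RF

  if (length(id_p) > 0) {
    m_p <- sdf_matrix(spt, id_p, grid_cue, sigma_ms)
    pk <- avg_peak(m_p, grid_cue)
    out["metric_02"] <- pk[1]
    out["metric_03"] <- pk[2]
    at_peak <- m_p[, which.max(colMeans(m_p))]
    out["metric_04"] <- fano_factor(at_peak, fano_convention)
    out["metric_08"] <- fano_factor(apply(m_p, 1, max), fano_convention)
  }
  if (length(id_d) > 0) {
    m_d <- sdf_matrix(spt, id_d, grid_dis, sigma_ms)
    pk <- avg_peak(m_d, grid_dis)
    out["metric_06"] <- pk[1]
    out["metric_07"] <- pk[2] - CUE_MS
  }
  out["metric_05"] <- safe_ratio(out[["metric_02"]], out[["metric_06"]])
  if (length(id_a) > 0) {
    m_a <- sdf_matrix(spt, id_a, grid_cue, sigma_ms)
    pk <- avg_peak(m_a, grid_cue)
    out["metric_10"] <- pk[1]
    out["metric_11"] <- pk[2]
  }
  out["metric_09"] <- safe_ratio(out[["metric_02"]], out[["metric_10"]])
  out
}

# per-trial sustained-attention rates: 400 ms window centered midway
# between cue offset and saccade onset, spikes/s
attention_window_rates <- function(spt, trials) {
  mid <- (trials$cue_off + trials$saccade_time) / 2
  lo <- mid - 200
  hi <- mid + 200
  vapply(seq_len(nrow(trials)), function(i) {
    sp <- spt[[as.character(trials$trial_index[i])]]
    if (is.null(sp)) 0 else sum(sp >= lo[i] & sp < hi[i]) / 0.4
  }, numeric(1))
}

#' Attention-epoch metrics (12-15) for one neuron
#'
#' Sustained response in a 400 ms window centered midway between cue
#' offset and saccade onset (per trial): 12 with attention in the RF
#' (preferred quadrant), 13 in the anti-preferred quadrant, 14 their
#' ratio, 15 the variability (SD/mean) of the per-trial values in 12.
#'
#' @inheritParams visual_metrics
#' @param tuning one row of the attention-epoch selectivity table.
#' @return named numeric vector `metric_12` ... `metric_15`.
#' @export
attention_metrics <- function(session, neuron, tuning, sigma_ms = 30,
                              fano_convention = "cv") {
  out <- stats::setNames(rep(NA_real_, 4), METRIC_COLS[12:15])
  pref <- tuning$preferred_quadrant
  anti <- tuning$anti_preferred_quadrant
  if (is.na(pref) || is.na(anti)) return(out)
  tr <- session$trials
  tr <- tr[tr$trial_type == "target" & tr$outcome == "hit" &
             !is.na(tr$saccade_time), ]
  if (nrow(tr) == 0) return(out)
  spt <- neuron_spikes_by_trial(session, neuron)
  tr_p <- tr[tr$cue_quadrant == pref, ]
  tr_a <- tr[tr$cue_quadrant == anti, ]
  if (nrow(tr_p) > 0) {
    r_p <- attention_window_rates(spt, tr_p)
    out["metric_12"] <- mean(r_p)
    out["metric_15"] <- fano_factor(r_p, fano_convention)
  }
  if (nrow(tr_a) > 0) out["metric_13"] <- mean(attention_window_rates(spt, tr_a))
  out["metric_14"] <- safe_ratio(out[["metric_12"]], out[["metric_13"]])
  out
}

#' Saccade-epoch metrics (16-19) for one neuron
#'
#' Saccade-aligned SDF peaks in `[-50, +50)` ms around saccade onset:
#' 16 saccade toward the preferred quadrant, 17 toward the anti-preferred,
#' 18 their ratio, 19 the variability of per-trial peaks toward the
#' preferred quadrant.  Trials without a saccade contribute nothing.
#'
#' @inheritParams visual_metrics
#' @param tuning one row of the saccade-epoch selectivity table.
#' @return named numeric vector `metric_16` ... `metric_19`.
#' @export
saccade_metrics <- function(session, neuron, tuning, sigma_ms = 30,
                            fano_convention = "cv") {
  out <- stats::setNames(rep(NA_real_, 4), METRIC_COLS[16:19])
  pref <- tuning$preferred_quadrant
  anti <- tuning$anti_preferred_quadrant
  if (is.na(pref) || is.na(anti)) return(out)
  tr <- session$trials
  tr <- tr[tr$trial_type == "target" & tr$outcome == "hit" &
             !is.na(tr$saccade_time), ]
  if (nrow(tr) == 0) return(out)
  spt <- neuron_spikes_by_trial(session, neuron)
  grid <- -50:49
  sacc_sdf <- function(rows) {
    m <- matrix(0, nrow(rows), length(grid))
    for (i in seq_len(nrow(rows))) {
      sp <- spt[[as.character(rows$trial_index[i])]]
      if (!is.null(sp) && length(sp) > 0)
        m[i, ] <- spike_density(sp - rows$saccade_time[i], grid, sigma_ms)$rate
    }
    m
  }
  # on hit target trials the saccade endpoint is the cue quadrant
  tr_p <- tr[tr$cue_quadrant == pref, ]
  tr_a <- tr[tr$cue_quadrant == anti, ]
  if (nrow(tr_p) > 0) {
    m_p <- sacc_sdf(tr_p)
    pk <- avg_peak(m_p, grid)
    out["metric_16"] <- pk[1]
    out["metric_19"] <- fano_factor(apply(m_p, 1, max), fano_convention)
  }
  if (nrow(tr_a) > 0) out["metric_17"] <- avg_peak(sacc_sdf(tr_a), grid)[1]
  out["metric_18"] <- safe_ratio(out[["metric_16"]], out[["metric_17"]])
  out
}

#' Metric table for every neuron of a session
#'
#' Applies the eligibility mask: visual metrics only for cue-epoch
#' selective neurons, attention metrics only for attention-selective,
#' saccade metrics only for saccade-selective.
#'
#' @param session a `session_record`.
#' @param selectivity output of [session_selectivity()] (computed if
#'   omitted).
#' @param sigma_ms SDF kernel SD.
#' @param fano_convention passed to [fano_factor()].
#' @return data.frame: `neuron_id`, `visual_selective`,
#'   `attention_selective`, `saccade_selective`, `metric_01` ...
#'   `metric_19`.
#' @export
compute_metrics <- function(session, selectivity = NULL, sigma_ms = 30,
                            fano_convention = "cv") {
  if (is.null(selectivity)) selectivity <- session_selectivity(session)
  neurons <- session$electrode_map$neuron_id
  rows <- vector("list", length(neurons))
  for (j in seq_along(neurons)) {
    nid <- neurons[j]
    sel_v <- selectivity$cue[selectivity$cue$neuron_id == nid, ]
    sel_a <- selectivity$attention[selectivity$attention$neuron_id == nid, ]
    sel_s <- selectivity$saccade[selectivity$saccade$neuron_id == nid, ]
    vals <- stats::setNames(rep(NA_real_, 19), METRIC_COLS)
    if (nrow(sel_v) == 1 && isTRUE(sel_v$selective))
      vals[1:11] <- visual_metrics(session, nid, sel_v, sigma_ms,
                                   fano_convention)
    if (nrow(sel_a) == 1 && isTRUE(sel_a$selective))
      vals[12:15] <- attention_metrics(session, nid, sel_a, sigma_ms,
                                       fano_convention)
    if (nrow(sel_s) == 1 && isTRUE(sel_s$selective))
      vals[16:19] <- saccade_metrics(session, nid, sel_s, sigma_ms,
                                     fano_convention)
    rows[[j]] <- data.frame(
      neuron_id = nid,
      visual_selective = nrow(sel_v) == 1 && isTRUE(sel_v$selective),
      attention_selective = nrow(sel_a) == 1 && isTRUE(sel_a$selective),
      saccade_selective = nrow(sel_s) == 1 && isTRUE(sel_s$selective),
      as.list(vals),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-metric dose-effect scan
#'
#' One-way ANOVA with treatment (placebo plus each dose) as the factor,
#' per metric per subject, never pooling subjects.  The Bonferroni family
#' is the declared grid of metrics x subjects (38 for 19 metrics and 2
#' subjects) regardless of how many tests could actually be run; skipped
#' tests (fewer than 2 eligible neurons in 2 or more groups) are reported
#' with their reason.
#'
#' @param metric_tables data.frame of stacked [compute_metrics()] outputs
#'   with added `subject` and `label` (treatment) columns.
#' @param alpha family-wise error rate (default 0.05).
#' @param metrics metric column names (default all 19).
#' @return list with `tests` (subject, metric, F, p_uncorrected,
#'   p_bonferroni, eta_sq, significant, skipped, reason, m), `group_stats`
#'   (per subject x metric x treatment mean, SEM, n) and `m` (family size).
#' @export
dose_effect_scan <- function(metric_tables, alpha = 0.05,
                             metrics = METRIC_COLS) {
  stopifnot(all(c("subject", "label") %in% names(metric_tables)))
  subjects <- unique(metric_tables$subject)
  m <- length(metrics) * length(subjects)
  tests <- list()
  gstats <- list()
  for (s in subjects) {
    d_s <- metric_tables[metric_tables$subject == s, ]
    for (mc in metrics) {
      vals <- d_s[[mc]]
      ok <- !is.na(vals)
      groups <- split(vals[ok], d_s$label[ok])
      if (length(groups) > 0) {
        gstats[[length(gstats) + 1]] <- data.frame(
          subject = s, metric = mc,
          label = names(groups),
          mean = vapply(groups, mean, numeric(1)),
          sem = vapply(groups, function(x)
            if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
            numeric(1)),
          n = lengths(groups),
          stringsAsFactors = FALSE
        )
      }
      groups <- groups[lengths(groups) >= 2]
      row <- data.frame(subject = s, metric = mc, n_groups = length(groups),
                        F = NA_real_, p_uncorrected = NA_real_,
                        p_bonferroni = NA_real_, eta_sq = NA_real_,
                        significant = FALSE, skipped = FALSE,
                        reason = NA_character_, stringsAsFactors = FALSE)
      if (length(groups) < 2) {
        row$skipped <- TRUE
        row$reason <- "fewer than 2 treatment groups with >= 2 eligible neurons"
      } else {
        t <- one_way_anova(groups)
        row$F <- t$statistic
        row$p_uncorrected <- t$p
        row$p_bonferroni <- min(1, t$p * m)
        row$eta_sq <- t$eta_sq
        row$significant <- bonferroni(t$p, alpha, m)
        if (t$degenerate) row$reason <- "degenerate ANOVA"
      }
      tests[[length(tests) + 1]] <- row
    }
  }
  list(tests = do.call(rbind, tests),
       group_stats = do.call(rbind, gstats),
       m = m)
}
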