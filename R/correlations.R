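# Pairwise trial-to-trial (noise) and tuning (signal) correlations.
#
# Noise correlations: spike counts in the epoch window are z-scored within
# each cue-quadrant condition (removing the condition mean and SD), pooled
# across conditions, and Pearson-correlated per pair.  Pairs recorded on
# the same electrode are excluded (spike-sorting artifacts inflate those),
# as are neurons with zero count variance in any included condition.
# Signal correlations: Pearson correlation of the two neurons' 4-point
# condition-mean tuning vectors.

#' Signal-correlation matrix of an epoch count matrix
#'
#' @param counts a `count_matrix` (target-only trials); all four cue
#'   quadrants must be represented.
#' @return neurons x neurons matrix of tuning-vector correlations; `NA`
#'   for pairs involving a flat-tuned (zero-variance) neuron.
#' @export
signal_correlations <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  quad <- factor(counts$conditions, levels = 1:4)
  if (any(table(quad) == 0))
    stop("signal_correlations(): all 4 conditions must be present")
  tune <- apply(counts$counts, 2, function(x) tapply(x, quad, mean))
  flat <- apply(tune, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(tune))
  r[flat, ] <- NA_real_
  r[, flat] <- NA_real_
  r
}

#' Pairwise noise (and signal) correlations for one session and epoch
#'
#' @param session a `session_record`.
#' @param epoch an [epoch_window()].
#' @param selectivity output of [session_selectivity()]; computed if
#'   omitted.  Used for the `both_selective` flag (visual tuning
#'   substitutes for the baseline epoch).
#' @param min_trials minimum trials per cue-quadrant condition; conditions
#'   below it are dropped (correlation-estimator stability).
#' @param trial_types trial types entering the computation (default
#'   target-only, matching the selectivity computation).
#' @return data.frame of pair records: `session_index`, `label`, `epoch`,
#'   `neuron_i`, `neuron_j`, `electrode_i`, `electrode_j`, `noise_r`,
#'   `signal_r`, `both_selective`; attribute `"log"` lists dropped
#'   conditions and excluded neurons.
#' @export
noise_correlations <- function(session, epoch, selectivity = NULL,
                               min_trials = 10, trial_types = "target") {
  cm <- extract_counts(session, epoch, trial_types = trial_types)
  log <- character(0)
  quad <- cm$conditions
  keep_cond <- names(which(table(factor(quad, levels = 1:4)) >= min_trials))
  if (length(keep_cond) < length(unique(quad)))
    log <- c(log, sprintf("COND_DROPPED: conditions with < %d trials: %s",
                          min_trials,
                          paste(setdiff(as.character(unique(quad)), keep_cond),
                                collapse = ",")))
  keep <- as.character(quad) %in% keep_cond
  x <- cm$counts[keep, , drop = FALSE]
  q <- quad[keep]
  neurons <- colnames(x)

  # z-score within condition, then pool
  z <- x * NA_real_
  bad <- rep(FALSE, ncol(x))
  for (cond in unique(q)) {
    rows <- q == cond
    mu <- colMeans(x[rows, , drop = FALSE])
    s <- apply(x[rows, , drop = FALSE], 2, stats::sd)
    bad <- bad | s == 0 | !is.finite(s)
    s[s == 0 | !is.finite(s)] <- 1
    z[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, mu), 2, s, "/")
  }
  if (any(bad))
    log <- c(log, sprintf("NEURON_EXCLUDED_ZERO_VAR: %s",
                          paste(neurons[bad], collapse = ",")))
  r_noise <- if (nrow(z) >= 3) suppressWarnings(stats::cor(z)) else
    matrix(NA_real_, ncol(z), ncol(z), dimnames = list(neurons, neurons))
  r_noise[bad, ] <- NA_real_
  r_noise[, bad] <- NA_real_

  # signal correlations need all 4 conditions; NA matrix when impossible
  r_signal <- tryCatch(signal_correlations(cm), error = function(e) {
    log <<- c(log, paste0("SIGNAL_R_UNAVAILABLE: ", conditionMessage(e)))
    matrix(NA_real_, length(neurons), length(neurons),
           dimnames = list(neurons, neurons))
  })

  if (is.null(selectivity)) selectivity <- session_selectivity(session)
  sel_tab <- selectivity[[epoch$name]]
  if (is.null(sel_tab)) sel_tab <- selectivity$cue
  sel_flag <- stats::setNames(rep(FALSE, length(neurons)), neurons)
  sel_flag[sel_tab$neuron_id[sel_tab$selective]] <- TRUE

  emap <- stats::setNames(session$electrode_map$electrode_id,
                          session$electrode_map$neuron_id)
  idx <- which(upper.tri(r_noise), arr.ind = TRUE)
  out <- data.frame(
    session_index = session$session_index,
    label = session$label,
    epoch = epoch$name,
    neuron_i = neurons[idx[, 1]],
    neuron_j = neurons[idx[, 2]],
    electrode_i = unname(emap[neurons[idx[, 1]]]),
    electrode_j = unname(emap[neurons[idx[, 2]]]),
    noise_r = r_noise[idx],
    signal_r = r_signal[idx],
    both_selective = unname(sel_flag[neurons[idx[, 1]]] &
                              sel_flag[neurons[idx[, 2]]]),
    stringsAsFactors = FALSE
  )
  same_el <- out$electrode_i == out$electrode_j
  out <- out[!same_el & !is.na(out$noise_r), ]
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Sign-split medians and percent change from flanking placebo
#'
#' Medians are reported separately for the positive-coefficient and the
#' negative-coefficient sub-populations (pairs with r exactly 0 belong to
#' neither).  When a schedule is supplied, the placebo reference pool for
#' each dose is its flanking placebo sessions; otherwise all placebo pairs
#' form the pool.
#'
#' @param pairs stacked [noise_correlations()] output (one treatment pool
#'   per `label`, sessions identified by `session_index`).
#' @param schedule optional [build_schedule()] data.frame for the flanking
#'   placebo mapping.
#' @return data.frame per treatment label: pair counts, medians per sign,
#'   and percent change from the (flanking) placebo medians.
#' @export
sign_split_summary <- function(pairs, schedule = NULL) {
  med <- function(x) if (length(x) > 0) stats::median(x) else NA_real_
  summarize_pool <- function(p) {
    pos <- p$noise_r[p$noise_r > 0]
    neg <- p$noise_r[p$noise_r < 0]
    list(n_pos = length(pos), n_neg = length(neg),
         median_pos = med(pos), median_neg = med(neg))
  }
  pct <- function(dose, pb) {
    if (is.na(dose) || is.na(pb) || pb == 0) NA_real_
    else 100 * (dose - pb) / abs(pb)
  }
  labels <- unique(pairs$label)
  doses <- setdiff(labels, "placebo")
  rows <- list()
  pb_all <- summarize_pool(pairs[pairs$label == "placebo", ])
  rows[["placebo"]] <- data.frame(
    label = "placebo", n_pos = pb_all$n_pos, n_neg = pb_all$n_neg,
    median_pos = pb_all$median_pos, median_neg = pb_all$median_neg,
    pct_change_pos = 0, pct_change_neg = 0, stringsAsFactors = FALSE)
  for (d in doses) {
    s_d <- summarize_pool(pairs[pairs$label == d, ])
    pb <- pb_all
    if (!is.null(schedule)) {
      di <- unique(schedule$dose_index[schedule$label == d])
      fl <- flanking_sessions(schedule, di[1])
      pb <- summarize_pool(pairs[pairs$session_index %in% fl, ])
    }
    rows[[d]] <- data.frame(
      label = d, n_pos = s_d$n_pos, n_neg = s_d$n_neg,
      median_pos = s_d$median_pos, median_neg = s_d$median_neg,
      pct_change_pos = pct(s_d$median_pos, pb$median_pos),
      pct_change_neg = pct(s_d$median_neg, pb$median_neg),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noise-correlation structure over signal-correlation bins
#'
#' Bins pairs into the 10 signal-correlation intervals `[-1,-0.8)`, ...,
#' `[0.8,1]`, reports the mean noise correlation (+/- SEM) per bin, a
#' monotone-trend statistic (Spearman correlation of bin index vs mean
#' noise r over non-empty bins), and -- when more than one treatment label
#' is present -- a per-bin one-way dose ANOVA with eta squared.
#'
#' @param pairs stacked [noise_correlations()] output; pairs with
#'   undefined `signal_r` are excluded.
#' @return list with `curve` (bin, bounds, n, mean_noise_r, sem),
#'   `trend_spearman`, and `anova` (per-bin F, p, eta_sq; `NULL` with a
#'   single treatment group).
#' @export
correlation_structure <- function(pairs) {
  p <- pairs[!is.na(pairs$signal_r) & !is.na(pairs$noise_r), ]
  breaks <- seq(-1, 1, by = 0.2)
  bin <- cut(p$signal_r, breaks = breaks, right = FALSE,
             include.lowest = TRUE)
  lv <- levels(bin)
  curve <- data.frame(
    bin = seq_along(lv),
    lo = breaks[-length(breaks)], hi = breaks[-1],
    n = as.integer(table(bin)),
    mean_noise_r = as.numeric(tapply(p$noise_r, bin, mean)),
    sem = as.numeric(tapply(p$noise_r, bin, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)),
    stringsAsFactors = FALSE
  )
  nonempty <- curve$n > 0
  trend <- if (sum(nonempty) >= 3)
    stats::cor(curve$bin[nonempty], curve$mean_noise_r[nonempty],
               method = "spearman") else NA_real_
  anova_rows <- NULL
  if (length(unique(p$label)) > 1) {
    anova_rows <- list()
    for (b in seq_along(lv)) {
      pb <- p[as.integer(bin) == b, ]
      groups <- split(pb$noise_r, pb$label)
      groups <- groups[lengths(groups) >= 2]
      row <- data.frame(bin = b, F = NA_real_, p = NA_real_,
                        eta_sq = NA_real_, n = nrow(pb))
      if (length(groups) >= 2) {
        t <- one_way_anova(groups)
        row$F <- t$statistic
        row$p <- t$p
        row$eta_sq <- t$eta_sq
      }
      anova_rows[[b]] <- row
    }
    anova_rows <- do.call(rbind, anova_rows)
  }
  list(curve = curve, trend_spearman = trend, anova = anova_rows)
}
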