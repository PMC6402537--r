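# Session-level behavioral summaries and dose-vs-placebo comparisons.
# Hit rate is Hits / (Hits + Misses) with "misses" meaning all non-hit
# outcomes (every error type counts against the hit rate); per-category
# error rates are reported separately.

#' Summarize trial outcomes of a pooled trial set
#'
#' @param trials data.frame of trial records (possibly pooled over the
#'   sessions of a treatment block).
#' @param hit_rate_denominator `"all"` (default: hits over all trials) or
#'   `"responded"` (no-response trials excluded from the denominator).
#' @return list with `n_trials`, per-outcome counts, `hit_rate`, and the
#'   standard error of each proportion (`se_*`).
#' @export
summarize_behavior <- function(trials, hit_rate_denominator = c("all", "responded")) {
  hit_rate_denominator <- match.arg(hit_rate_denominator)
  stopifnot(nrow(trials) >= 1)
  n <- nrow(trials)
  cnt <- vapply(OUTCOMES, function(o) sum(trials$outcome == o), integer(1))
  stopifnot(sum(cnt) == n)  # outcome conservation
  denom <- if (hit_rate_denominator == "all") n else n - cnt[["no_response"]]
  hit_rate <- if (denom > 0) cnt[["hit"]] / denom else NA_real_
  se <- function(p, n) if (n > 0) sqrt(p * (1 - p) / n) else NA_real_
  rates <- cnt / n
  out <- list(n_trials = n,
              hits = cnt[["hit"]],
              fixation_breaks = cnt[["fixation_break"]],
              saccades_to_distractor = cnt[["saccade_to_distractor"]],
              no_responses = cnt[["no_response"]],
              hit_rate = hit_rate,
              se_hit_rate = se(hit_rate, denom))
  for (o in OUTCOMES) {
    out[[paste0("rate_", o)]] <- rates[[o]]
    out[[paste0("se_", o)]] <- se(rates[[o]], n)
  }
  out
}

#' Compare a dose pool against its flanking placebo pool
#'
#' Pearson chi-square difference-in-proportions tests (no continuity
#' correction) for the hit rate and for each error category.
#'
#' @param dose_trials,placebo_trials trial data.frames pooled over the
#'   dose block and its flanking placebo sessions.
#' @param hit_rate_denominator passed to [summarize_behavior()].
#' @return data.frame with one row per outcome measure: proportions in
#'   each pool, their SEs, chi-square, df, p.
#' @export
compare_to_matched_placebo <- function(dose_trials, placebo_trials,
                                       hit_rate_denominator = "all") {
  stopifnot(nrow(dose_trials) >= 1, nrow(placebo_trials) >= 1)
  a <- summarize_behavior(dose_trials, hit_rate_denominator)
  b <- summarize_behavior(placebo_trials, hit_rate_denominator)
  measures <- c(hit_rate = "hit", fixation_break = "fixation_break",
                saccade_to_distractor = "saccade_to_distractor",
                no_response = "no_response")
  rows <- list()
  for (i in seq_along(measures)) {
    nm <- names(measures)[i]
    o <- measures[[i]]
    if (nm == "hit_rate") {
      na <- if (hit_rate_denominator == "all") a$n_trials else
        a$n_trials - a$no_responses
      nb <- if (hit_rate_denominator == "all") b$n_trials else
        b$n_trials - b$no_responses
      ka <- a$hits
      kb <- b$hits
    } else {
      na <- a$n_trials
      nb <- b$n_trials
      ka <- sum(dose_trials$outcome == o)
      kb <- sum(placebo_trials$outcome == o)
    }
    t <- chi_square_proportions(ka, na, kb, nb)
    rows[[nm]] <- data.frame(
      measure = nm, p_dose = t$p_a, se_dose = t$se_a,
      p_placebo = t$p_b, se_placebo = t$se_b,
      diff = t$p_a - t$p_b, chi_sq = t$statistic, df = t$df, p = t$p,
      degenerate = t$degenerate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Error taxonomy: impulsivity- and distractibility-type rates
#'
#' Fixation breaks (responding before the Go signal) index impulsivity;
#' saccades to a distractor index distractibility.  Rates are proportions
#' of all trials, with binomial SEs.
#'
#' @param trials trial data.frame.
#' @return data.frame with one row per error category: `rate`, `se`, `n`.
#' @export
error_taxonomy <- function(trials) {
  n <- nrow(trials)
  cats <- c(impulsivity = "fixation_break",
            distractibility = "saccade_to_distractor",
            no_response = "no_response")
  out <- data.frame(
    category = names(cats),
    outcome = unname(cats),
    rate = vapply(cats, function(o)
      if (n > 0) mean(trials$outcome == o) else 0, numeric(1)),
    n = n,
    stringsAsFactors = FALSE
  )
  out$se <- ifelse(n > 0, sqrt(out$rate * (1 - out$rate) / n), NA_real_)
  rownames(out) <- NULL
  out
}
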