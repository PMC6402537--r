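# Per-epoch tuning classification.  A neuron is "selective" for an epoch
# when a Kruskal-Wallis test on its per-trial firing rate across the four
# cue quadrants (target-only trials) is significant at p < 0.01; the
# preferred quadrant is the one with the highest mean epoch rate, the
# anti-preferred the lowest.

#' Classify quadrant selectivity of every neuron in an epoch
#'
#' @param counts a `count_matrix` from [extract_counts()], computed on
#'   target-only trials for the epoch of interest.
#' @param alpha significance level for the selectivity call (default 0.01).
#' @return data.frame with one row per neuron: `neuron_id`, `epoch`, `H`,
#'   `p`, `selective`, `preferred_quadrant`, `anti_preferred_quadrant`,
#'   `excluded`, `reason`.  Neurons with fewer than 2 trials in any
#'   quadrant, fewer than 4 quadrants represented, or all-identical counts
#'   are excluded (or flagged degenerate) with the reason recorded.
#' @export
classify_selectivity <- function(counts, alpha = 0.01) {
  stopifnot(inherits(counts, "count_matrix"))
  quad <- counts$conditions
  neurons <- colnames(counts$counts)
  res <- vector("list", length(neurons))
  dur <- counts$duration_s
  tab <- table(factor(quad, levels = 1:4))
  for (j in seq_along(neurons)) {
    row <- list(neuron_id = neurons[j], epoch = counts$epoch$name,
                H = NA_real_, p = NA_real_, selective = FALSE,
                preferred_quadrant = NA_integer_,
                anti_preferred_quadrant = NA_integer_,
                excluded = FALSE, reason = NA_character_)
    if (any(tab == 0)) {
      row$excluded <- TRUE
      row$reason <- "fewer than 4 quadrants represented"
    } else if (any(tab < 2)) {
      row$excluded <- TRUE
      row$reason <- "fewer than 2 trials in some quadrant"
    } else {
      rates <- counts$counts[, j] / dur
      groups <- split(rates, quad)
      kw <- kruskal_wallis(groups)
      row$H <- kw$statistic
      row$p <- kw$p
      means <- vapply(groups, mean, numeric(1))
      # ties broken by lowest quadrant index (which.max/min convention)
      row$preferred_quadrant <- as.integer(names(means)[which.max(means)])
      row$anti_preferred_quadrant <- as.integer(names(means)[which.min(means)])
      if (kw$degenerate) {
        row$selective <- FALSE
        row$reason <- "degenerate (identical counts across trials)"
        row$preferred_quadrant <- NA_integer_
        row$anti_preferred_quadrant <- NA_integer_
      } else {
        row$selective <- kw$p < alpha
        if (row$preferred_quadrant == row$anti_preferred_quadrant) {
          # constant means: no orderable tuning
          row$preferred_quadrant <- NA_integer_
          row$anti_preferred_quadrant <- NA_integer_
          row$selective <- FALSE
          row$reason <- "flat tuning"
        }
      }
    }
    res[[j]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Selectivity tables for all canonical epochs of a session
#'
#' Runs [classify_selectivity()] on target-only trials for the cue,
#' attention and saccade epochs.  Baseline-epoch analyses that require a
#' tuning assignment reuse the visual (cue-epoch) tuning, since no tuning
#' is measurable before stimulus onset; the returned list therefore maps
#' `baseline` to the cue-epoch table.
#'
#' @param session a `session_record`.
#' @param alpha significance level (default 0.01).
#' @param epochs epoch set, default [canonical_epochs()].
#' @return named list of selectivity data.frames
#'   (`baseline`, `cue`, `attention`, `saccade`).
#' @export
session_selectivity <- function(session, alpha = 0.01,
                                epochs = canonical_epochs()) {
  sel <- list()
  for (nm in c("cue", "attention", "saccade")) {
    cm <- extract_counts(session, epochs[[nm]], trial_types = "target")
    sel[[nm]] <- classify_selectivity(cm, alpha)
  }
  sel$baseline <- sel$cue  # visual tuning substitutes for baseline epoch
  sel
}
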