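# Cross-validated ensemble decoding of task variables from simultaneous
# spike counts, with label-permutation nulls and flanking-placebo
# comparisons.  The decoder is a linear maximum-margin classifier
# (one-vs-rest hinge-loss SVM, see src/svm_linear.cpp) with fixed
# regularization C = 1; features are standardized per fold using training
# statistics only.

#' Train the linear maximum-margin classifier (one-vs-rest)
#'
#' @param x numeric feature matrix (trials x features), already scaled.
#' @param y integer class labels in `1..n_classes`.
#' @param n_classes number of classes.
#' @param C regularization strength (upper bound on the dual variables).
#' @param max_passes maximum coordinate-descent passes.
#' @return weight matrix `(features + 1) x n_classes` (last row = bias).
#' @keywords internal
svm_train <- function(x, y, n_classes = max(y), C = 1, max_passes = 60) {
  xb <- cbind(x, 1)
  .svm_ovr_train(t(xb), as.integer(y), as.integer(n_classes), C,
                 as.integer(max_passes), 1e-3)
}

svm_predict <- function(w, x) {
  scores <- cbind(x, 1) %*% w
  max.col(scores, ties.method = "first")
}

#' Cross-validated decoding of a labeled count matrix
#'
#' Stratified k-fold cross-validation (default 4/5 train, 1/5 test):
#' within each class, trials are shuffled (seeded) and dealt round-robin
#' into folds, so fold assignment is label-stratified and reproducible.
#' Features are standardized per fold with training-set statistics;
#' accuracy is the mean of the fold accuracies.
#'
#' @param counts numeric matrix (trials x neurons) or a `count_matrix`.
#' @param labels integer class label per trial (e.g. quadrant 1..4).
#' @param folds number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param C classifier regularization (default 1).
#' @return A `decode_result`: list with `accuracy`, `fold_accuracies`,
#'   `n_trials`, `n_neurons`, `folds`.
#' @export
decode_epoch <- function(counts, labels, folds = 5, seed = 1L, C = 1) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  tab <- table(labels)
  small <- names(tab)[tab < folds]
  if (length(small) > 0)
    stop("decode_epoch(): class ", paste(small, collapse = ","),
         " has fewer trials than folds (", folds, ")")
  y <- match(labels, classes)

  set.seed(seed)
  fold <- integer(nrow(x))
  for (k in seq_along(classes)) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }

  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    s <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    xs_tr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, s, "/")
    xs_te <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, s, "/")
    w <- svm_train(xs_tr, y[tr], n_classes = length(classes), C = C)
    acc[f] <- mean(svm_predict(w, xs_te) == y[!tr])
  }
  structure(
    list(accuracy = mean(acc), fold_accuracies = acc,
         n_trials = nrow(x), n_neurons = ncol(x), folds = folds),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: accuracy %.1f%% over %d folds (%d trials, %d neurons)\n",
              100 * x$accuracy, x$folds, x$n_trials, x$n_neurons))
  invisible(x)
}

#' Label-permutation null distribution for decoding accuracy
#'
#' Trial labels are permuted before training on every iteration and the
#' full cross-validation is re-run, giving the distribution of accuracies
#' achievable with no label information.  The empirical p value uses the
#' +1 correction, `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so it
#' is never exactly 0.
#'
#' @inheritParams decode_epoch
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param observed optional precomputed `decode_result` for the unpermuted
#'   labels (computed if omitted).
#' @return list with `observed` (accuracy), `null_accuracies`, `null_mean`,
#'   `null_q95`, `n_perm`, `p`.
#' @export
permutation_null <- function(counts, labels, n_perm = 1000, seed = 1L,
                             folds = 5, C = 1, observed = NULL) {
  if (n_perm < 100)
    warning("permutation_null(): n_perm < 100 gives a coarse null")
  if (is.null(observed))
    observed <- decode_epoch(counts, labels, folds = folds, seed = seed, C = C)
  obs <- if (inherits(observed, "decode_result")) observed$accuracy
         else observed
  null_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 1000L + b))
    perm <- sample(labels)
    null_acc[b] <- decode_epoch(counts, perm, folds = folds,
                                seed = derive_seed(seed, 2000L + b),
                                C = C)$accuracy
  }
  list(observed = obs,
       null_accuracies = null_acc,
       null_mean = mean(null_acc),
       null_q95 = unname(stats::quantile(null_acc, 0.95)),
       n_perm = n_perm,
       p = (1 + sum(null_acc >= obs)) / (n_perm + 1))
}

#' Decode one task variable from one session and epoch
#'
#' The decoded label is the cue quadrant for the baseline/cue epochs, the
#' attended (target) quadrant for the attention epoch, and the saccade
#' endpoint quadrant for the saccade epoch.  By default only hit trials
#' enter (configurable; error trials carry ambiguous attentional labels).
#'
#' @param session a `session_record`.
#' @param epoch an [epoch_window()].
#' @param hit_only restrict to hit trials (default `TRUE`).
#' @inheritParams decode_epoch
#' @return a `decode_result` (see [decode_epoch()]).
#' @export
decode_session <- function(session, epoch, folds = 5, seed = 1L, C = 1,
                           hit_only = TRUE) {
  outcomes <- if (hit_only || epoch$name == "saccade") "hit" else NULL
  # saccade decoding always uses hit trials: on hits the saccade endpoint
  # is the target (cue) quadrant, and trials without a saccade are dropped
  # by the alignment anyway
  cm <- extract_counts(session, epoch, outcomes = outcomes)
  labels <- cm$conditions
  decode_epoch(cm$counts, labels, folds = folds, seed = seed, C = C)
}

#' Decoding percent change from flanking placebo, with dose ANOVA
#'
#' For each dose the reference is the mean accuracy of its flanking
#' placebo sessions (recorded immediately before and after that dose's
#' block); percent change is `100 * (dose - flank) / flank`.  A one-way
#' ANOVA with treatment (placebo and each dose) as the factor is run per
#' epoch over per-session accuracies.
#'
#' @param results data.frame with columns `session_index`, `epoch`,
#'   `accuracy` (one row per session x epoch).
#' @param schedule the [build_schedule()] data.frame for these sessions.
#' @return list with `summary` (dose x epoch percent change; doses whose
#'   flanks are missing are flagged `incomplete`) and `anova` (per epoch).
#' @export
percent_change_from_flanking <- function(results, schedule) {
  stopifnot(all(c("session_index", "epoch", "accuracy") %in% names(results)))
  epochs <- unique(results$epoch)
  doses <- sort(unique(schedule$dose_index[schedule$dose_index > 0]))
  rows <- list()
  for (e in epochs) {
    r_e <- results[results$epoch == e, ]
    for (d in doses) {
      dose_sess <- schedule$session_index[schedule$dose_index == d]
      fl <- flanking_sessions(schedule, d)
      acc_d <- r_e$accuracy[r_e$session_index %in% dose_sess]
      acc_f <- r_e$accuracy[r_e$session_index %in% fl]
      incomplete <- length(acc_f) == 0 || length(acc_d) == 0
      rows[[length(rows) + 1]] <- data.frame(
        epoch = e, dose_index = d,
        label = paste0("dose_", d),
        mean_dose_accuracy = if (length(acc_d)) mean(acc_d) else NA_real_,
        mean_flank_accuracy = if (length(acc_f)) mean(acc_f) else NA_real_,
        pct_change = if (incomplete || mean(acc_f) == 0) NA_real_ else
          100 * (mean(acc_d) - mean(acc_f)) / mean(acc_f),
        incomplete = incomplete,
        stringsAsFactors = FALSE
      )
    }
  }
  anova_rows <- list()
  lab <- schedule$label[match(results$session_index, schedule$session_index)]
  for (e in epochs) {
    sel <- results$epoch == e
    groups <- split(results$accuracy[sel], lab[sel])
    groups <- groups[lengths(groups) >= 2]
    row <- data.frame(epoch = e, F = NA_real_, p = NA_real_,
                      eta_sq = NA_real_, stringsAsFactors = FALSE)
    if (length(groups) >= 2) {
      t <- one_way_anova(groups)
      row$F <- t$statistic
      row$p <- t$p
      row$eta_sq <- t$eta_sq
    }
    anova_rows[[e]] <- row
  }
  list(summary = do.call(rbind, rows),
       anova = do.call(rbind, anova_rows))
}
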