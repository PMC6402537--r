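# Epoching, spike counting, spike-density functions and normalization.
# Conventions fixed here and relied on everywhere else:
#   * all windows are half-open [start, end) on a 1-ms grid, which makes
#     spike-count additivity over disjoint windows exact;
#   * SDFs use a unit-area Gaussian kernel (SD 30 ms by default) truncated
#     at +/-5 SD with zero padding outside the trial, no edge
#     renormalization -- the resulting bias is confined to the outer
#     150 ms of a trial, outside every analysis window.

#' Epoch window definition
#'
#' @param name epoch name.
#' @param align alignment event: `"cue"` (cue onset), `"stimuli"`
#'   (distractor array onset) or `"saccade"` (saccade onset).
#' @param start,end window offsets in ms relative to the alignment event;
#'   half-open `[start, end)`; `end > start`.
#' @return An object of class `"epoch_window"`.
#' @export
epoch_window <- function(name, align = c("cue", "stimuli", "saccade"),
                         start, end) {
  align <- match.arg(align)
  stopifnot(end > start)
  structure(list(name = name, align = align, start = start, end = end),
            class = "epoch_window")
}

#' The canonical four-epoch set
#'
#' baseline `[-200, 0)` and cue `[0, 200)` ms relative to cue onset,
#' attention `[600, 1000)` ms relative to cue onset, saccade `[-50, +50)`
#' ms relative to saccade onset.
#'
#' @return named list of [epoch_window()]s.
#' @export
canonical_epochs <- function() {
  list(baseline = epoch_window("baseline", "cue", -200, 0),
       cue = epoch_window("cue", "cue", 0, 200),
       attention = epoch_window("attention", "cue", 600, 1000),
       saccade = epoch_window("saccade", "saccade", -50, 50))
}

#' Spike-density function
#'
#' Convolves a spike train with a unit-area Gaussian kernel, yielding an
#' instantaneous rate estimate in spikes/s evaluated on the supplied time
#' grid.  The kernel is truncated at +/-5 SD; spikes outside the grid but
#' within 5 SD of its edges still contribute (callers should pass spikes
#' with a margin around the window of interest).
#'
#' @param spike_times sorted spike times (ms).
#' @param grid evaluation grid (ms, uniform 1-ms step by convention).
#' @param sigma_ms kernel SD in ms (> 0); default 30.
#' @return A `rate_series`: list with `time` and `rate` (spikes/s).
#' @examples
#' s <- spike_density(50, seq(0, 100), sigma_ms = 30)
#' max(s$rate)  # ~ 1000 / (30 * sqrt(2 * pi)) = 13.30 spikes/s
#' @export
spike_density <- function(spike_times, grid, sigma_ms = 30) {
  if (sigma_ms <= 0) stop("spike_density(): sigma_ms must be > 0")
  if (is.unsorted(spike_times)) stop("spike_density(): spikes must be sorted")
  r <- numeric(length(grid))
  cut <- 5 * sigma_ms
  keep <- spike_times >= grid[1] - cut & spike_times <= grid[length(grid)] + cut
  for (ts in spike_times[keep]) {
    d <- grid - ts
    w <- abs(d) <= cut
    r[w] <- r[w] + stats::dnorm(d[w], 0, sigma_ms)
  }
  structure(list(time = grid, rate = 1000 * r), class = "rate_series")
}

# SDF matrix for a set of trials: rows = trials, cols = grid points.
# spikes_by_trial: list of numeric vectors keyed by as.character(trial_index)
sdf_matrix <- function(spikes_by_trial, trial_ids, grid, sigma_ms = 30) {
  m <- matrix(0, length(trial_ids), length(grid))
  for (i in seq_along(trial_ids)) {
    sp <- spikes_by_trial[[as.character(trial_ids[i])]]
    if (!is.null(sp) && length(sp) > 0)
      m[i, ] <- spike_density(sp, grid, sigma_ms)$rate
  }
  m
}

#' Average a set of rate series across trials
#'
#' @param series a list of `rate_series` on identical grids, or a numeric
#'   matrix (trials x time).
#' @return list with `time` (when available), `mean`, `sem`, `n`.
#' @export
trial_average <- function(series) {
  if (is.matrix(series)) {
    m <- series
    tm <- NULL
  } else {
    if (length(series) == 0) stop("trial_average(): no trials in condition")
    tm <- series[[1]]$time
    if (!all(vapply(series, function(s) identical(s$time, tm), logical(1))))
      stop("trial_average(): series are on different grids")
    m <- do.call(rbind, lapply(series, function(s) s$rate))
  }
  if (nrow(m) == 0) stop("trial_average(): no trials in condition")
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else rep(NA_real_, ncol(m))
  list(time = tm, mean = mu, sem = sem, n = n)
}

#' Z-score a trial-averaged rate series
#'
#' Standardizes a series to mean 0, SD 1 over the normalization window
#' (the full series by default).  A zero-variance series cannot be
#' normalized: `NULL` is returned with a warning and the caller is expected
#' to exclude the neuron from the population average.
#'
#' @param series a `rate_series`, or a numeric vector.
#' @param window optional logical/integer index into the series selecting
#'   the normalization window.
#' @return a `rate_series` of z values (or numeric vector if the input was
#'   one), or `NULL` for a constant series.
#' @export
zscore_series <- function(series, window = NULL) {
  x <- if (inherits(series, "rate_series")) series$rate else series
  w <- if (is.null(window)) x else x[window]
  s <- stats::sd(w)
  if (!is.finite(s) || s == 0) {
    warning("zscore_series(): zero variance, series excluded")
    return(NULL)
  }
  z <- (x - mean(w)) / s
  if (inherits(series, "rate_series"))
    structure(list(time = series$time, rate = z), class = "rate_series")
  else z
}

align_times <- function(trials, align) {
  switch(align,
         cue = trials$cue_on,
         stimuli = trials$stimuli_on,
         saccade = trials$saccade_time,
         stop("unknown alignment event: ", align))
}

#' Extract an epoch spike-count matrix from a session
#'
#' Counts spikes in `[align + start, align + end)` per trial and neuron.
#' Trials lacking the alignment event (e.g. the saccade epoch on a
#' no-response trial) are dropped and listed in the `dropped` field.
#'
#' @param session a `session_record`.
#' @param epoch an [epoch_window()].
#' @param trial_types optional subset of trial types (default: all).
#' @param outcomes optional subset of outcomes (default: all).
#' @return A `count_matrix`: list with `counts` (trials x neurons integer
#'   matrix), `trial_index`, `conditions` (cue quadrant per kept trial),
#'   `epoch`, `duration_s`, and `dropped` (trial indices without the
#'   alignment event).
#' @export
extract_counts <- function(session, epoch, trial_types = NULL,
                           outcomes = NULL) {
  stopifnot(inherits(epoch, "epoch_window"))
  tr <- session$trials
  if (!is.null(trial_types)) tr <- tr[tr$trial_type %in% trial_types, ]
  if (!is.null(outcomes)) tr <- tr[tr$outcome %in% outcomes, ]
  a <- align_times(tr, epoch$align)
  dropped <- tr$trial_index[is.na(a)]
  keep <- !is.na(a)
  tr <- tr[keep, ]
  a <- a[keep]
  pre <- if (!is.null(session$pre_window_ms)) session$pre_window_ms else 0
  if (epoch$align == "cue" && epoch$start < -pre)
    stop("epoch '", epoch$name, "' starts before the recorded span (-",
         pre, " ms)")
  neurons <- session$electrode_map$neuron_id
  counts <- matrix(0L, nrow(tr), length(neurons),
                   dimnames = list(NULL, neurons))
  if (nrow(tr) > 0 && nrow(session$spikes) > 0) {
    sp <- data.table::as.data.table(session$spikes)
    al <- data.table::data.table(trial_index = tr$trial_index, align = a)
    sp <- sp[al, on = "trial_index", nomatch = NULL]
    sp <- sp[time_ms >= align + epoch$start & time_ms < align + epoch$end]
    if (nrow(sp) > 0) {
      agg <- sp[, list(count = .N), by = list(trial_index, neuron_id)]
      ri <- match(agg$trial_index, tr$trial_index)
      ci <- match(agg$neuron_id, neurons)
      ok <- !is.na(ci)
      counts[cbind(ri[ok], ci[ok])] <- agg$count[ok]
    }
  }
  structure(
    list(counts = counts,
         trial_index = tr$trial_index,
         conditions = tr$cue_quadrant,
         trial_type = tr$trial_type,
         outcome = tr$outcome,
         epoch = epoch,
         duration_s = (epoch$end - epoch$start) / 1000,
         dropped = dropped),
    class = "count_matrix"
  )
}

# spikes of one neuron split by trial (list keyed by trial index), for SDFs
neuron_spikes_by_trial <- function(session, neuron) {
  sp <- session$spikes[session$spikes$neuron_id == neuron, ]
  split(sp$time_ms, sp$trial_index)
}
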