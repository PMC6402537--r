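# On-disk session format: one directory per session holding
#   manifest.json  -- metadata, electrode map, exclusion log
#   trials.csv     -- one row per trial (event times in ms, cue onset = 0)
#   spikes.csv     -- long format: trial_index, neuron_id, electrode_id, time_ms
# Plain text, comma-separated, header row, UTF-8, '.' decimal; a missing
# saccade/change time is an empty field, never 0.  Spike times are signed
# offsets from cue onset and may extend down to -pre_window_ms (the
# recording span preceding the cue, needed for the baseline epoch).

TRIAL_COLUMNS <- c("trial_index", "trial_type", "cue_quadrant", "cue_on",
                   "cue_off", "stimuli_on", "change_time", "saccade_time",
                   "outcome")

#' Validate a session record
#'
#' Checks every structural invariant of the session format: trial event
#' times (363 ms cue, delay within 585-1755 ms, non-decreasing where
#' present), categorical domains, spike-train sorting and span, and
#' consistency between spikes, trials and the electrode map.
#'
#' @param record a `session_record`.
#' @return character vector of violation messages; empty iff valid.
#' @export
validate_session <- function(record) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  if (!all(TRIAL_COLUMNS %in% names(record$trials))) {
    return(sprintf("trials table is missing columns: %s",
                   paste(setdiff(TRIAL_COLUMNS, names(record$trials)),
                         collapse = ", ")))
  }
  tr <- record$trials
  if (nrow(tr) > 0) {
    if (anyDuplicated(tr$trial_index)) say("duplicated trial_index values")
    bad <- which(!(tr$trial_type %in% TRIAL_TYPES))
    for (i in head(bad, 3)) say("trial %d: unknown trial_type '%s'",
                                tr$trial_index[i], tr$trial_type[i])
    bad <- which(!(tr$cue_quadrant %in% 1:4))
    for (i in head(bad, 3)) say("trial %d: cue_quadrant outside 1-4",
                                tr$trial_index[i])
    bad <- which(!(tr$outcome %in% OUTCOMES))
    for (i in head(bad, 3)) say("trial %d: unknown outcome '%s'",
                                tr$trial_index[i], tr$outcome[i])
    bad <- which(abs(tr$cue_off - tr$cue_on - CUE_MS) > 1e-9)
    for (i in head(bad, 3))
      say("trial %d: cue_off - cue_on = %g violates the %d ms cue rule",
          tr$trial_index[i], tr$cue_off[i] - tr$cue_on[i], CUE_MS)
    delay <- tr$change_time - tr$stimuli_on
    bad <- which(!is.na(delay) &
                   (delay < DELAY_MIN_MS | delay > DELAY_MAX_MS))
    for (i in head(bad, 3))
      say("trial %d: delay %g ms outside [%d, %d]",
          tr$trial_index[i], delay[i], DELAY_MIN_MS, DELAY_MAX_MS)
    # non-decreasing event times where present
    tcols <- c("cue_on", "cue_off", "stimuli_on", "change_time", "saccade_time")
    tm <- as.matrix(tr[, tcols])
    for (i in seq_len(nrow(tm))) {
      x <- tm[i, !is.na(tm[i, ])]
      if (length(x) > 1 && any(diff(x) < 0))
        say("trial %d: event times not non-decreasing", tr$trial_index[i])
    }
  }
  sp <- record$spikes
  if (nrow(sp) > 0) {
    pre <- if (!is.null(record$pre_window_ms)) record$pre_window_ms else 0
    if (any(sp$time_ms < -pre))
      say("%d spike times precede the recording window (-%g ms)",
          sum(sp$time_ms < -pre), pre)
    orphan <- setdiff(unique(sp$trial_index), tr$trial_index)
    if (length(orphan) > 0)
      say("spikes reference unknown trial_index: %s",
          paste(head(orphan, 5), collapse = ", "))
    unknown <- setdiff(unique(sp$neuron_id), record$electrode_map$neuron_id)
    if (length(unknown) > 0)
      say("spikes reference neurons missing from the electrode map: %s",
          paste(head(unknown, 5), collapse = ", "))
    dt <- data.table::as.data.table(sp)
    unsorted <- dt[, list(bad = is.unsorted(time_ms, strictly = TRUE)),
                   by = list(trial_index, neuron_id)]
    nbad <- sum(unsorted$bad)
    if (nbad > 0)
      say("%d trial x neuron spike trains are not strictly sorted", nbad)
  }
  if (anyDuplicated(record$electrode_map$neuron_id))
    say("duplicated neuron_id in electrode map")
  v
}

#' Write a session to disk
#'
#' Refuses to write a record that fails [validate_session()], reporting
#' the violations.  The output is round-trippable with [read_session()].
#'
#' @param record a `session_record`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  viol <- validate_session(record)
  if (length(viol) > 0)
    stop("refusing to write invalid session:\n  ",
         paste(viol, collapse = "\n  "))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  manifest <- list(
    format = "pfcdose-session/1",
    subject_id = record$subject_id,
    session_index = record$session_index,
    treatment = record$treatment,
    dose_index = record$dose_index,
    dose_mg_kg = record$dose_mg_kg,
    label = record$label,
    pre_window_ms = record$pre_window_ms,
    n_trials = nrow(record$trials),
    n_neurons = nrow(record$electrode_map),
    electrode_map = record$electrode_map,
    log = as.list(record$log)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  data.table::fwrite(record$trials, file.path(path, "trials.csv"), na = "")
  sp <- data.table::as.data.table(record$spikes)
  emap <- data.table::as.data.table(record$electrode_map)
  sp <- emap[sp, on = "neuron_id"]
  data.table::setcolorder(sp, c("trial_index", "neuron_id", "electrode_id",
                                "time_ms"))
  data.table::fwrite(sp, file.path(path, "spikes.csv"), na = "")
  invisible(path)
}

read_table_checked <- function(file, required, integer_cols = character(0),
                               numeric_cols = character(0)) {
  if (!file.exists(file)) stop("missing session file: ", file)
  dt <- tryCatch(
    data.table::fread(file, na.strings = "", colClasses = NULL,
                      showProgress = FALSE),
    error = function(e) stop("parse error in ", file, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0)
    stop("parse error in ", file, ": missing columns ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(dt)
  for (cl in intersect(integer_cols, names(df))) {
    conv <- suppressWarnings(as.integer(df[[cl]]))
    bad <- which(is.na(conv) & !is.na(df[[cl]]))
    if (length(bad) > 0)
      stop("parse error in ", file, ", row ", bad[1],
           ": non-integer value in column ", cl)
    df[[cl]] <- conv
  }
  for (cl in intersect(numeric_cols, names(df))) {
    conv <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(conv) & !is.na(df[[cl]]))
    if (length(bad) > 0)
      stop("parse error in ", file, ", row ", bad[1],
           ": non-numeric value in column ", cl)
    df[[cl]] <- conv
  }
  df
}

#' Read a session from disk
#'
#' @param path session directory written by [write_session()].
#' @param validate run [validate_session()] on the result (default `TRUE`);
#'   violations raise an error.
#' @return a `session_record`.
#' @export
read_session <- function(path, validate = TRUE) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing session file: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  trials <- read_table_checked(
    file.path(path, "trials.csv"), TRIAL_COLUMNS,
    integer_cols = c("trial_index", "cue_quadrant"),
    numeric_cols = c("cue_on", "cue_off", "stimuli_on", "change_time",
                     "saccade_time"))
  trials$trial_type <- as.character(trials$trial_type)
  trials$outcome <- as.character(trials$outcome)
  spikes <- read_table_checked(
    file.path(path, "spikes.csv"),
    c("trial_index", "neuron_id", "time_ms"),
    integer_cols = "trial_index", numeric_cols = "time_ms")
  spikes$neuron_id <- as.character(spikes$neuron_id)
  emap <- as.data.frame(manifest$electrode_map)
  if (nrow(emap) > 0) {
    emap$neuron_id <- as.character(emap$neuron_id)
    emap$electrode_id <- as.character(emap$electrode_id)
  } else {
    emap <- data.frame(neuron_id = character(), electrode_id = character(),
                       stringsAsFactors = FALSE)
  }
  record <- structure(
    list(subject_id = manifest$subject_id,
         session_index = as.integer(manifest$session_index),
         treatment = manifest$treatment,
         dose_index = as.integer(manifest$dose_index),
         dose_mg_kg = if (is.null(manifest$dose_mg_kg)) NA_real_
           else as.numeric(manifest$dose_mg_kg),
         label = manifest$label,
         trials = trials,
         spikes = spikes[, c("trial_index", "neuron_id", "time_ms")],
         electrode_map = emap,
         pre_window_ms = as.numeric(manifest$pre_window_ms),
         log = as.character(unlist(manifest$log))),
    class = "session_record"
  )
  if (validate) {
    viol <- validate_session(record)
    if (length(viol) > 0)
      stop("invalid session at ", path, ":\n  ",
           paste(viol, collapse = "\n  "))
  }
  record
}
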