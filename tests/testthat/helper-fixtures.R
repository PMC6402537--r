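# Shared fixture builders.  Everything is generated in code at test time;
# sizes are scaled down from the full study (48 neurons x ~800 trials) to
# keep the suite fast, except where a spec-level claim fixes the size.

placebo_spec <- function(session_index = 1L) {
  data.frame(session_index = session_index, treatment = "placebo",
             dose_index = 0L, dose_mg = NA_real_, dose_mg_kg = NA_real_,
             label = "placebo", stringsAsFactors = FALSE)
}

dose_spec <- function(dose_index = 1L, session_index = 1L) {
  data.frame(session_index = session_index, treatment = "MPH",
             dose_index = as.integer(dose_index), dose_mg = NA_real_,
             dose_mg_kg = NA_real_,
             label = paste0("dose_", dose_index), stringsAsFactors = FALSE)
}

# homogeneous strongly tuned ensemble: known gains, known latency
tuned_ensemble <- function(n_neurons = 12, baseline = 20, visual_gain = 2,
                           attention_gain = 1.5, saccade_gain = 2,
                           latency = 120, loadings = 0) {
  neurons <- do.call(rbind, lapply(seq_len(n_neurons), function(i) {
    neuron_spec(sprintf("n%02d", i), sprintf("e%02d", i), baseline,
                preferred_quadrant = ((i - 1L) %% 4L) + 1L,
                visual_gain = visual_gain, attention_gain = attention_gain,
                saccade_gain = saccade_gain, response_latency = latency)
  }))
  ensemble_spec(neurons, rep_len(loadings, n_neurons))
}

quick_session <- function(n_neurons = 8, n_trials = 150, seed = 1,
                          hit_prob = 0.72, ensemble = NULL, spec = NULL,
                          loading_sd = 0) {
  if (is.null(ensemble))
    ensemble <- make_ensemble(n_neurons = n_neurons,
                              n_electrodes = max(2, n_neurons %/% 2),
                              loading_sd = loading_sd, seed = seed)
  if (is.null(spec)) spec <- placebo_spec()
  simulate_session(spec, ensemble, behavior_model(hit_prob = hit_prob),
                   seed = seed, n_trials = n_trials)
}

# count_matrix built directly from a counts matrix (bypasses a session)
count_matrix_stub <- function(counts, quadrants, epoch = NULL,
                              duration_s = 0.2) {
  if (is.null(epoch)) epoch <- epoch_window("cue", "cue", 0, 200)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("n%03d", seq_len(ncol(counts)))
  structure(
    list(counts = counts, trial_index = seq_len(nrow(counts)),
         conditions = quadrants,
         trial_type = rep("target", nrow(counts)),
         outcome = rep("hit", nrow(counts)),
         epoch = epoch, duration_s = duration_s, dropped = integer(0)),
    class = "count_matrix"
  )
}

# null metric tables at the statistical level: one row per neuron with all
# 19 metrics drawn iid across treatments (the null world of the dose scan)
null_metric_tables <- function(n_neurons = 40, subjects = c("F", "JL"),
                               labels = c("placebo", paste0("dose_", 1:5))) {
  do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(labels, function(lb) {
      m <- matrix(stats::rlnorm(n_neurons * 19, log(10), 0.4), n_neurons, 19)
      colnames(m) <- sprintf("metric_%02d", 1:19)
      data.frame(subject = s, label = lb,
                 neuron_id = sprintf("n%03d", seq_len(n_neurons)),
                 m, stringsAsFactors = FALSE)
    }))
  }))
}
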