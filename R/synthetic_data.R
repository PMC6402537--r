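# Synthetic study generator: dosing schedules, task behavior, and Poisson
# spike trains with shared-latent correlated variability.  The generator is
# the ground truth against which every analysis stage is validated: tuning
# gains must be recovered by the response metrics, latent loadings by the
# noise correlations, and injected dose effects by the dose scans.

TRIAL_TYPES <- c("target", "distractor", "target+distractor")
OUTCOMES <- c("hit", "fixation_break", "saccade_to_distractor", "no_response")

# task timing constants (ms): cue presentation, delay bounds, response window
CUE_MS <- 363
DELAY_MIN_MS <- 585
DELAY_MAX_MS <- 1755
RESPONSE_WINDOW_MS <- 250
PRE_WINDOW_MS <- 500   # recording span before cue onset
POST_WINDOW_MS <- 400  # recording span after the last event

#' Diagonally opposite quadrant
#'
#' In the task the changing distractor sits diagonally opposite the target,
#' so quadrant 1 maps to 3, 2 to 4, and vice versa.
#' @param q quadrant index in 1..4 (vectorized).
#' @return opposite quadrant index.
#' @export
opposite_quadrant <- function(q) ((q - 1L + 2L) %% 4L) + 1L

derive_seed <- function(master, index) {
  # master seed + stream index -> substream seed, kept below 2^31
  as.integer((as.numeric(master) * 10007 + as.numeric(index) * 101) %% 2147483647)
}

#' Subject configuration for a dosing study
#'
#' @param subject_id subject label.
#' @param body_weight_kg body weight in kg (> 0).
#' @param tablet_doses_mg strictly increasing tablet doses in mg; the
#'   study default is `c(2.5, 5, 6.25, 7.5, 10)`.
#' @param sessions_per_dose_block consecutive sessions per dose (default 3).
#' @param flank_placebo_count placebo sessions before and after each dose
#'   block (default 2); consecutive blocks share their flanks.
#' @return An object of class `"subject_config"`.
#' @export
subject_config <- function(subject_id, body_weight_kg,
                           tablet_doses_mg = c(2.5, 5, 6.25, 7.5, 10),
                           sessions_per_dose_block = 3,
                           flank_placebo_count = 2) {
  stopifnot(length(subject_id) == 1, body_weight_kg > 0,
            sessions_per_dose_block >= 0, flank_placebo_count >= 0)
  if (length(tablet_doses_mg) > 1 && any(diff(tablet_doses_mg) <= 0))
    stop("tablet_doses_mg must be strictly increasing")
  if (any(tablet_doses_mg <= 0)) stop("tablet doses must be positive")
  structure(
    list(subject_id = as.character(subject_id),
         body_weight_kg = body_weight_kg,
         tablet_doses_mg = tablet_doses_mg,
         sessions_per_dose_block = as.integer(sessions_per_dose_block),
         flank_placebo_count = as.integer(flank_placebo_count)),
    class = "subject_config"
  )
}

#' Weight-based dose
#'
#' Tablet dose divided by body weight, rounded half-up to 2 decimals
#' (the convention under which the printed mg/kg dose tables reproduce
#' exactly from the tablet doses and body weights).
#'
#' @param dose_mg tablet dose in mg (> 0, vectorized).
#' @param weight_kg body weight in kg (> 0).
#' @return dose in mg/kg, 2 decimals.
#' @examples
#' mg_per_kg(10, 5.8)   # 1.72
#' mg_per_kg(5, 7.5)    # 0.67
#' @export
mg_per_kg <- function(dose_mg, weight_kg) {
  if (any(dose_mg <= 0) || any(weight_kg <= 0))
    stop("mg_per_kg(): dose and weight must be positive")
  x <- dose_mg / weight_kg
  floor(x * 100 + 0.5 + 1e-9) / 100
}

#' Build the session schedule for a subject
#'
#' Blocks of `sessions_per_dose_block` consecutive sessions per dose, each
#' block preceded and followed by `flank_placebo_count` placebo sessions;
#' consecutive blocks share their flanking placebos
#' (Pb-Pb-D1-D1-D1-Pb-Pb-D2-...).  For D dose blocks the total session
#' count is `flank + D * (block + flank)`.
#'
#' @param config a [subject_config()].
#' @return data.frame with one row per session: `session_index`, `treatment`
#'   (`"placebo"` or `"MPH"`), `dose_index` (0 for placebo), `dose_mg`,
#'   `dose_mg_kg`, `label` (`"placebo"` or `"dose_<i>"`).
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "subject_config"))
  d <- length(config$tablet_doses_mg)
  fl <- config$flank_placebo_count
  bl <- config$sessions_per_dose_block
  if (d == 0) {
    return(data.frame(session_index = integer(), treatment = character(),
                      dose_index = integer(), dose_mg = numeric(),
                      dose_mg_kg = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  dose_index <- integer(0)
  for (i in seq_len(d)) {
    dose_index <- c(dose_index, rep(0L, fl), rep(i, bl))
  }
  dose_index <- c(dose_index, rep(0L, fl))
  placebo <- dose_index == 0L
  dose_mg <- ifelse(placebo, NA_real_, config$tablet_doses_mg[dose_index])
  data.frame(
    session_index = seq_along(dose_index),
    treatment = ifelse(placebo, "placebo", "MPH"),
    dose_index = dose_index,
    dose_mg = dose_mg,
    dose_mg_kg = ifelse(placebo, NA_real_,
                        mg_per_kg(ifelse(placebo, 1, dose_mg),
                                  config$body_weight_kg)),
    label = ifelse(placebo, "placebo", paste0("dose_", dose_index)),
    stringsAsFactors = FALSE
  )
}

#' Flanking placebo sessions of a dose block
#'
#' The matched control pool for a dose: the placebo sessions recorded
#' immediately before and immediately after that dose's block of
#' treatment sessions.
#'
#' @param schedule a schedule from [build_schedule()].
#' @param dose_index dose block number (1-based).
#' @return integer vector of placebo `session_index` values.
#' @export
flanking_sessions <- function(schedule, dose_index) {
  stopifnot(dose_index >= 1)
  idx <- schedule$session_index[schedule$dose_index == dose_index]
  if (length(idx) == 0) stop("no sessions for dose_index ", dose_index)
  is_pb <- schedule$treatment == "placebo"
  # maximal consecutive placebo runs touching the block on either side
  run <- function(start, step) {
    out <- integer(0)
    i <- start
    while (i >= 1 && i <= nrow(schedule) && is_pb[schedule$session_index == i]) {
      out <- c(out, i)
      i <- i + step
    }
    out
  }
  sort(c(run(min(idx) - 1L, -1L), run(max(idx) + 1L, 1L)))
}

#' Behavioral model for trial-outcome simulation
#'
#' @param hit_prob probability of a hit; either a single value or a named
#'   vector keyed by treatment label (`"placebo"`, `"dose_1"`, ...).
#' @param error_mix named probabilities of the three error types
#'   (`fixation_break`, `saccade_to_distractor`, `no_response`) conditional
#'   on an error; must sum to 1.
#' @param trials_mean,trials_sd mean and SD of the per-session trial count
#'   (normal, truncated at 1).  Defaults 817 / 93, the scale of a long
#'   2-hour session for a well-trained subject.
#' @param random_policy if `TRUE` the simulated subject responds to a
#'   uniformly random one of the four locations on every trial (hit iff the
#'   chosen location is the target); used for chance-level calibration.
#' @return An object of class `"behavior_model"`.
#' @export
behavior_model <- function(hit_prob = 0.72,
                           error_mix = c(fixation_break = 0.45,
                                         saccade_to_distractor = 0.30,
                                         no_response = 0.25),
                           trials_mean = 817, trials_sd = 93,
                           random_policy = FALSE) {
  stopifnot(all(hit_prob >= 0 & hit_prob <= 1),
            all(error_mix >= 0), trials_mean >= 1, trials_sd >= 0)
  if (abs(sum(error_mix) - 1) > 1e-12)
    stop("error_mix must sum to 1")
  if (!all(c("fixation_break", "saccade_to_distractor", "no_response")
           %in% names(error_mix)))
    stop("error_mix must name fixation_break, saccade_to_distractor, no_response")
  structure(
    list(hit_prob = hit_prob, error_mix = error_mix,
         trials_mean = trials_mean, trials_sd = trials_sd,
         random_policy = isTRUE(random_policy)),
    class = "behavior_model"
  )
}

model_hit_prob <- function(model, label) {
  p <- model$hit_prob
  if (!is.null(names(p)) && label %in% names(p)) unname(p[label])
  else unname(p[1])
}

#' Single-neuron generative specification
#'
#' Rates are Poisson with a piecewise-constant intensity: baseline, times a
#' transient visual gain spanning +/-80 ms around `response_latency`
#' (so `response_latency` is the time-to-peak) when the cue -- or, at array
#' onset, a distractor -- falls in the preferred quadrant, times a sustained
#' attention gain from 500 ms post-cue to 50 ms before saccade onset when
#' attention is in the preferred quadrant (the regimes are disjoint by
#' construction), times a saccade gain in +/-50 ms around saccade
#' onset when the saccade lands in the preferred quadrant.
#'
#' @param neuron_id,electrode_id identifiers.
#' @param baseline_rate baseline intensity, spikes/s (>= 0).
#' @param preferred_quadrant 1..4, or `NA` for an untuned neuron.
#' @param visual_gain,attention_gain,saccade_gain multiplicative rate
#'   factors (>= 0; 1 = no modulation).
#' @param response_latency time-to-peak of the visual transient, ms.
#' @return A one-row data.frame.
#' @export
neuron_spec <- function(neuron_id, electrode_id, baseline_rate,
                        preferred_quadrant = NA_integer_,
                        visual_gain = 1, attention_gain = 1,
                        saccade_gain = 1, response_latency = 120) {
  stopifnot(baseline_rate >= 0, visual_gain >= 0, attention_gain >= 0,
            saccade_gain >= 0,
            is.na(preferred_quadrant) || preferred_quadrant %in% 1:4,
            response_latency >= 60, response_latency <= 300)
  data.frame(neuron_id = as.character(neuron_id),
             electrode_id = as.character(electrode_id),
             baseline_rate = baseline_rate,
             preferred_quadrant = as.integer(preferred_quadrant),
             visual_gain = visual_gain, attention_gain = attention_gain,
             saccade_gain = saccade_gain,
             response_latency = response_latency,
             stringsAsFactors = FALSE)
}

#' Ensemble specification: neurons plus shared-latent noise structure
#'
#' Pairwise trial-to-trial correlations are induced by a single global
#' scalar latent per trial, z ~ N(0,1): neuron i's intensity is shifted by
#' `latent_loadings[i] * z` spikes/s for the whole trial (plus an optional
#' independent per-trial jitter), then clipped at 0.  Signed loadings
#' produce both positive and negative pairwise noise correlations.
#'
#' @param neurons data.frame of [neuron_spec()] rows.
#' @param latent_loadings numeric vector, one per neuron (spikes/s per
#'   latent SD); default 0 (independent neurons).
#' @param independent_noise_scale SD of the per-trial, per-neuron
#'   independent intensity jitter (spikes/s); default 0.
#' @return An object of class `"ensemble_spec"`.
#' @export
ensemble_spec <- function(neurons, latent_loadings = rep(0, nrow(neurons)),
                          independent_noise_scale = 0) {
  stopifnot(is.data.frame(neurons), nrow(neurons) >= 1,
            length(latent_loadings) == nrow(neurons),
            all(is.finite(latent_loadings)),
            independent_noise_scale >= 0,
            !anyDuplicated(neurons$neuron_id))
  structure(
    list(neurons = neurons, latent_loadings = latent_loadings,
         independent_noise_scale = independent_noise_scale),
    class = "ensemble_spec"
  )
}

#' Random ensemble of realistic tuned neurons
#'
#' Convenience constructor used by tests and the pipeline's simulate step.
#' Roughly 48 neurons over 32 electrodes mirrors a typical recording block;
#' loadings can optionally be coupled to tuning so that similarly tuned
#' neurons share noise (giving the usual rising noise-vs-signal-correlation
#' structure).
#'
#' @param n_neurons,n_electrodes ensemble size (some electrodes carry more
#'   than one isolated unit, so same-electrode pairs exist).
#' @param tuned_fraction fraction of neurons with a preferred quadrant.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline-rate
#'   parameters (spikes/s).
#' @param visual_gain_range,attention_gain_range,saccade_gain_range uniform
#'   ranges for the multiplicative gains of tuned neurons.
#' @param latency_range uniform range of visual time-to-peak (ms).
#' @param loading_sd scale of the shared-latent loadings (spikes/s).
#' @param tuning_coupled_loadings couple loading sign/magnitude to the
#'   preferred quadrant (default `TRUE`).
#' @param independent_noise_scale passed to [ensemble_spec()].
#' @param seed RNG seed.
#' @return An [ensemble_spec()].
#' @export
make_ensemble <- function(n_neurons = 48, n_electrodes = 32,
                          tuned_fraction = 0.7,
                          baseline_meanlog = log(8), baseline_sdlog = 0.4,
                          visual_gain_range = c(1.8, 3),
                          attention_gain_range = c(1.3, 2),
                          saccade_gain_range = c(1.8, 3),
                          latency_range = c(100, 140),
                          loading_sd = 1.5,
                          tuning_coupled_loadings = TRUE,
                          independent_noise_scale = 0,
                          seed = 1L) {
  set.seed(derive_seed(seed, 0L))
  electrode <- sprintf("e%02d", (seq_len(n_neurons) - 1L) %% n_electrodes + 1L)
  tuned <- stats::runif(n_neurons) < tuned_fraction
  pref <- ifelse(tuned, sample(1:4, n_neurons, replace = TRUE), NA_integer_)
  runif_in <- function(r, n) stats::runif(n, r[1], r[2])
  neurons <- data.frame(
    neuron_id = sprintf("n%03d", seq_len(n_neurons)),
    electrode_id = electrode,
    baseline_rate = stats::rlnorm(n_neurons, baseline_meanlog, baseline_sdlog),
    preferred_quadrant = as.integer(pref),
    visual_gain = ifelse(tuned, runif_in(visual_gain_range, n_neurons), 1),
    attention_gain = ifelse(tuned, runif_in(attention_gain_range, n_neurons), 1),
    saccade_gain = ifelse(tuned, runif_in(saccade_gain_range, n_neurons), 1),
    response_latency = round(runif_in(latency_range, n_neurons)),
    stringsAsFactors = FALSE
  )
  if (tuning_coupled_loadings) {
    quad_load <- c(1, 0.4, -0.4, -1)  # tuning-dependent common-input sign
    base <- ifelse(is.na(pref), 0, quad_load[ifelse(is.na(pref), 1, pref)])
    loadings <- loading_sd * (base + stats::rnorm(n_neurons, 0, 0.4))
  } else {
    loadings <- stats::rnorm(n_neurons, 0, loading_sd)
  }
  ensemble_spec(neurons, loadings, independent_noise_scale)
}

#' Dose-effect specification (generator-side injected effects)
#'
#' Per-dose multipliers applied when simulating treatment sessions; the
#' default (all 1) is the null study in which every generated quantity has
#' the same distribution under every treatment label.
#'
#' @param n_doses number of dose levels.
#' @param attention_gain_mult,latent_loading_mult,hit_prob_mult numeric
#'   vectors of length `n_doses` (or scalars, recycled), all >= 0.
#' @return An object of class `"dose_effect_spec"`.
#' @export
dose_effect_spec <- function(n_doses = 5,
                             attention_gain_mult = 1,
                             latent_loading_mult = 1,
                             hit_prob_mult = 1) {
  rec <- function(x) {
    stopifnot(all(x >= 0))
    rep_len(x, n_doses)
  }
  structure(
    list(n_doses = as.integer(n_doses),
         attention_gain_mult = rec(attention_gain_mult),
         latent_loading_mult = rec(latent_loading_mult),
         hit_prob_mult = rec(hit_prob_mult)),
    class = "dose_effect_spec"
  )
}

dose_multiplier <- function(dose_fx, field, dose_index) {
  if (is.null(dose_fx) || dose_index == 0L) return(1)
  v <- dose_fx[[field]]
  if (dose_index > length(v)) 1 else v[dose_index]
}

#' Simulate the behavioral trials of one session
#'
#' Trial types are drawn uniformly over the three interleaved types, the
#' cue quadrant uniformly over the four locations.  Event times follow the
#' task: 363 ms cue, distractor array at cue offset, a delay drawn
#' uniformly in 585-1755 ms, then the orientation change (Go signal) and a
#' saccade inside the 250 ms response window.  Outcomes are drawn from the
#' model's hit probability and conditional error mix; fixation breaks abort
#' the trial before the change (no `change_time`), no-response trials and
#' hits on distractor trials (where the correct response is holding
#' fixation) carry no saccade time.
#'
#' @param session one row of a [build_schedule()] data.frame (or a list
#'   with `label` and `dose_index`).
#' @param model a [behavior_model()].
#' @param dose_fx optional [dose_effect_spec()]; its `hit_prob_mult` scales
#'   the hit probability on treatment sessions.
#' @param seed RNG seed for this session.
#' @param n_trials trial count; default drawn from the model's truncated
#'   normal.
#' @return data.frame of trial records (one row per trial).
#' @export
simulate_behavior <- function(session, model, dose_fx = NULL, seed = 1L,
                              n_trials = NULL) {
  stopifnot(inherits(model, "behavior_model"))
  set.seed(derive_seed(seed, 1L))
  if (is.null(n_trials)) {
    n_trials <- max(1L, as.integer(round(
      stats::rnorm(1, model$trials_mean, model$trials_sd))))
  }
  label <- if (!is.null(session$label)) session$label else "placebo"
  dose_index <- if (!is.null(session$dose_index)) session$dose_index else 0L
  p_hit <- min(1, model_hit_prob(model, label) *
                 dose_multiplier(dose_fx, "hit_prob_mult", dose_index))

  trial_type <- sample(TRIAL_TYPES, n_trials, replace = TRUE)
  cue_quadrant <- sample.int(4L, n_trials, replace = TRUE)
  delay <- round(stats::runif(n_trials, DELAY_MIN_MS, DELAY_MAX_MS))
  cue_on <- rep(0, n_trials)
  cue_off <- rep(CUE_MS, n_trials)
  stimuli_on <- rep(CUE_MS, n_trials)
  change_time <- CUE_MS + delay
  saccade_lat <- round(stats::runif(n_trials, 100, RESPONSE_WINDOW_MS))

  if (model$random_policy) {
    response_q <- sample.int(4L, n_trials, replace = TRUE)
    outcome <- ifelse(response_q == cue_quadrant, "hit",
                      "saccade_to_distractor")
    saccade_time <- change_time + saccade_lat
  } else {
    is_hit <- stats::runif(n_trials) < p_hit
    err <- sample(names(model$error_mix), n_trials, replace = TRUE,
                  prob = model$error_mix)
    outcome <- ifelse(is_hit, "hit", err)
    saccade_time <- rep(NA_real_, n_trials)
    responds <- outcome == "saccade_to_distractor" |
      (outcome == "hit" & trial_type != "distractor")
    saccade_time[responds] <- change_time[responds] + saccade_lat[responds]
    fb <- outcome == "fixation_break"
    # break occurs during the delay, before the scheduled Go signal
    saccade_time[fb] <- CUE_MS + round(stats::runif(sum(fb), 50, delay[fb] - 1))
    change_time[fb] <- NA_real_
  }

  data.frame(
    trial_index = seq_len(n_trials),
    trial_type = trial_type,
    cue_quadrant = cue_quadrant,
    cue_on = cue_on, cue_off = cue_off, stimuli_on = stimuli_on,
    change_time = change_time, saccade_time = saccade_time,
    outcome = outcome,
    stringsAsFactors = FALSE
  )
}

# quadrant the saccade landed in, NA when no saccade was made
saccade_endpoint <- function(trials) {
  ep <- rep(NA_integer_, nrow(trials))
  hit <- trials$outcome == "hit" & !is.na(trials$saccade_time)
  ep[hit] <- trials$cue_quadrant[hit]
  sd_ <- trials$outcome == "saccade_to_distractor" &
    !is.na(trials$saccade_time) & !is.na(trials$change_time)
  ep[sd_] <- opposite_quadrant(trials$cue_quadrant[sd_])
  ep
}

#' Simulate one full session (behavior + spike trains)
#'
#' Each neuron emits an inhomogeneous-Poisson spike train over the trial's
#' recording span (500 ms before cue onset to 400 ms after the last event).
#' The intensity is `baseline * gain(t) + loading * z + e`, where `gain(t)`
#' multiplies the epoch-dependent factors of [neuron_spec()] active at time
#' t, `z ~ N(0,1)` is the session-wide per-trial shared latent, and `e` is
#' optional independent per-trial jitter; negative intensities are clipped
#' at 0 and counted in the session log.  On treatment sessions the
#' [dose_effect_spec()] multipliers are applied to attention gains, latent
#' loadings and hit probability.  Bit-identical output under a fixed seed.
#'
#' @param session one row of a [build_schedule()] data.frame.
#' @param ensemble an [ensemble_spec()].
#' @param model a [behavior_model()].
#' @param dose_fx optional [dose_effect_spec()].
#' @param seed RNG seed for this session.
#' @param n_trials optional fixed trial count.
#' @param subject_id subject label stored in the record.
#' @return A `session_record`: list with `subject_id`, `session_index`,
#'   `treatment`, `dose_index`, `dose_mg_kg`, `label`, `trials`, `spikes`
#'   (data.frame `trial_index`, `neuron_id`, `time_ms`), `electrode_map`,
#'   `pre_window_ms`, `log`.
#' @export
simulate_session <- function(session, ensemble, model, dose_fx = NULL,
                             seed = 1L, n_trials = NULL, subject_id = "S1") {
  stopifnot(inherits(ensemble, "ensemble_spec"))
  trials <- simulate_behavior(session, model, dose_fx, seed, n_trials)
  dose_index <- if (!is.null(session$dose_index)) session$dose_index else 0L

  set.seed(derive_seed(seed, 2L))
  nn <- nrow(ensemble$neurons)
  nt <- nrow(trials)
  nrn <- ensemble$neurons
  ag_mult <- dose_multiplier(dose_fx, "attention_gain_mult", dose_index)
  ll_mult <- dose_multiplier(dose_fx, "latent_loading_mult", dose_index)
  att_gain <- nrn$attention_gain * ag_mult
  loadings <- ensemble$latent_loadings * ll_mult

  z <- stats::rnorm(nt)
  eps <- if (ensemble$independent_noise_scale > 0) {
    matrix(stats::rnorm(nt * nn, 0, ensemble$independent_noise_scale), nt, nn)
  } else NULL

  endpoint <- saccade_endpoint(trials)
  t_last <- pmax(trials$stimuli_on, trials$change_time, trials$saccade_time,
                 na.rm = TRUE)
  t_end <- t_last + POST_WINDOW_MS
  # the sustained-attention regime ends where the perisaccadic burst
  # begins (50 ms before saccade onset), keeping the two gains disjoint
  att_end <- ifelse(is.na(trials$saccade_time) & is.na(trials$change_time),
                    t_end,
                    pmin(trials$saccade_time - 50, trials$change_time +
                           RESPONSE_WINDOW_MS, t_end, na.rm = TRUE))

  n_clipped <- 0L
  acc_trial <- vector("list", nt)
  for (ti in seq_len(nt)) {
    cq <- trials$cue_quadrant[ti]
    st <- trials$saccade_time[ti]
    span0 <- -PRE_WINDOW_MS
    span1 <- t_end[ti]
    shift <- loadings * z[ti]
    if (!is.null(eps)) shift <- shift + eps[ti, ]
    spk_times <- vector("list", nn)
    for (ni in seq_len(nn)) {
      b <- nrn$baseline_rate[ni]
      pref <- nrn$preferred_quadrant[ni]
      wins <- NULL
      if (!is.na(pref)) {
        lat <- nrn$response_latency[ni]
        if (cq == pref) {
          wins <- rbind(wins, c(lat - 80, lat + 80, nrn$visual_gain[ni]))
          if (att_gain[ni] != 1)
            wins <- rbind(wins, c(500, att_end[ti], att_gain[ni]))
        } else {
          # a distractor occupies the preferred quadrant from array onset
          wins <- rbind(wins,
                        c(CUE_MS + lat - 80, CUE_MS + lat + 80,
                          nrn$visual_gain[ni]))
        }
        if (!is.na(st) && !is.na(endpoint[ti]) && endpoint[ti] == pref &&
            nrn$saccade_gain[ni] != 1)
          wins <- rbind(wins, c(st - 50, st + 50, nrn$saccade_gain[ni]))
      }
      lv <- shift[ni]
      if (is.null(wins)) {
        rate <- b + lv
        if (rate < 0) { n_clipped <- n_clipped + 1L; rate <- 0 }
        k <- stats::rpois(1L, rate * (span1 - span0) / 1000)
        spk_times[[ni]] <- if (k > 0)
          sort(stats::runif(k, span0, span1)) else numeric(0)
      } else {
        wins[, 1] <- pmax(wins[, 1], span0)
        wins[, 2] <- pmin(wins[, 2], span1)
        bp <- sort(unique(c(span0, span1, wins[, 1], wins[, 2])))
        mid <- (bp[-1] + bp[-length(bp)]) / 2
        g <- rep(1, length(mid))
        for (w in seq_len(nrow(wins)))
          g <- g * ifelse(mid >= wins[w, 1] & mid < wins[w, 2], wins[w, 3], 1)
        rates <- b * g + lv
        neg <- rates < 0
        if (any(neg)) { n_clipped <- n_clipped + sum(neg); rates[neg] <- 0 }
        dur <- diff(bp)
        k <- stats::rpois(length(rates), rates * dur / 1000)
        tot <- sum(k)
        spk_times[[ni]] <- if (tot > 0) {
          sort(stats::runif(tot, rep(bp[-length(bp)], k), rep(bp[-1], k)))
        } else numeric(0)
      }
    }
    counts <- lengths(spk_times)
    acc_trial[[ti]] <- data.frame(
      trial_index = rep.int(ti, sum(counts)),
      neuron_id = rep.int(nrn$neuron_id, counts),
      time_ms = unlist(spk_times, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  spikes <- do.call(rbind, acc_trial)
  rownames(spikes) <- NULL

  log <- character(0)
  if (n_clipped > 0)
    log <- c(log, sprintf("RATE_CLIPPED: %d negative instantaneous rates clipped to 0",
                          n_clipped))
  structure(
    list(subject_id = subject_id,
         session_index = if (!is.null(session$session_index))
           as.integer(session$session_index) else 1L,
         treatment = if (!is.null(session$treatment)) session$treatment
           else "placebo",
         dose_index = as.integer(dose_index),
         dose_mg_kg = if (!is.null(session$dose_mg_kg))
           session$dose_mg_kg else NA_real_,
         label = if (!is.null(session$label)) session$label else "placebo",
         trials = trials,
         spikes = spikes,
         electrode_map = data.frame(neuron_id = nrn$neuron_id,
                                    electrode_id = nrn$electrode_id,
                                    stringsAsFactors = FALSE),
         pre_window_ms = PRE_WINDOW_MS,
         log = log),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("session_record: subject %s, session %d (%s), %d trials, %d neurons, %d spikes\n",
              x$subject_id, x$session_index, x$label, nrow(x$trials),
              nrow(x$electrode_map), nrow(x$spikes)))
  invisible(x)
}

#' Simulate a whole study (all sessions of a schedule)
#'
#' Seeds follow the substream policy master-seed + session-index, so each
#' session is reproducible in isolation.
#'
#' @param config a [subject_config()].
#' @param ensemble an [ensemble_spec()].
#' @param model a [behavior_model()].
#' @param dose_fx optional [dose_effect_spec()].
#' @param seed master seed.
#' @param n_trials optional fixed trial count per session.
#' @return list of `session_record`s, one per scheduled session.
#' @export
simulate_study <- function(config, ensemble, model, dose_fx = NULL,
                           seed = 1L, n_trials = NULL) {
  schedule <- build_schedule(config)
  lapply(seq_len(nrow(schedule)), function(i) {
    simulate_session(schedule[i, ], ensemble, model, dose_fx,
                     seed = derive_seed(seed, schedule$session_index[i]),
                     n_trials = n_trials, subject_id = config$subject_id)
  })
}
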