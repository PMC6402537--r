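# Generator: schedule arithmetic, dosing, behavior, spike statistics and
# the shared-latent correlation structure, all against independent oracles.

test_that("schedule arithmetic is exact for the full design and in general", {
  sch <- build_schedule(subject_config("F", 5.8))
  expect_equal(nrow(sch), 27)
  expect_equal(sum(sch$treatment == "MPH"), 15)
  expect_equal(sum(sch$treatment == "placebo"), 12)
  # single-block case: Pb,Pb,D,D,D,Pb,Pb
  s1 <- build_schedule(subject_config("x", 5, tablet_doses_mg = 5))
  expect_equal(s1$treatment,
               c("placebo", "placebo", "MPH", "MPH", "MPH", "placebo", "placebo"))
  # degenerate: no doses -> empty schedule
  s0 <- build_schedule(subject_config("x", 5, tablet_doses_mg = numeric(0)))
  expect_equal(nrow(s0), 0)
  # total = flank + D * (block + flank), blocks share flanks
  for (d in 1:4) for (bl in 1:3) for (fl in 0:2) {
    cfg <- subject_config("x", 5, tablet_doses_mg = seq_len(d),
                          sessions_per_dose_block = bl,
                          flank_placebo_count = fl)
    sch <- build_schedule(cfg)
    expect_equal(nrow(sch), fl + d * (bl + fl))
    expect_equal(sum(sch$treatment == "MPH"), d * bl)
    # between consecutive blocks there is exactly one shared flank run
    if (d >= 2 && fl > 0) {
      r <- rle(sch$treatment)
      expect_equal(r$lengths[r$values == "placebo"],
                   rep(fl, d + 1))
    }
  }
})

test_that("flanking sessions are the placebo runs touching the block", {
  sch <- build_schedule(subject_config("F", 5.8))
  expect_equal(flanking_sessions(sch, 1), c(1, 2, 6, 7))
  expect_equal(flanking_sessions(sch, 2), c(6, 7, 11, 12))
  expect_equal(flanking_sessions(sch, 5), c(21, 22, 26, 27))
})

test_that("mg_per_kg rounds half-up to 2 decimals and rejects bad input", {
  expect_equal(mg_per_kg(10, 5.8), 1.72)
  expect_equal(mg_per_kg(5, 7.5), 0.67)
  expect_equal(mg_per_kg(3.7, 3.7), 1.00)
  expect_equal(mg_per_kg(1.115, 1), 1.12)  # half-up, not banker's
  expect_error(mg_per_kg(0, 5), "positive")
  expect_error(mg_per_kg(5, -1), "positive")
})

test_that("simulate_behavior respects the outcome model", {
  m1 <- behavior_model(hit_prob = 1)
  tr <- simulate_behavior(placebo_spec(), m1, seed = 1, n_trials = 300)
  expect_true(all(tr$outcome == "hit"))
  # empirical hit rate within 3 binomial SEs of p
  p <- 0.63
  tr2 <- simulate_behavior(placebo_spec(), behavior_model(hit_prob = p),
                           seed = 2, n_trials = 10000)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(tr2$outcome == "hit") - p), 3 * se)
  # random-response policy over 4 targets: hit rate ~ 25%
  tr3 <- simulate_behavior(placebo_spec(),
                           behavior_model(random_policy = TRUE),
                           seed = 3, n_trials = 10000)
  expect_lt(abs(mean(tr3$outcome == "hit") - 0.25), 3 * sqrt(0.25 * 0.75 / 1e4))
})

test_that("simulated event times respect the task structure", {
  tr <- simulate_behavior(placebo_spec(), behavior_model(hit_prob = 0.6),
                          seed = 4, n_trials = 400)
  expect_true(all(tr$cue_off - tr$cue_on == 363))
  delay <- tr$change_time - tr$stimuli_on
  expect_true(all(is.na(delay) | (delay >= 585 & delay <= 1755)))
  expect_true(all(is.na(tr$change_time[tr$outcome == "fixation_break"])))
  resp <- !is.na(tr$saccade_time) & !is.na(tr$change_time)
  expect_true(all(tr$saccade_time[resp] - tr$change_time[resp] <= 250))
  expect_true(all(tr$trial_type %in%
                    c("target", "distractor", "target+distractor")))
  # trial types near-uniform over the three
  expect_gt(min(table(tr$trial_type)), 400 / 3 - 3 * sqrt(400 * 2 / 9))
})

test_that("same seed gives a bit-identical session", {
  ens <- tuned_ensemble(4)
  m <- behavior_model()
  a <- simulate_session(placebo_spec(), ens, m, seed = 99, n_trials = 60)
  b <- simulate_session(placebo_spec(), ens, m, seed = 99, n_trials = 60)
  expect_identical(a, b)
  c <- simulate_session(placebo_spec(), ens, m, seed = 100, n_trials = 60)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("null dose effects leave every generated quantity label-invariant", {
  ens <- tuned_ensemble(6, loadings = 1.5)
  m <- behavior_model()
  fx <- dose_effect_spec(5)  # all multipliers 1
  s_pb <- simulate_session(placebo_spec(), ens, m, fx, seed = 11,
                           n_trials = 400)
  s_d <- simulate_session(dose_spec(3), ens, m, fx, seed = 12,
                          n_trials = 400)
  ep <- canonical_epochs()$attention
  c_pb <- rowSums(extract_counts(s_pb, ep)$counts)
  c_d <- rowSums(extract_counts(s_d, ep)$counts)
  ks <- suppressWarnings(ks.test(c_pb, c_d))
  expect_gt(ks$p.value, 0.001)
  expect_gt(suppressWarnings(
    ks.test(s_pb$trials$change_time, s_d$trials$change_time))$p.value, 0.001)
})

test_that("zero-latent spike counts are Poisson (variance/mean ~ 1)", {
  ens <- ensemble_spec(neuron_spec("n1", "e1", 15))  # untuned, no latent
  s <- simulate_session(placebo_spec(), ens, behavior_model(hit_prob = 1),
                        seed = 21, n_trials = 600)
  cnt <- extract_counts(s, canonical_epochs()$baseline)$counts[, 1]
  ff <- var(cnt) / mean(cnt)
  expect_lt(abs(ff - 1), 3 * sqrt(2 / (length(cnt) - 1)))
})

test_that("independent neurons have mean pairwise noise r near 0", {
  ens <- make_ensemble(n_neurons = 10, n_electrodes = 10, loading_sd = 0,
                       seed = 5)
  s <- simulate_session(placebo_spec(), ens, behavior_model(hit_prob = 1),
                        seed = 22, n_trials = 300)
  pr <- noise_correlations(s, canonical_epochs()$attention)
  expect_gt(nrow(pr), 30)
  expect_lt(abs(mean(pr$noise_r)), 0.03)
})

test_that("shared-latent pair correlation matches the brute-force oracle", {
  # the correlation estimate itself has SE ~ 1/sqrt(n) ~ 0.02 at n = 2000,
  # so both the oracle and the generator estimate are averaged over
  # replicate runs of >= 2000 trials before the +/-0.02 comparison
  b <- 20; l <- 3; w <- 0.4; n <- 2000
  ens <- ensemble_spec(rbind(neuron_spec("a", "e1", b),
                             neuron_spec("b", "e2", b)),
                       latent_loadings = c(l, l))
  r_gen <- mean(vapply(31:34, function(seed) {
    s <- simulate_session(placebo_spec(), ens, behavior_model(hit_prob = 1),
                          seed = seed, n_trials = n)
    noise_correlations(s, canonical_epochs()$attention)$noise_r
  }, numeric(1)))
  # brute-force oracle: Poisson counts with the same latent mixture
  set.seed(777)
  r_oracle <- mean(replicate(30, {
    z <- rnorm(n)
    cor(rpois(n, pmax(b + l * z, 0) * w), rpois(n, pmax(b + l * z, 0) * w))
  }))
  r_closed <- l^2 * w^2 / (b * w + l^2 * w^2)
  expect_lt(abs(r_oracle - r_closed), 0.02)  # oracle vs closed form
  expect_lt(abs(r_gen - r_closed), 0.02)     # generator vs closed form
  expect_lt(abs(r_gen - r_oracle), 0.02)     # generator vs oracle
})

test_that("dose multipliers act only on treatment sessions", {
  fx <- dose_effect_spec(2, latent_loading_mult = c(1, 3))
  ens <- ensemble_spec(rbind(neuron_spec("a", "e1", 20),
                             neuron_spec("b", "e2", 20)),
                       latent_loadings = c(2, 2))
  m <- behavior_model(hit_prob = 1)
  r_of <- function(spec, seed) {
    s <- simulate_session(spec, ens, m, fx, seed = seed, n_trials = 1500)
    noise_correlations(s, canonical_epochs()$attention)$noise_r
  }
  r_pb <- r_of(placebo_spec(), 41)
  r_d2 <- r_of(dose_spec(2), 42)
  expect_gt(r_d2, r_pb + 0.1)  # loadings x3 => much stronger correlation
})
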