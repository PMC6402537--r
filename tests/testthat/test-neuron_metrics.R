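# The 19 response metrics: ground-truth recovery of the generator gains,
# symmetry and invariance properties, eligibility masking, and the dose
# scan's bookkeeping/power.  One shared 800-trial session (200 trials per
# condition) with 12 identical strongly tuned neurons serves the recovery
# tests; medians across neurons separate estimator bias from single-draw
# noise.

metrics_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ens <- tuned_ensemble(12, baseline = 20, visual_gain = 2,
                            attention_gain = 1.5, saccade_gain = 2,
                            latency = 120)
      s <- simulate_session(placebo_spec(), ens,
                            behavior_model(hit_prob = 1),
                            seed = 17, n_trials = 800)
      sel <- session_selectivity(s)
      cache <<- list(session = s, sel = sel,
                     metrics = compute_metrics(s, sel))
    }
    cache
  }
})

test_that("visual gain and latency are recovered (metrics 3 and 9)", {
  m <- metrics_fixture()$metrics
  expect_true(all(m$visual_selective))
  expect_lt(abs(median(m$metric_03) - 120), 30)  # within one kernel SD
  expect_lt(abs(median(m$metric_09) / 2 - 1), 0.10)
  # baseline metric recovers the generator baseline
  expect_lt(abs(median(m$metric_01) / 20 - 1), 0.10)
})

test_that("attentional gain is recovered (metric 14)", {
  m <- metrics_fixture()$metrics
  expect_true(all(m$attention_selective))
  expect_lt(abs(median(m$metric_14) / 1.5 - 1), 0.05)
})

test_that("saccade gain is recovered (metric 18)", {
  m <- metrics_fixture()$metrics
  expect_true(all(m$saccade_selective))
  expect_lt(abs(median(m$metric_18) / 2 - 1), 0.10)
})

test_that("symmetric responses give ratio metrics near 1", {
  # the generator applies the same visual gain to cue- and
  # distractor-elicited transients, so metric 5 is 1 by construction
  m <- metrics_fixture()$metrics
  expect_lt(abs(median(m$metric_05) - 1), 0.10)
  # distractor latency mirrors the cue latency
  expect_lt(abs(median(m$metric_07) - 120), 30)
})

test_that("latency metrics are invariant to uniform rate scaling", {
  lat_of <- function(baseline) {
    ens <- tuned_ensemble(4, baseline = baseline, visual_gain = 2.5,
                          latency = 130)
    s <- simulate_session(placebo_spec(), ens,
                          behavior_model(hit_prob = 1), seed = 18,
                          n_trials = 400)
    median(compute_metrics(s)$metric_03)
  }
  expect_lt(abs(lat_of(12) - lat_of(36)), 30)
})

test_that("non-selective neurons and silent denominators yield NA", {
  # untuned neuron: not selective anywhere, all metrics masked
  ens <- ensemble_spec(rbind(neuron_spec("flat", "e1", 10),
                             neuron_spec("tuned", "e2", 15, 2,
                                         visual_gain = 3)))
  s <- simulate_session(placebo_spec(), ens, behavior_model(hit_prob = 1),
                        seed = 19, n_trials = 400)
  m <- compute_metrics(s)
  flat <- m[m$neuron_id == "flat", ]
  expect_false(flat$visual_selective)
  expect_true(all(is.na(as.numeric(flat[sprintf("metric_%02d", 1:19)]))))
  # silent neuron with forced tuning: baseline 0, ratio metrics undefined
  tuning <- data.frame(neuron_id = "ghost", selective = TRUE,
                       preferred_quadrant = 1L,
                       anti_preferred_quadrant = 3L)
  v <- visual_metrics(s, "ghost", tuning)
  expect_equal(unname(v["metric_01"]), 0)
  expect_true(is.na(v["metric_05"]))
  expect_true(is.na(v["metric_09"]))
})

test_that("fano_factor uses the CV convention with a var/mean switch", {
  x <- c(8, 10, 12, 10, 9, 11)
  expect_equal(fano_factor(x), sd(x) / mean(x))
  expect_equal(fano_factor(x, "var_over_mean"), var(x) / mean(x))
  expect_true(is.na(fano_factor(c(0, 0, 0))))  # mean below epsilon
})

test_that("dose scan bookkeeping: 19 metrics x 2 subjects = 38 tests", {
  set.seed(20)
  tab <- null_metric_tables(n_neurons = 30)
  scan <- dose_effect_scan(tab)
  expect_equal(scan$m, 38)
  expect_equal(nrow(scan$tests), 38)
  expect_false(any(scan$tests$skipped))
  expect_true(all(scan$tests$p_bonferroni >= scan$tests$p_uncorrected,
                  na.rm = TRUE))
  # group stats cover every subject x metric x treatment cell
  expect_equal(nrow(scan$group_stats), 2 * 19 * 6)
  # subjects are never pooled: each test row is a single subject
  expect_setequal(unique(scan$tests$subject), c("F", "JL"))
})

test_that("an injected attention dose effect is detected by the scan", {
  set.seed(21)
  hits <- replicate(10, {
    tab <- null_metric_tables(n_neurons = 150)
    # dose 3 multiplies the attentional modulation ratio by 1.5
    sel <- tab$label == "dose_3"
    tab$metric_14[sel] <- tab$metric_14[sel] * 1.5
    scan <- dose_effect_scan(tab)
    sig <- scan$tests[scan$tests$metric == "metric_14", "significant"]
    all(sig)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("metric scan skips under-populated groups with a reason", {
  tab <- null_metric_tables(n_neurons = 3, labels = c("placebo", "dose_1"))
  tab$metric_02[tab$label == "dose_1"] <- NA  # nothing eligible at dose 1
  scan <- dose_effect_scan(tab)
  r <- scan$tests[scan$tests$metric == "metric_02", ]
  expect_true(all(r$skipped))
  expect_match(r$reason[1], "fewer than 2 treatment groups")
})
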