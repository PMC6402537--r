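# Pairwise correlations: exclusion rules, oracle agreement, sign-split
# summaries, and the signal-vs-noise correlation structure.

test_that("same-electrode pairs are excluded and pair counts are exact", {
  # 6 neurons on 3 electrodes: C(6,2) = 15 pairs, 3 same-electrode
  neurons <- do.call(rbind, lapply(1:6, function(i)
    neuron_spec(sprintf("n%d", i), sprintf("e%d", (i - 1) %/% 2 + 1), 15,
                preferred_quadrant = ((i - 1) %% 4) + 1, visual_gain = 2)))
  ens <- ensemble_spec(neurons)
  s <- simulate_session(placebo_spec(), ens, behavior_model(hit_prob = 1),
                        seed = 23, n_trials = 300)
  pr <- noise_correlations(s, canonical_epochs()$attention)
  expect_equal(nrow(pr), 15 - 3)
  expect_false(any(pr$electrode_i == pr$electrode_j))
  # brute-force recount
  emap <- setNames(s$electrode_map$electrode_id, s$electrode_map$neuron_id)
  combs <- combn(s$electrode_map$neuron_id, 2)
  expected <- sum(emap[combs[1, ]] != emap[combs[2, ]])
  expect_equal(nrow(pr), expected)
})

test_that("noise correlation is invariant to per-neuron affine rescaling", {
  set.seed(24)
  quad <- rep(1:4, each = 40)
  z <- rnorm(160)
  c1 <- rpois(160, pmax(8 + 2 * z, 0))
  c2 <- rpois(160, pmax(8 + 2 * z, 0))
  # manual reference: condition z-score then pool then Pearson
  zs <- function(x) ave(x, quad, FUN = function(v) (v - mean(v)) / sd(v))
  r_ref <- cor(zs(c1), zs(c2))
  r_scaled <- cor(zs(c1 * 7 + 3), zs(c2 * 0.5 + 11))
  expect_equal(r_scaled, r_ref, tolerance = 1e-12)
})

test_that("equal-loading pairs agree with the brute-force oracle", {
  b <- 18; l <- 2.5; w <- 0.4; n <- 2000
  ens <- ensemble_spec(rbind(neuron_spec("a", "e1", b),
                             neuron_spec("b", "e2", b)),
                       latent_loadings = c(l, l))
  # average replicate sessions: a single r estimate has SE ~ 0.02 itself
  r_gen <- mean(vapply(25:28, function(seed) {
    s <- simulate_session(placebo_spec(), ens, behavior_model(hit_prob = 1),
                          seed = seed, n_trials = n)
    noise_correlations(s, canonical_epochs()$attention)$noise_r
  }, numeric(1)))
  set.seed(26)
  r_oracle <- mean(replicate(20, {
    z <- rnorm(n)
    cor(rpois(n, pmax(b + l * z, 0) * w), rpois(n, pmax(b + l * z, 0) * w))
  }))
  expect_lt(abs(r_gen - r_oracle), 0.02)
})

test_that("signal correlations reflect tuning similarity", {
  # two neurons with identical tuning vectors, one mirrored, one flat
  quad <- rep(1:4, each = 30)
  lam_a <- c(12, 6, 6, 6)[quad]
  set.seed(27)
  counts <- cbind(a1 = rpois(120, lam_a), a2 = rpois(120, lam_a * 2),
                  b = rpois(120, rev(c(12, 6, 6, 6))[quad]),
                  flat = rep(5L, 120))
  cm <- count_matrix_stub(counts, quad)
  r <- signal_correlations(cm)
  expect_gt(r["a1", "a2"], 0.8)   # same preferred quadrant
  expect_lt(r["a1", "b"], 0)      # opposite tuning
  expect_true(all(is.na(r["flat", c("a1", "a2", "b")])))  # flat excluded
  # fewer than 4 conditions is an error
  expect_error(signal_correlations(count_matrix_stub(counts[quad < 4, ],
                                                     quad[quad < 4])),
               "4 conditions")
})

test_that("sign_split_summary medians, percent change, degenerate strata", {
  mk <- function(label, r, session_index = 1) {
    data.frame(session_index = session_index, label = label, epoch = "cue",
               neuron_i = "a", neuron_j = "b", electrode_i = "e1",
               electrode_j = "e2", noise_r = r, signal_r = 0,
               both_selective = TRUE, stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk("placebo", c(0.2, 0.4, -0.1, -0.3)),
                 mk("dose_1", c(0.3, 0.6, -0.2, -0.6)))
  sm <- sign_split_summary(pairs)
  expect_equal(sm$median_pos[sm$label == "placebo"], 0.3)
  expect_equal(sm$median_neg[sm$label == "placebo"], -0.2)
  expect_equal(sm$pct_change_pos[sm$label == "dose_1"],
               100 * (0.45 - 0.3) / 0.3)
  expect_equal(sm$pct_change_neg[sm$label == "dose_1"],
               100 * (-0.4 - (-0.2)) / 0.2)
  # identical dose distribution: percent change 0
  sm0 <- sign_split_summary(rbind(mk("placebo", c(0.2, -0.2)),
                                  mk("dose_1", c(0.2, -0.2))))
  expect_equal(sm0$pct_change_pos[2], 0)
  # all-positive pairs: negative stratum absent, no crash
  smp <- sign_split_summary(rbind(mk("placebo", c(0.1, 0.2)),
                                  mk("dose_1", c(0.15, 0.25))))
  expect_true(is.na(smp$median_neg[1]))
  expect_true(is.na(smp$pct_change_neg[2]))
  # pairs with r exactly 0 belong to neither stratum
  smz <- sign_split_summary(mk("placebo", c(0, 0.5, -0.5)))
  expect_equal(smz$n_pos, 1)
  expect_equal(smz$n_neg, 1)
})

test_that("an injected latent dose effect moves the positive median", {
  ens <- ensemble_spec(
    do.call(rbind, lapply(1:6, function(i)
      neuron_spec(sprintf("n%d", i), sprintf("e%d", i), 20))),
    latent_loadings = rep(2, 6))
  fx <- dose_effect_spec(1, latent_loading_mult = 1.6)
  m <- behavior_model(hit_prob = 1)
  pr_pb <- noise_correlations(
    simulate_session(placebo_spec(), ens, m, fx, seed = 28, n_trials = 700),
    canonical_epochs()$attention)
  pr_d <- noise_correlations(
    simulate_session(dose_spec(1, 2), ens, m, fx, seed = 29, n_trials = 700),
    canonical_epochs()$attention)
  pr_d$label <- "dose_1"
  sm <- sign_split_summary(rbind(pr_pb, pr_d))
  expect_gt(sm$pct_change_pos[sm$label == "dose_1"], 0)
})

test_that("correlation structure rises with tuning similarity", {
  ens <- make_ensemble(n_neurons = 30, n_electrodes = 30,
                       tuned_fraction = 1, loading_sd = 2,
                       tuning_coupled_loadings = TRUE, seed = 30)
  s <- simulate_session(placebo_spec(), ens, behavior_model(hit_prob = 1),
                        seed = 31, n_trials = 500)
  pr <- noise_correlations(s, canonical_epochs()$attention)
  st <- correlation_structure(pr)
  expect_gt(st$trend_spearman, 0.5)
  expect_equal(sum(st$curve$n), sum(!is.na(pr$signal_r)))
  expect_null(st$anova)  # single treatment group: ANOVA skipped
})

test_that("per-bin dose ANOVA reports eta squared under a null dose", {
  set.seed(32)
  n <- 3000
  mk <- function(label) data.frame(
    session_index = 1, label = label, epoch = "cue",
    neuron_i = "a", neuron_j = "b", electrode_i = "e1", electrode_j = "e2",
    noise_r = rnorm(n, 0.08, 0.1) , signal_r = runif(n, -1, 1),
    both_selective = TRUE, stringsAsFactors = FALSE)
  pairs <- rbind(mk("placebo"), mk("dose_1"), mk("dose_2"))
  st <- correlation_structure(pairs)
  expect_false(is.null(st$anova))
  expect_true(all(st$anova$eta_sq < 0.01, na.rm = TRUE))
})
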