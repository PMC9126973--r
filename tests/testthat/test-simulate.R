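test_that("sessions are bit-reproducible under a fixed seed", {
  cfg <- cohort_config("MST", seed = 77, n_neurons = 5)
  a <- simulate_session(cfg, n_trials = 60)
  b <- simulate_session(cfg, n_trials = 60)
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes$spike_times, b$spikes$spike_times)
  expect_identical(a$licks, b$licks)
  expect_identical(a$pupil, b$pupil)
})

test_that("behaviour follows the bivariate detection model across cohorts", {
  set.seed(1)
  trials <- sample_trial_sequence(2000, rng_seed = 2)

  # noncontingent exposure: visual 'hit' rate equals the catch response rate
  ne <- simulate_behavior(trials, cohort_config("NE"))
  p_vis <- mean(ne$outcome[ne$trial_type == "visual"] != "miss")
  p_catch <- mean(ne$outcome[ne$trial_type == "catch"] == "FA")
  n1 <- sum(ne$trial_type == "visual"); n2 <- sum(ne$trial_type == "catch")
  se_diff <- sqrt(p_vis * (1 - p_vis) / n1 + p_catch * (1 - p_catch) / n2)
  expect_lt(abs(p_vis - p_catch), 3 * se_diff + 0.02)

  # effectively infinite d-prime: maximal-saliency hits approach certainty
  strong <- cohort_config("MST", dprime_visual = c(thr = 8, max = 8))
  st <- simulate_behavior(trials, strong)
  vmax <- st$trial_type == "visual" & st$saliency == "max"
  expect_gt(mean(st$outcome[vmax] == "hit"), 0.95)

  # reaction times live inside the response window
  rts <- st$reaction_time[!is.na(st$reaction_time)]
  expect_true(all(rts > 0.1 & rts <= 1.5))

  # multisensory animals are slower than unisensory ones
  ust <- simulate_behavior(trials, cohort_config("UST"))
  mst <- simulate_behavior(trials, cohort_config("MST"))
  expect_gt(median(mst$reaction_time[mst$trial_type == "visual" &
                                       mst$outcome == "hit"], na.rm = TRUE),
            median(ust$reaction_time[ust$trial_type == "visual" &
                                       ust$outcome == "hit"], na.rm = TRUE))
})

test_that("generated d-prime is recovered by the detection-model fit", {
  cfg <- cohort_config("MST")
  err <- vapply(55:64, function(s) {
    tr <- simulate_behavior(sample_trial_sequence(600, rng_seed = s), cfg)
    fit <- fit_madc(count_responses(tr), n_starts = 5)
    fit$by_saliency[["max"]]$d_visual - cfg$dprime_visual[["max"]]
  }, numeric(1))
  # sessions of 600 trials estimate d-prime within sampling error (~0.15
  # SE per session); averaging 10 sessions isolates estimator bias
  expect_lt(abs(mean(err)), 0.15)
  expect_true(all(abs(err) < 0.5))
})

test_that("baseline spiking is Poisson-like when the shared gain is off", {
  cfg <- cohort_config("MST", seed = 3, n_neurons = 12,
                       nc_baseline_target = 1e-6)
  se <- simulate_session(cfg, n_trials = 80)
  tr <- se$trials
  # counts in a fixed pre-stimulus window across trials
  cnt <- vapply(se$spikes$spike_times, function(sp) {
    vapply(tr$change_time, function(ct)
      sum(sp >= ct - 0.9 & sp < ct - 0.1), numeric(1))
  }, numeric(nrow(tr)))
  fano <- apply(cnt, 2, var) / pmax(colMeans(cnt), 1e-9)
  expect_equal(mean(fano), 1, tolerance = 0.1)
})

test_that("without a late component, hit and miss rates agree after the transient", {
  cfg <- cohort_config("MST", seed = 19, n_neurons = 10,
                       late_gain_by_layer = c(SG = 0, G = 0, IG = 0))
  se <- simulate_session(cfg, n_trials = 150)
  tr <- se$trials
  tens <- compute_rates(se$spikes, tr$change_time, window = c(-1.2, 1.2))
  z <- zscore_rates(tens, baseline = c(-1, -0.2))
  late <- z$bin_centers >= 0.2 & z$bin_centers <= 1
  hits <- tr$trial_type == "visual" & tr$outcome == "hit"
  miss <- tr$trial_type == "visual" & tr$outcome == "miss"
  dz <- mean(z$values[!z$flagged, hits, late]) -
    mean(z$values[!z$flagged, miss, late])
  expect_lt(abs(dz), 0.1)
})

test_that("photostimulation silences spiking to a few percent of baseline", {
  cfg <- cohort_config("MST", seed = 23, n_neurons = 10)
  se <- simulate_session(cfg, n_trials = 120, photostim_frac = 0.5)
  tr <- se$trials
  tens <- compute_rates(se$spikes, tr$change_time, window = c(-1, 1))
  early_ps <- which(tr$photostim == "early")
  ctrl <- which(tr$photostim == "none")
  win <- tens$bin_centers > 0.1 & tens$bin_centers < 0.4
  base <- mean(tens$values[, ctrl, tens$bin_centers < -0.2])
  sil <- mean(tens$values[, early_ps, win])
  expect_lt(sil, 0.1 * base)
})

test_that("cohort pairs order reaction times and require the MST side to be slower", {
  cfgs <- list(u = cohort_config("UST", n_neurons = 3),
               m = cohort_config("MST", n_neurons = 3))
  pair <- simulate_cohort_pair(cfgs$u, cfgs$m, n_sessions = 2,
                               n_trials = 80, seed = 4)
  rt_of <- function(ss) median(unlist(lapply(ss, function(se)
    se$trials$reaction_time[se$trials$outcome == "hit"])), na.rm = TRUE)
  expect_gt(rt_of(pair$mst), rt_of(pair$ust))
  expect_error(simulate_cohort_pair(cfgs$m, cfgs$u, n_sessions = 1,
                                    n_trials = 80), "slower")
})
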