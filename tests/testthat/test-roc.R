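test_that("AUC equals the Mann-Whitney relation and separates perfectly separable rates", {
  set.seed(14)
  for (k in 1:100) {
    n1 <- sample(10:20, 1); n2 <- sample(10:20, 1)
    x <- rnorm(n1 + n2) + rep(c(0.5, 0), c(n1, n2))
    lab <- rep(c(TRUE, FALSE), c(n1, n2))
    a <- auc_timecourse(matrix(x, ncol = 1), lab, n_shuffle = 20)
    w <- suppressWarnings(
      wilcox.test(x[lab], x[!lab], exact = FALSE)$statistic)
    expect_equal(unname(a$auc_raw), unname(w / (n1 * n2)),
                 tolerance = 1e-12)
  }
  sep <- c(rnorm(12, 10), rnorm(12, -10))
  a <- auc_timecourse(matrix(sep, ncol = 1),
                      rep(c(TRUE, FALSE), each = 12), n_shuffle = 50)
  expect_equal(unname(a$auc), 1)

  # classes below the trial minimum are skipped
  expect_null(auc_timecourse(matrix(rnorm(15), ncol = 1),
                             rep(c(TRUE, FALSE), c(5, 10))))
})

test_that("the permutation test is calibrated near its nominal 1% level", {
  set.seed(15)
  sigs <- replicate(200, {
    r <- matrix(rnorm(40 * 3), 40, 3)
    auc_timecourse(r, rep(c(TRUE, FALSE), 20), n_shuffle = 500)$sig
  })
  expect_lt(mean(sigs), 0.03)
  # identical class distributions keep AUC near chance
  a <- auc_timecourse(matrix(rnorm(200), 100, 2), rep(c(TRUE, FALSE), 50),
                      n_shuffle = 200)
  expect_lt(max(a$auc), 0.65)
})

test_that("coder classification demands three consecutive significant bins", {
  mk <- function(sig) {
    structure(list(sig = sig, times = seq(0.0125, by = 0.025,
                                          length.out = length(sig))),
              class = "auc_series")
  }
  expect_true(classify_coder(mk(c(FALSE, TRUE, TRUE, TRUE, FALSE))))
  expect_false(classify_coder(mk(rep(c(TRUE, FALSE), 10))))
  expect_false(classify_coder(mk(rep(FALSE, 20))))
  # significant bins outside the window do not count
  late_only <- mk(c(rep(FALSE, 40), TRUE, TRUE, TRUE))
  expect_false(classify_coder(late_only, window = c(0, 1)))
  expect_null(NULL) # NULL series are simply not coders
  expect_false(classify_coder(NULL))
})

test_that("coding fractions count neurons and normalise only on a real rise", {
  times <- seq(-0.4875, 1.4875, by = 0.025)
  mk <- function(sig) structure(list(sig = sig, times = times),
                                class = "auc_series")
  flat <- replicate(10, mk(rep(FALSE, length(times))), simplify = FALSE)
  one_on <- flat
  on_bins <- times > 0.3
  one_on[[1]] <- mk(on_bins)
  cf <- coding_fraction(one_on)
  expect_equal(max(cf$fraction), 0.1)
  expect_equal(cf$fraction[times > 0.3][1], 0.1)
  # a 10% rise is exactly the normalisation threshold
  expect_true(cf$normalized_applied)
  expect_equal(max(cf$normalized), 1)

  cf_flat <- coding_fraction(flat)
  expect_false(cf_flat$normalized_applied)
  expect_true(all(cf_flat$fraction == 0))
})

test_that("onset detection finds steps, never fires on flat series, and is scale-free", {
  times <- seq(-0.4875, 1.4875, by = 0.025)
  flat <- rep(0.01, length(times))
  expect_true(is.na(onset_from_fraction(flat, times)$onset_s))

  step <- ifelse(times >= 0.3, 0.4, 0.01)
  on <- onset_from_fraction(step, times)
  expect_equal(on$onset_s, times[times >= 0.3][1], tolerance = 1e-9)
  expect_identical(unname(on$robustness), rep(on$onset_s, 3))

  # onsets from AUC series are invariant to scaling all rates
  se <- demo_session()
  tr <- se$trials
  vis <- which(tr$trial_type == "visual" & tr$outcome %in% c("hit", "miss"))
  tens <- compute_rates(se$spikes, tr$change_time[vis],
                        window = c(-0.5, 1.5), kernel_sd = 0.01,
                        bin_width = 0.025)
  lab <- tr$outcome[vis] == "hit"
  a1 <- auc_timecourse(tens$values[2, , ], lab, times = tens$bin_centers,
                       seed = 5, n_shuffle = 200)
  a2 <- auc_timecourse(tens$values[2, , ] * 7.3, lab,
                       times = tens$bin_centers, seed = 5, n_shuffle = 200)
  expect_identical(a1$auc, a2$auc)
  expect_identical(a1$sig, a2$sig)
})

test_that("bootstrap onsets are seeded, degenerate for identical neurons, and CI-covered", {
  times <- seq(-0.4875, 1.4875, by = 0.025)
  mk <- function(sig) structure(list(sig = sig, times = times),
                                class = "auc_series")
  same <- replicate(25, mk(times >= 0.4), simplify = FALSE)
  bo <- bootstrap_onset(same, n_boot = 200, seed = 3)
  expect_equal(unname(diff(bo$ci95)), 0)
  expect_equal(bo$onset_s, times[times >= 0.4][1], tolerance = 1e-9)
  bo2 <- bootstrap_onset(same, n_boot = 200, seed = 3)
  expect_identical(bo$onsets, bo2$onsets)
  expect_true(bo$onset_s >= bo$ci95[1] && bo$onset_s <= bo$ci95[2])
})

test_that("session onsets need ten neurons and find the population signal", {
  se <- demo_session()
  tr <- se$trials
  vis <- which(tr$trial_type == "visual" & tr$outcome %in% c("hit", "miss"))
  tens <- compute_rates(se$spikes, tr$change_time[vis],
                        window = c(-0.5, 1.5), kernel_sd = 0.01,
                        bin_width = 0.025)
  lab <- tr$outcome[vis] == "hit"
  expect_null(session_onset(tens, lab, min_neurons = 10))  # 8 < 10
  on <- session_onset(tens, lab, min_neurons = 5, n_shuffle = 400,
                      consec = 2, seed = 8)
  expect_false(is.null(on))
  expect_true(is.na(on$onset_s) || on$onset_s > 0)
})

test_that("laminar maps bin depth into 23 rows and smoothing conserves mass", {
  times <- seq(-0.4875, 0.9875, by = 0.025)
  mk <- function(sig) structure(list(sig = sig, times = times),
                                class = "auc_series")
  set.seed(6)
  n <- 60L
  series <- replicate(n, mk(runif(length(times)) < 0.2), simplify = FALSE)
  depths <- runif(n, 50, 1100)
  lm_ <- laminar_map(series, depths)
  expect_identical(dim(lm_$map), c(23L, length(times)))
  expect_identical(sum(lm_$counts), n)
  # interior mass is conserved by the normalised smoothing kernel
  interior_d <- 8:16; interior_t <- 20:40
  raw <- mean(lm_$map[interior_d, interior_t], na.rm = TRUE)
  sm <- mean(lm_$smoothed[interior_d, interior_t], na.rm = TRUE)
  expect_equal(sm, raw, tolerance = 0.05 * raw + 0.01)
})

test_that("onset-RT regression recovers algebraic relations", {
  rts <- c(0.35, 0.42, 0.5, 0.61, 0.68)
  reg <- onset_rt_regression(rts - 0.28, rts, fixed_slope = 1)
  expect_equal(reg$offset_s, 0.28)
  reg0 <- onset_rt_regression(rep(0.2, 5), rts)
  expect_equal(reg0$slope, 0, tolerance = 1e-12)
  expect_error(onset_rt_regression(c(0.1, 0.2), c(0.3, 0.4)), "3")
})
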