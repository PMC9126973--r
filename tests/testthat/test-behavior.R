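test_that("cumulative-normal psychometric has the right landmarks", {
  f0 <- list(gamma = 0, lambda = 0, mu = 10, sigma = 4)
  expect_equal(cumnorm_psychometric(10, f0), 0.5)
  expect_equal(cumnorm_psychometric(1e6, list(gamma = 0, lambda = 0.1,
                                              mu = 10, sigma = 4)), 0.9)
  expect_equal(cumnorm_psychometric(10, list(gamma = 0.1, lambda = 0.1,
                                             mu = 10, sigma = 4)), 0.5)
  expect_error(cumnorm_psychometric(1, list(gamma = 0.6, lambda = 0.6,
                                            mu = 0, sigma = 1)), "invalid")
})

test_that("psychometric fitting recovers generating parameters and saliency levels", {
  set.seed(42)
  truth <- c(gamma = 0.1, lambda = 0.05, mu = 10, sigma = 4)
  x <- c(2, 5, 8, 10, 12, 15, 20, 30)
  p <- truth["gamma"] + (1 - truth["gamma"] - truth["lambda"]) *
    pnorm(x, truth["mu"], truth["sigma"])
  fit <- fit_cumnorm(x, rbinom(length(x), 500, p), rep(500, length(x)))
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - 10), 1)
  expect_lt(abs(fit$sigma - 4), 1.5)
  expect_lt(abs(fit$gamma - 0.1), 0.05)
  expect_lt(abs(fit$lambda - 0.05), 0.05)
  expect_equal(unname(fit$saliency_levels["sub"]), fit$mu - fit$sigma)
  expect_equal(unname(fit$saliency_levels["thr"]), fit$mu)
  expect_equal(unname(fit$saliency_levels["sup"]), fit$mu + fit$sigma)

  # perfect step data: slope collapses to the optimiser floor, not below
  step <- as.integer(x > 10) * 300
  sfit <- fit_cumnorm(x, step, rep(300, length(x)))
  expect_gte(sfit$sigma, 1e-3)
})

test_that("m-ADC response table is a proper conditional distribution", {
  tab <- madc_rates(1.2, 2.1, 0.4, 0.7)
  expect_equal(rowSums(tab), c(visual = 1, auditory = 1, catch = 1),
               tolerance = 1e-9)
  # no-go certain when both criteria are unreachable
  far <- madc_rates(0, 0, 50, 50)
  expect_equal(unname(far[, "nogo"]), c(1, 1, 1), tolerance = 1e-9)
  # symmetric parameters give symmetric catch-trial responses
  sym <- madc_rates(1.5, 1.5, 0.5, 0.5)
  expect_equal(sym["catch", "visual"], sym["catch", "auditory"],
               tolerance = 1e-9)
  expect_error(madc_rates(-0.1, 1, 0, 0), ">= 0")
})

test_that("m-ADC table matches brute-force Monte-Carlo simulation of the decision rule", {
  set.seed(7)
  n <- 2e5
  for (rep in 1:4) {
    d_v <- runif(1, 0, 3); d_a <- runif(1, 0, 3)
    c_v <- runif(1, -0.5, 1.5); c_a <- runif(1, -0.5, 1.5)
    tab <- madc_rates(d_v, d_a, c_v, c_a)
    for (row in c("visual", "auditory", "catch")) {
      mu <- switch(row, visual = c(d_v, 0), auditory = c(0, d_a),
                   catch = c(0, 0))
      pv <- rnorm(n, mu[1]); pa <- rnorm(n, mu[2])
      rv <- pv >= c_v & (pv - c_v) >= (pa - c_a)
      ra <- pa >= c_a & (pa - c_a) > (pv - c_v)
      mc <- c(mean(rv), mean(ra), mean(!rv & !ra))
      se <- sqrt(pmax(mc * (1 - mc), 1e-12) / n)
      expect_true(all(abs(tab[row, ] - mc) <= 3 * se + 1e-4),
                  info = sprintf("row %s, pars %.2f %.2f %.2f %.2f",
                                 row, d_v, d_a, c_v, c_a))
    }
  }
})

test_that("m-ADC fitting recovers d-prime and criterion and requires catch trials", {
  set.seed(11)
  errs <- replicate(15, {
    cnt <- draw_madc_counts(1.2, 1.8, 0.4, 0.6)
    f <- fit_madc(cnt, n_starts = 5)$by_saliency[["thr"]]
    c(f$d_visual - 1.2, f$d_auditory - 1.8,
      f$c_visual - 0.4, f$c_auditory - 0.6)
  })
  bias <- rowMeans(errs)
  expect_lt(abs(bias[1]), 0.15)
  expect_lt(abs(bias[2]), 0.15)
  expect_lt(abs(bias[3]), 0.10)
  expect_lt(abs(bias[4]), 0.10)

  no_catch <- draw_madc_counts(1, 1, 0.5, 0.5)
  no_catch <- no_catch[no_catch$trial_type != "catch", ]
  expect_error(fit_madc(no_catch), "catch")
})

test_that("hyperbolic d-prime psychometric has its algebraic landmarks", {
  expect_equal(hyperbolic_dprime(5, d_max = 2.4, n = 1.7, s50 = 5), 1.2)
  expect_equal(hyperbolic_dprime(0, 2.4, 1.7, 5), 0)
  # nondecreasing in x for arbitrary valid parameters
  set.seed(2)
  for (k in 1:20) {
    dm <- runif(1, 0.5, 4); nn <- runif(1, 0.3, 4); s <- runif(1, 0.5, 30)
    x <- sort(runif(50, 0, 100))
    expect_true(all(diff(hyperbolic_dprime(x, dm, nn, s)) >= -1e-12))
  }
})

test_that("d-prime from rates matches the inverse-normal oracle and is antisymmetric", {
  # oracle: qnorm via erfinv
  erfinv_q <- function(p) sqrt(2) * pracma::erfinv(2 * p - 1)
  expect_equal(dprime_from_rates(0.84, 0.16),
               erfinv_q(0.84) - erfinv_q(0.16), tolerance = 1e-9)
  expect_equal(dprime_from_rates(0.84, 0.16), 1.98891, tolerance = 1e-4)
  expect_equal(dprime_from_rates(0.5, 0.5), 0)
  expect_equal(dprime_from_rates(0.3, 0.3), 0)
  set.seed(3)
  for (k in 1:20) {
    h <- runif(1, 0.01, 0.99); f <- runif(1, 0.01, 0.99)
    expect_equal(dprime_from_rates(h, f), -dprime_from_rates(f, h))
  }
  # 1/(2N) correction at the boundary needs the trial count
  expect_error(dprime_from_rates(1, 0.2), "trial count")
  expect_equal(dprime_from_rates(1, 0.2, n_signal = 50),
               qnorm(1 - 1 / 100) - qnorm(0.2))
})

test_that("multinomial side-detection model normalises and refits its own draws", {
  fit0 <- list(b_right = -0.5, b_left = -1, sL_right = 0.2, sR_right = 2,
               sL_left = 2.2, sR_left = 0.1, n_exp = 0.7)
  # no stimulus: odds against no-go reduce to the bias terms
  p0 <- mnlogit_probs(0, 0, fit0)
  expect_equal(unname(p0[1, "p_right"] / p0[1, "p_nogo"]),
               exp(fit0$b_right))
  set.seed(5)
  cL <- runif(50, 0, 1); cR <- runif(50, 0, 1)
  pr <- mnlogit_probs(cL, cR, fit0)
  expect_equal(unname(rowSums(pr)), rep(1, 50), tolerance = 1e-12)

  # simulate choices and refit
  cL <- sample(c(0, 0.25, 0.5, 1), 2000, replace = TRUE)
  cR <- sample(c(0, 0.25, 0.5, 1), 2000, replace = TRUE)
  pr <- mnlogit_probs(cL, cR, fit0)
  ch <- vapply(seq_len(2000), function(i)
    sample(c("left", "right", "nogo"), 1, prob = pr[i, ]), character(1))
  refit <- fit_mnlogit(cL, cR, ch, n_starts = 5)
  expect_true(refit$converged)
  pr_hat <- predict(refit, c(0, 0.5, 1), c(0, 0, 1))
  pr_true <- mnlogit_probs(c(0, 0.5, 1), c(0, 0, 1), fit0)
  expect_lt(max(abs(pr_hat - pr_true)), 0.08)
})

test_that("artificial catch insertion respects ITI statistics and matches FA latencies to hit RTs", {
  se <- demo_session()
  tr <- se$trials
  aug <- insert_artificial_catch(tr, se$licks$time_s)
  ins <- aug[aug$inserted_catch %in% TRUE, ]
  expect_gt(nrow(ins), 0)
  expect_true(all(ins$trial_type == "catch"))
  expect_true(all(ins$saliency == "none"))
  # inserted events keep their distance from real changes
  dists <- vapply(ins$change_time, function(tc)
    min(abs(tc - tr$change_time)), numeric(1))
  expect_true(all(dists >= 3))

  # with no licks at all, every inserted trial is a correct rejection
  quiet <- insert_artificial_catch(tr, numeric(0))
  qi <- quiet[quiet$inserted_catch %in% TRUE, ]
  expect_true(all(qi$outcome == "CR"))

  # latency matching shrinks the KS distance to the hit RT distribution
  set.seed(13)
  hit_rt <- tr$reaction_time[tr$outcome == "hit" & !is.na(tr$reaction_time)]
  # unmatched FA latencies: uniform spontaneous licking
  fa_unmatched <- runif(300, 0.1, 1.5)
  ks_before <- suppressWarnings(ks.test(fa_unmatched, hit_rt)$statistic)
  dense_licks <- sort(runif(4000, 0, max(tr$change_time)))
  aug2 <- insert_artificial_catch(tr, dense_licks)
  fa_lat <- aug2$reaction_time[aug2$inserted_catch %in% TRUE &
                                 aug2$outcome == "FA"]
  expect_gt(length(fa_lat), 5)
  ks_after <- suppressWarnings(ks.test(fa_lat, hit_rt)$statistic)
  expect_lt(ks_after, ks_before)
})

test_that("session filters trim non-responsive tails and exclude poor sessions", {
  se <- demo_session()
  tr <- se$trials
  # append 25 no-response trials
  tail25 <- tr[rep(nrow(tr), 25), ]
  tail25$choice <- "none"; tail25$outcome <- "miss"
  tail25$change_time <- max(tr$change_time) + seq_len(25) * 6
  ext <- rbind(tr, tail25)
  out <- session_filters(ext)
  expect_lte(nrow(out$trials), nrow(tr))
  expect_true(any(grepl("trimmed", out$reasons)))

  # a session detecting 95% of maximal changes stays in
  expect_true(session_filters(tr, modalities = "visual")$included)
  # force the max-saliency hit rate below 30%
  bad <- tr
  vmax <- bad$trial_type == "visual" & bad$saliency == "max"
  bad$outcome[vmax] <- ifelse(seq_len(sum(vmax)) <= ceiling(0.75 * sum(vmax)),
                              "miss", "hit")
  bad$choice[bad$outcome == "miss" & vmax] <- "none"
  expect_false(session_filters(bad, modalities = "visual")$included)
})
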