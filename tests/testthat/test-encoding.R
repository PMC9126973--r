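test_that("raised-cosine bases tile their span as a partition of unity", {
  b <- raised_cosine_basis(10, c(0, 2))
  t_int <- seq(0.21, 1.79, by = 0.01)  # interior of the span
  sums <- rowSums(b$eval(t_int))
  expect_true(all(sums >= 0.99 & sums <= 1.01))
  vals <- b$eval(seq(-0.5, 2.5, by = 0.01))
  expect_true(all(vals >= 0 & vals <= 1))

  one <- raised_cosine_basis(1, c(0, 0.2))
  tt <- seq(0, 0.2, by = 0.001)
  v <- one$eval(tt)
  expect_equal(tt[which.max(v)], 0.1)

  expect_error(raised_cosine_basis(3, c(1, 1)), "span")
})

test_that("the full design matrix has the published family arithmetic", {
  se <- demo_session()
  des <- build_design(se$trials, se$licks, se$pupil)
  fam <- table(des$family)
  expect_identical(unname(fam[["sensory"]]), 96L)
  expect_identical(unname(fam[["hit"]]), 20L)
  expect_identical(unname(fam[["movement"]]), 6L)
  expect_identical(unname(fam[["pupil"]]), 3L)
  expect_identical(unname(fam[["trial_number"]]), 1L)
  expect_identical(ncol(des$X), 126L)

  # every populated column is scaled to maximum magnitude one
  mx <- apply(abs(des$X), 2, max)
  expect_true(all(mx %in% c(0, 1) | abs(mx - 1) < 1e-12))

  # split-hit layout keeps the total at 126
  des2 <- build_design(se$trials, se$licks, se$pupil,
                       split_hit_by_modality = TRUE)
  expect_identical(ncol(des2$X), 126L)

  # null model: a single random column
  dn <- build_design(se$trials, null_model = TRUE, seed = 3)
  expect_identical(ncol(dn$X), 1L)

  # missing pupil: family zeroed and flagged
  dp <- build_design(se$trials, se$licks, pupil = NULL)
  expect_true(dp$pupil_missing)
  expect_true(all(dp$X[, dp$family == "pupil"] == 0))
})

test_that("elastic-net fit is deterministic, per-trial folded, and shrinks to zero at high lambda", {
  se <- demo_session()
  tr <- se$trials[1:80, ]
  des <- build_design(tr, se$licks, se$pupil)
  Y <- bin_spike_counts(se$spikes$spike_times[[1]], tr, des$window,
                        des$bin_width)
  fit <- fit_poisson_elasticnet(des, Y, seed = 4)
  expect_true(fit$converged)

  # folds partition rows and never split a trial
  expect_identical(length(fit$foldid), nrow(des$X))
  per_trial_folds <- tapply(fit$foldid, des$row_trial,
                            function(f) length(unique(f)))
  expect_true(all(per_trial_folds == 1))
  expect_setequal(unique(fit$foldid), 1:5)

  # identical seed, identical fit
  fit2 <- fit_poisson_elasticnet(des, Y, seed = 4)
  expect_identical(fit$foldid, fit2$foldid)
  expect_identical(fit$beta, fit2$beta)

  # at the top of the regularisation path all coefficients vanish
  top <- as.numeric(glmnet::coef.glmnet(fit$cv$glmnet.fit,
                                        s = max(fit$cv$lambda)))[-1]
  expect_true(all(top == 0))
})

test_that("the fit recovers the support of planted sparse kernel weights", {
  se <- demo_session()
  tr <- se$trials
  des <- build_design(tr, se$licks, se$pupil)
  set.seed(21)
  # plant coefficients in three groups: early sensory, hit, movement
  beta <- numeric(ncol(des$X))
  names(beta) <- colnames(des$X)
  active <- list(
    sens = grep("sens_visual_max_AB", names(beta)),
    hit = grep("hit_stim", names(beta)),
    mov = grep("lick_left", names(beta)))
  beta[active$sens] <- 1.2
  beta[active$hit] <- 1.0
  beta[active$mov] <- 0.8
  eta <- log(8 * des$bin_width) + as.numeric(des$X %*% beta)
  Y <- rpois(length(eta), exp(eta))
  fit <- fit_poisson_elasticnet(des, Y, seed = 6)
  got <- vapply(active, function(ix) any(fit$beta[-1][ix] != 0), logical(1))
  expect_gte(mean(got), 0.8)
  # and coefficients in the active groups are predominantly positive
  expect_gt(sum(fit$beta[-1][unlist(active)]), 0)
})

test_that("explained variance has its fixed points and family subsets behave", {
  y <- c(rpois(500, 3))
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, rep(mean(y), 500)), 0)
  expect_true(is.na(explained_variance(rep(2, 10), rep(2, 10))))

  se <- demo_session()
  tr <- se$trials[1:80, ]
  des <- build_design(tr, se$licks, se$pupil)
  Y <- bin_spike_counts(se$spikes$spike_times[[2]], tr, des$window,
                        des$bin_width)
  fit <- fit_poisson_elasticnet(des, Y, seed = 9)
  all_fams <- levels(des$family)
  ev_full <- explained_variance(Y, fit$Yhat)
  ev_all <- subset_ev(des, fit, all_fams, Y)
  expect_equal(ev_all, ev_full, tolerance = 1e-10)
  # intercept-only prediction explains (almost) nothing
  ev_none <- subset_ev(des, fit, character(0), Y)
  expect_lt(abs(ev_none), 0.02)
  expect_error(subset_ev(des, fit, "arousalz", Y), "unknown")
})
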