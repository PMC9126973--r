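## Behavioral models: cumulative-normal psychometric, multi-alternative
## signal-detection (m-ADC) response model, multinomial logistic side-detection
## model, d-prime from rates, artificial catch insertion, session filters and
## silencing-effect quantification.

#' Cumulative-normal psychometric function
#'
#' Response probability as a function of stimulus change magnitude:
#' `gamma + (1 - gamma - lambda) * pnorm(x, mu, sigma)`, where `gamma` is the
#' false-alarm (guess) rate, `lambda` the lapse rate, `mu` the perceptual
#' threshold and `sigma` the slope of the psychometric function.
#'
#' @param x Stimulus change magnitude (degrees or partial octaves).
#' @param fit A `psychfit` object or a named list/vector with `gamma`,
#'   `lambda`, `mu`, `sigma`.
#' @return Response probability, same length as `x`.
#' @export
cumnorm_psychometric <- function(x, fit) {
  p <- as.list(unlist(fit[c("gamma", "lambda", "mu", "sigma")]))
  if (any(vapply(p, is.null, TRUE)) || p$sigma <= 0 ||
      p$gamma < 0 || p$lambda < 0 || p$gamma + p$lambda >= 1) {
    stop("invalid psychometric parameters")
  }
  p$gamma + (1 - p$gamma - p$lambda) * stats::pnorm(x, mean = p$mu, sd = p$sigma)
}

#' Fit the cumulative-normal psychometric function
#'
#' Maximum-likelihood (binomial) fit of the four-parameter cumulative normal
#' to response counts per stimulus level.  Also reports the conventional
#' saliency levels along the fitted curve: subthreshold (`mu - sigma`),
#' threshold (`mu`), suprathreshold (`mu + sigma`) and maximal (largest
#' tested level).
#'
#' @param x_levels Stimulus change magnitudes (at least 4 distinct values).
#' @param n_resp Number of response (lick) trials per level.
#' @param n_trials Number of trials per level.
#' @param n_starts Number of optimiser restarts.
#' @return A `psychfit` object with elements `gamma`, `lambda`, `mu`,
#'   `sigma`, `logLik`, `converged`, `saliency_levels`.
#' @export
fit_cumnorm <- function(x_levels, n_resp, n_trials, n_starts = 10) {
  stopifnot(length(x_levels) == length(n_resp),
            length(n_resp) == length(n_trials))
  if (length(unique(x_levels)) < 4) {
    stop("need at least 4 distinct stimulus levels")
  }
  xr <- range(x_levels)
  nll <- function(par) {
    p <- par["gamma"] +
      (1 - par["gamma"] - par["lambda"]) *
        stats::pnorm(x_levels, par["mu"], par["sigma"])
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(stats::dbinom(n_resp, n_trials, p, log = TRUE))
  }
  lower <- c(gamma = 0, lambda = 0, mu = xr[1] - diff(xr), sigma = 1e-3)
  upper <- c(gamma = 0.5, lambda = 0.5, mu = xr[2] + diff(xr),
             sigma = 10 * diff(xr))
  best <- NULL
  base <- c(gamma = max(min(n_resp / n_trials) , 0.01),
            lambda = 0.05, mu = stats::median(x_levels), sigma = diff(xr) / 4)
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) base else pmin(pmax(
      base * exp(stats::rnorm(4, 0, 0.3)), lower + 1e-6), upper - 1e-6)
    names(start) <- names(base)
    o <- try(stats::optim(start, nll, method = "L-BFGS-B",
                          lower = lower, upper = upper), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, diagnostics = "no start converged"),
                     class = "psychfit"))
  }
  par <- best$par
  structure(list(
    gamma = unname(par["gamma"]), lambda = unname(par["lambda"]),
    mu = unname(par["mu"]), sigma = unname(par["sigma"]),
    logLik = -best$value, converged = best$convergence == 0,
    saliency_levels = c(sub = unname(par["mu"] - par["sigma"]),
                        thr = unname(par["mu"]),
                        sup = unname(par["mu"] + par["sigma"]),
                        max = max(x_levels)),
    x_levels = x_levels, n_resp = n_resp, n_trials = n_trials),
    class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("psychometric fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Cumulative-normal psychometric fit\n  gamma=%.3f lambda=%.3f mu=%.3g sigma=%.3g  logLik=%.2f\n",
    x$gamma, x$lambda, x$mu, x$sigma, x$logLik))
  cat(sprintf("  saliency levels: sub=%.3g thr=%.3g sup=%.3g max=%.3g\n",
              x$saliency_levels["sub"], x$saliency_levels["thr"],
              x$saliency_levels["sup"], x$saliency_levels["max"]))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(gamma = object$gamma, lambda = object$lambda,
    mu = object$mu, sigma = object$sigma)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$logLik, df = 4, class = "logLik")
}

#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x_levels else newdata
  cumnorm_psychometric(x, object)
}

#' @export
plot.psychfit <- function(x, ...) {
  xs <- seq(min(x$x_levels), max(x$x_levels), length.out = 200)
  graphics::plot(x$x_levels, x$n_resp / x$n_trials, xlab = "stimulus change",
                 ylab = "response rate", ylim = c(0, 1), ...)
  graphics::lines(xs, cumnorm_psychometric(xs, x))
  invisible(x)
}

## ---- m-ADC response model ---------------------------------------------------

# Gauss-Legendre nodes/weights cache on [0, 1]
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n = 80) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}

# P(respond m) for evidence Psi_m ~ N(mu_m, 1), Psi_o ~ N(mu_o, 1) independent,
# response rule: Psi_m >= c_m and Psi_m - c_m >= Psi_o - c_o.
# = int_{c_m}^inf dnorm(x - mu_m) * pnorm(x - c_m + c_o - mu_o) dx
.madc_p_respond <- function(mu_m, mu_o, c_m, c_o, n_nodes = 80) {
  gl <- .gl_nodes(n_nodes)
  hi <- max(c_m, mu_m) + 8
  if (hi <= c_m) return(0)
  x <- c_m + (hi - c_m) * gl$x
  w <- (hi - c_m) * gl$w
  sum(w * stats::dnorm(x - mu_m) * stats::pnorm(x - c_m + c_o - mu_o))
}

#' Response-probability table of the multi-alternative detection model
#'
#' Under the bivariate-evidence model, each trial yields independent
#' standard-normal evidence on the visual and auditory axes; a stimulated
#' modality adds its d-prime to the mean of its axis.  The observer responds
#' to modality m iff the evidence on that axis exceeds the modality's
#' criterion `c_m` and its criterion-relative evidence exceeds the other
#' axis's (`Psi_m - c_m >= Psi_o - c_o`); otherwise no-go.  Probabilities are
#' computed by one-dimensional Gauss-Legendre integration.
#'
#' @param d_visual,d_auditory d-prime of the stimulated modality (>= 0).
#' @param c_visual,c_auditory Decision criteria.
#' @return A 3x3 matrix, rows = trial type (`visual`, `auditory`, `catch`),
#'   columns = response (`visual`, `auditory`, `nogo`); each row sums to 1.
#' @export
madc_rates <- function(d_visual, d_auditory, c_visual, c_auditory) {
  if (d_visual < 0 || d_auditory < 0) stop("d-prime must be >= 0")
  row_for <- function(mu_v, mu_a) {
    pv <- .madc_p_respond(mu_v, mu_a, c_visual, c_auditory)
    pa <- .madc_p_respond(mu_a, mu_v, c_auditory, c_visual)
    c(visual = pv, auditory = pa, nogo = 1 - pv - pa)
  }
  out <- rbind(
    visual = row_for(d_visual, 0),
    auditory = row_for(0, d_auditory),
    catch = row_for(0, 0))
  colnames(out) <- c("visual", "auditory", "nogo")
  out
}

#' Tabulate responses of a trial table for signal-detection fitting
#'
#' @param trials A `trial_table` with outcomes filled.  Multimodal (conflict)
#'   trials are excluded.
#' @return Data frame with columns `trial_type`, `saliency`, `response`
#'   (`visual`/`auditory`/`nogo`) and `n`.
#' @export
count_responses <- function(trials) {
  t2 <- trials[trials$trial_type %in% c("visual", "auditory", "catch"), ]
  resp <- ifelse(is.na(t2$choice) | t2$choice == "none", "nogo",
                 ifelse(t2$choice == "left", "visual", "auditory"))
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(t2))),
    by = list(trial_type = t2$trial_type, saliency = t2$saliency,
              response = resp), FUN = sum)
  agg
}

.madc_nll <- function(counts, d_v, d_a, c_v, c_a) {
  tab <- madc_rates(d_v, d_a, c_v, c_a)
  p <- tab[cbind(counts$trial_type, counts$response)]
  p <- pmin(pmax(p, 1e-12), 1)
  -sum(counts$n * log(p))
}

#' Fit the multi-alternative signal-detection model
#'
#' Multinomial maximum-likelihood fit of d-prime and criterion to response
#' counts, with catch trials anchoring the criteria.  Two variants:
#' `"two-level"` fits (d'_v, d'_a, c_v, c_a) separately for each saliency
#' level (threshold and maximal), reusing the catch trials in each fit;
#' `"hyperbolic"` fits a criterion per modality plus a three-parameter
#' hyperbolic d-prime psychometric
#' `d_i = d_max * x_i^n / (x_i^n + s50^n)` per modality (8 parameters),
#' which requires numeric saliencies.
#'
#' For visual fits in degrees, a fitted threshold (`s50` of the hyperbolic
#' variant) below 1 or above 45 degrees marks the fit invalid.
#'
#' @param counts Data frame as produced by [count_responses()]: columns
#'   `trial_type` (`visual`/`auditory`/`catch`), `saliency`, `response`, `n`.
#'   For the hyperbolic variant, `saliency` must be numeric stimulus change
#'   magnitudes (with catch trials at `saliency` `"none"` or 0).
#' @param variant `"two-level"` or `"hyperbolic"`.
#' @param n_starts Optimiser restarts (multi-start bounded quasi-Newton).
#' @param seed Seed controlling the restart jitter.
#' @return An object of class `"madc_fit"`.
#' @export
fit_madc <- function(counts, variant = c("two-level", "hyperbolic"),
                     n_starts = 10, seed = 1) {
  variant <- match.arg(variant)
  if (!any(counts$trial_type == "catch")) {
    stop("catch trials are required: criterion is unidentifiable without them")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  optim_ms <- function(start, nll, lower, upper) {
    best <- NULL
    for (s in seq_len(n_starts)) {
      st <- if (s == 1) start else {
        jit <- start + stats::rnorm(length(start), 0, 0.5)
        pmin(pmax(jit, lower + 1e-6), upper - 1e-6)
      }
      o <- try(stats::optim(st, nll, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }

  catch_counts <- counts[counts$trial_type == "catch", ]
  if (variant == "two-level") {
    levels_s <- setdiff(unique(counts$saliency[counts$trial_type != "catch"]),
                        c("none", NA))
    fits <- list()
    for (s in levels_s) {
      sub <- rbind(counts[counts$trial_type != "catch" & counts$saliency == s, ],
                   catch_counts)
      nll <- function(par) .madc_nll(sub, par[1], par[2], par[3], par[4])
      start <- c(d_v = 1, d_a = 1, c_v = 0.5, c_a = 0.5)
      best <- optim_ms(start, nll, lower = c(0, 0, -3, -3),
                       upper = c(8, 8, 6, 6))
      fits[[as.character(s)]] <- list(
        d_visual = best$par[[1]], d_auditory = best$par[[2]],
        c_visual = best$par[[3]], c_auditory = best$par[[4]],
        logLik = -best$value, converged = best$convergence == 0)
    }
    out <- list(variant = variant, by_saliency = fits,
                n_trials = sum(counts$n), valid = TRUE)
  } else {
    sal <- suppressWarnings(as.numeric(counts$saliency))
    if (any(is.na(sal) & counts$trial_type != "catch")) {
      stop("hyperbolic variant needs numeric saliencies")
    }
    counts$x <- ifelse(counts$trial_type == "catch", 0, sal)
    nll <- function(par) {
      # par: dmax_v, n_v, s50_v, c_v, dmax_a, n_a, s50_a, c_a
      total <- 0
      for (i in seq_len(nrow(counts))) {
        x <- counts$x[i]; tt <- counts$trial_type[i]
        d_v <- if (tt == "visual") hyperbolic_dprime(x, par[1], par[2], par[3]) else 0
        d_a <- if (tt == "auditory") hyperbolic_dprime(x, par[5], par[6], par[7]) else 0
        tab <- madc_rates(d_v, d_a, par[4], par[8])
        row <- if (tt == "catch") "catch" else tt
        p <- max(tab[row, counts$response[i]], 1e-12)
        total <- total - counts$n[i] * log(p)
      }
      total
    }
    xs <- counts$x[counts$trial_type == "visual"]
    s50_0 <- if (length(xs)) stats::median(xs) else 1
    start <- c(2, 1.5, s50_0, 0.5, 2, 1.5, s50_0, 0.5)
    best <- optim_ms(start, nll,
                     lower = c(0, 0.2, 1e-3, -3, 0, 0.2, 1e-3, -3),
                     upper = c(8, 6, 1e3, 6, 8, 6, 1e3, 6))
    par <- best$par
    valid <- par[3] >= 1 && par[3] <= 45
    out <- list(variant = variant,
                visual = list(d_max = par[1], n = par[2], s50 = par[3],
                              c = par[4]),
                auditory = list(d_max = par[5], n = par[6], s50 = par[7],
                                c = par[8]),
                logLik = -best$value, converged = best$convergence == 0,
                n_trials = sum(counts$n), valid = valid)
  }
  structure(out, class = "madc_fit")
}

#' @export
print.madc_fit <- function(x, ...) {
  cat("Multi-alternative signal-detection fit (", x$variant, " variant)\n",
      sep = "")
  if (x$variant == "two-level") {
    for (s in names(x$by_saliency)) {
      f <- x$by_saliency[[s]]
      cat(sprintf("  %s: d'_v=%.2f d'_a=%.2f c_v=%.2f c_a=%.2f  logLik=%.1f\n",
                  s, f$d_visual, f$d_auditory, f$c_visual, f$c_auditory,
                  f$logLik))
    }
  } else {
    cat(sprintf("  visual:   d_max=%.2f n=%.2f s50=%.3g c=%.2f\n",
                x$visual$d_max, x$visual$n, x$visual$s50, x$visual$c))
    cat(sprintf("  auditory: d_max=%.2f n=%.2f s50=%.3g c=%.2f\n",
                x$auditory$d_max, x$auditory$n, x$auditory$s50, x$auditory$c))
    cat(sprintf("  logLik=%.1f valid=%s\n", x$logLik, x$valid))
  }
  invisible(x)
}

#' Hyperbolic d-prime psychometric function
#'
#' `d(x) = d_max * x^n / (x^n + s50^n)`: d-prime saturating at `d_max`, half
#' saturation at stimulus strength `s50`, slope exponent `n`.
#'
#' @param x Stimulus change magnitude (>= 0).
#' @param d_max Asymptotic d-prime.
#' @param n Slope exponent.
#' @param s50 Stimulus strength at half the asymptotic d-prime.
#' @export
hyperbolic_dprime <- function(x, d_max, n, s50) {
  ifelse(x <= 0, 0, d_max * x^n / (x^n + s50^n))
}

#' d-prime from hit and false-alarm rates
#'
#' `qnorm(hit) - qnorm(fa)`.  Rates of exactly 0 or 1 are corrected by the
#' 1/(2N) convention before inversion, which requires the corresponding
#' trial count.
#'
#' @param hit_rate,fa_rate Rates in `[0, 1]`.
#' @param n_signal,n_noise Trial counts, needed only when a rate is exactly
#'   0 or 1.
#' @export
dprime_from_rates <- function(hit_rate, fa_rate, n_signal = NULL, n_noise = NULL) {
  fix <- function(r, n) {
    if (r > 0 && r < 1) return(r)
    if (is.null(n)) stop("rate of 0 or 1 needs a trial count for the 1/(2N) correction")
    min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  stats::qnorm(fix(hit_rate, n_signal)) - stats::qnorm(fix(fa_rate, n_noise))
}

## ---- multinomial logistic side-detection model ------------------------------

#' Choice probabilities of the multinomial side-detection model
#'
#' Log-odds of right and left choices against no-go are linear in saturated
#' stimulus intensities:
#' `log(p_right/p_nogo) = b_right + sL_right*cL^n + sR_right*cR^n` and
#' analogously for left, with saturation exponent `n` in (0, 1].
#'
#' @param cL,cR Stimulus intensity left / right (>= 0).
#' @param fit A `mnlogit_fit` or named list with `b_right`, `b_left`,
#'   `sL_right`, `sR_right`, `sL_left`, `sR_left`, `n_exp`.
#' @return Matrix with columns `p_left`, `p_right`, `p_nogo` (rows sum to 1).
#' @export
mnlogit_probs <- function(cL, cR, fit) {
  f <- fit
  stopifnot(all(cL >= 0), all(cR >= 0))
  eta_r <- f$b_right + f$sL_right * cL^f$n_exp + f$sR_right * cR^f$n_exp
  eta_l <- f$b_left + f$sL_left * cL^f$n_exp + f$sR_left * cR^f$n_exp
  m <- pmax(pmax(eta_r, eta_l), 0)
  den <- exp(-m) + exp(eta_r - m) + exp(eta_l - m)
  cbind(p_left = exp(eta_l - m) / den,
        p_right = exp(eta_r - m) / den,
        p_nogo = exp(-m) / den)
}

#' Fit the multinomial side-detection model
#'
#' Maximum-likelihood fit of the seven-parameter multinomial logistic model
#' to trial-level choices.
#'
#' @param cL,cR Stimulus intensities per trial.
#' @param choice Factor/character per trial: `"left"`, `"right"`, `"nogo"`.
#' @param n_starts Optimiser restarts.
#' @return A `mnlogit_fit` object.
#' @export
fit_mnlogit <- function(cL, cR, choice, n_starts = 10) {
  choice <- as.character(choice)
  stopifnot(all(choice %in% c("left", "right", "nogo")))
  unpack <- function(par) {
    list(b_right = par[1], b_left = par[2], sL_right = par[3],
         sR_right = par[4], sL_left = par[5], sR_left = par[6],
         n_exp = par[7])
  }
  col <- match(choice, c("left", "right", "nogo"))
  nll <- function(par) {
    pr <- mnlogit_probs(cL, cR, unpack(par))
    -sum(log(pmax(pr[cbind(seq_along(col), col)], 1e-12)))
  }
  lower <- c(-10, -10, -20, -20, -20, -20, 0.05)
  upper <- c(10, 10, 20, 20, 20, 20, 1)
  start <- c(-1, -1, 0, 1, 1, 0, 0.8)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) start else pmin(pmax(
      start + stats::rnorm(7, 0, 0.5), lower + 1e-4), upper - 1e-4)
    o <- try(stats::optim(st, nll, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 1000)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  f <- unpack(best$par)
  structure(c(f, list(logLik = -best$value, converged = best$convergence == 0,
                      n_trials = length(choice))),
            class = "mnlogit_fit")
}

#' @export
print.mnlogit_fit <- function(x, ...) {
  cat(sprintf(
    "Multinomial side-detection fit (n=%d)\n  right: b=%.2f sL=%.2f sR=%.2f\n  left:  b=%.2f sL=%.2f sR=%.2f\n  n_exp=%.2f  logLik=%.1f\n",
    x$n_trials, x$b_right, x$sL_right, x$sR_right, x$b_left, x$sL_left,
    x$sR_left, x$n_exp, x$logLik))
  invisible(x)
}

#' @export
coef.mnlogit_fit <- function(object, ...) {
  unlist(object[c("b_right", "b_left", "sL_right", "sR_right",
                  "sL_left", "sR_left", "n_exp")])
}

#' @export
predict.mnlogit_fit <- function(object, cL, cR, ...) {
  mnlogit_probs(cL, cR, object)
}

## ---- catch insertion, session filters, silencing ----------------------------

#' Insert artificial catch trials into long inter-trial intervals
#'
#' Catch events are inserted offline at times conforming to the session's
#' inter-change interval statistics, only inside intervals long enough to
#' respect the minimum spacing from real changes.  An inserted catch is a
#' false alarm if a lick follows it inside the response window (grace period
#' 100 ms, window 1.5 s); otherwise a correct rejection.  Inserted FAs are
#' thinned so that their latency distribution matches the hit reaction-time
#' distribution (density-ratio subsampling).
#'
#' @param trials `trial_table` with outcomes filled.
#' @param licks Numeric vector of lick times (s, session clock).
#' @param iti_min Minimum spacing (s) from real changes; default 3.
#' @param iti_mean Mean of the session's ITI distribution; default 6.
#' @param max_insert Cap on the number of inserted catches.
#' @return The augmented `trial_table`, inserted rows flagged by the logical
#'   column `inserted_catch`.
#' @export
insert_artificial_catch <- function(trials, licks, iti_min = 3, iti_mean = 6,
                                    max_insert = 200) {
  ct <- sort(trials$change_time)
  gaps <- data.frame(start = ct[-length(ct)], end = ct[-1])
  gaps <- gaps[gaps$end - gaps$start > 2 * iti_min, ]
  cand_time <- numeric(0)
  for (i in seq_len(nrow(gaps))) {
    t0 <- gaps$start[i]
    repeat {
      # candidate offset drawn from the original ITI law
      off <- stats::rexp(1, 1 / iti_mean)
      if (off < iti_min) next
      tc <- t0 + off
      if (tc > gaps$end[i] - iti_min) break
      cand_time <- c(cand_time, tc)
      t0 <- tc
    }
  }
  if (length(cand_time) > max_insert) {
    cand_time <- sort(sample(cand_time, max_insert))
  }
  if (length(cand_time) == 0) return(trials)

  lat <- vapply(cand_time, function(tc) {
    l <- licks[licks > tc + 0.1 & licks <= tc + 1.5]
    if (length(l)) min(l) - tc else NA_real_
  }, numeric(1))
  is_fa <- !is.na(lat)

  hit_rt <- trials$reaction_time[trials$outcome == "hit" &
                                   !is.na(trials$reaction_time)]
  keep <- rep(TRUE, length(cand_time))
  if (any(is_fa) && length(hit_rt) >= 5) {
    dens_hit <- stats::density(hit_rt, from = 0.1, to = 1.5, n = 128)
    fa_lat <- lat[is_fa]
    dens_fa <- stats::density(fa_lat, from = 0.1, to = 1.5, n = 128,
                              bw = dens_hit$bw)
    wh <- stats::approx(dens_hit$x, dens_hit$y, fa_lat, rule = 2)$y
    wf <- stats::approx(dens_fa$x, dens_fa$y, fa_lat, rule = 2)$y
    w <- wh / pmax(wf, 1e-9)
    w <- w / max(w)
    keep[is_fa] <- stats::runif(sum(is_fa)) < w
  }
  cand_time <- cand_time[keep]; lat <- lat[keep]; is_fa <- is_fa[keep]
  if (length(cand_time) == 0) return(trials)

  add <- trials[rep(1, length(cand_time)), ]
  add$trial_type <- "catch"
  add$pre_feature <- NA_real_; add$post_feature <- NA_real_
  add$saliency <- "none"
  add$change_time <- cand_time
  add$choice <- ifelse(is_fa, "left", "none")
  add$correct_side <- "none"
  add$outcome <- ifelse(is_fa, "FA", "CR")
  add$reaction_time <- lat
  add$photostim <- "none"; add$reward_time <- NA_real_
  if (!"inserted_catch" %in% names(trials)) trials$inserted_catch <- FALSE
  add$inserted_catch <- TRUE
  out <- rbind(trials, add)
  out <- out[order(out$change_time), ]
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Session inclusion filters
#'
#' Trims the session from the first run of 20 consecutive no-response trials
#' onwards (the animal stopped working) and excludes sessions whose hit rate
#' at maximal saliency falls below 30% for any of the tested modalities.
#'
#' @param trials `trial_table` with outcomes.
#' @param modalities Modalities whose maximal-saliency hit rate is checked.
#' @param min_hit_rate Exclusion threshold, default 0.30.
#' @param run_length No-response run triggering the trim, default 20.
#' @return List with `included` (logical), `trials` (trimmed table) and
#'   `reasons` (character).
#' @export
session_filters <- function(trials, modalities = c("visual", "auditory"),
                            min_hit_rate = 0.30, run_length = 20) {
  reasons <- character(0)
  no_resp <- is.na(trials$choice) | trials$choice == "none"
  r <- rle(no_resp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  long <- which(r$values & r$lengths >= run_length)
  if (length(long)) {
    cut <- starts[long[1]]
    trials <- trials[seq_len(cut - 1), , drop = FALSE]
    reasons <- c(reasons, sprintf("trimmed from trial %d (>=%d consecutive no-response trials)",
                                  cut, run_length))
  }
  included <- TRUE
  for (m in modalities) {
    sel <- trials$trial_type == m & trials$saliency == "max" &
      trials$photostim == "none"
    if (!any(sel)) next
    hr <- mean(trials$outcome[sel] == "hit")
    if (hr < min_hit_rate) {
      included <- FALSE
      reasons <- c(reasons, sprintf("max-saliency %s hit rate %.2f < %.2f",
                                    m, hr, min_hit_rate))
    }
  }
  list(included = included, trials = trials, reasons = reasons)
}

.session_dprime <- function(trials, photostim, saliency, modality = "visual") {
  sel_s <- trials$trial_type == modality & trials$saliency == saliency &
    trials$photostim == photostim
  sel_c <- trials$trial_type == "catch" & trials$photostim == photostim
  if (!any(sel_s) || !any(sel_c)) return(NA_real_)
  hit <- mean(trials$outcome[sel_s] == "hit")
  fa <- mean(trials$outcome[sel_c] == "FA")
  dprime_from_rates(hit, fa, sum(sel_s), sum(sel_c))
}

#' Behavioral effect of optogenetic silencing across sessions
#'
#' Quantifies, per session and saliency, the relative reduction in d-prime
#' under late photostimulation, `(d'_control - d'_late) / d'_control`, and
#' regresses it on the session's median control reaction time.  Sessions
#' qualify only if early silencing demonstrably worked: early photostimulation
#' must reduce maximal-saliency d-prime by at least `early_cut` (an internal
#' control for optogenetic efficacy).
#'
#' @param sessions List of `trial_table`s containing control, early- and
#'   late-photostim trials.
#' @param saliency Saliency level analysed (default `"thr"`).
#' @param early_cut Required fractional reduction of max-saliency d-prime
#'   under early silencing (default 0.5; the analysis is robust to 0.25/0.75).
#' @param modality Modality analysed (default `"visual"`).
#' @return List with a per-session data frame (`delta_dprime`, `median_rt`),
#'   Pearson `r`, `p` value and the least-squares line; empty with a warning
#'   if no session qualifies.
#' @export
silencing_effect <- function(sessions, saliency = "thr", early_cut = 0.5,
                             modality = "visual") {
  rows <- lapply(sessions, function(tr) {
    d_c_max <- .session_dprime(tr, "none", "max", modality)
    d_e_max <- .session_dprime(tr, "early", "max", modality)
    if (is.na(d_c_max) || is.na(d_e_max) || d_c_max <= 0) return(NULL)
    if ((d_c_max - d_e_max) / d_c_max < early_cut) return(NULL)
    d_c <- .session_dprime(tr, "none", saliency, modality)
    d_l <- .session_dprime(tr, "late", saliency, modality)
    if (is.na(d_c) || is.na(d_l) || d_c <= 0) return(NULL)
    rt <- tr$reaction_time[tr$trial_type == modality & tr$outcome == "hit" &
                             tr$photostim == "none"]
    data.frame(delta_dprime = (d_c - d_l) / d_c,
               median_rt = stats::median(rt, na.rm = TRUE))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 3) {
    warning("no (or too few) qualifying sessions for the silencing regression")
    return(list(sessions = rows, r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(rows$median_rt, rows$delta_dprime)
  fit <- stats::lm(delta_dprime ~ median_rt, data = rows)
  list(sessions = rows, r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

## RNG bookkeeping helpers (restore global seed after internally seeded fits)
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
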