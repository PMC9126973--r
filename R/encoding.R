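## Kernel-based Poisson encoding model: raised-cosine temporal bases, the
## 126-column design matrix over trial windows, elastic-net fits with
## cross-validation, and explained-variance partitioning by predictor family.

#' Raised-cosine temporal basis set
#'
#' `n_funcs` cosine bumps with centres evenly spaced over `span`;
#' `bump_j(t) = 0.5 * (1 + cos(pi * (t - c_j) / w))` on `|t - c_j| < w`,
#' 0 elsewhere.  By default the half-width `w` equals the centre spacing,
#' which makes adjacent bumps sum exactly to 1 on the interior of the span
#' (a partition of unity), so any smooth kernel over the span is
#' representable without ripple.
#'
#' @param n_funcs Number of basis functions (>= 1).
#' @param span Length-2 numeric `(start, end)` in seconds relative to the
#'   event.
#' @param width Optional half-width `w` in seconds; defaults to the centre
#'   spacing (or half the span for a single bump).
#' @return A `basis_set`: list with `centers`, `width`, `span`, `n_funcs`
#'   and the evaluator `eval(t)` returning a `length(t) x n_funcs` matrix.
#' @export
raised_cosine_basis <- function(n_funcs, span, width = NULL) {
  stopifnot(n_funcs >= 1)
  if (diff(span) <= 0) stop("degenerate span")
  centers <- if (n_funcs == 1) mean(span)
    else seq(span[1], span[2], length.out = n_funcs)
  if (is.null(width)) {
    width <- if (n_funcs == 1) diff(span) / 2 else diff(centers[1:2])
  }
  force(centers); force(width)
  evalf <- function(t) {
    out <- matrix(0, length(t), length(centers))
    for (j in seq_along(centers)) {
      u <- (t - centers[j]) / width
      on <- abs(u) < 1
      out[on, j] <- 0.5 * (1 + cos(pi * u[on]))
    }
    out
  }
  structure(list(centers = centers, width = width, span = span,
                 n_funcs = n_funcs, eval = evalf),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("raised-cosine basis: %d bumps on [%g, %g] s, half-width %g s\n",
              x$n_funcs, x$span[1], x$span[2], x$width))
  invisible(x)
}

#' Bin spike counts over concatenated trial windows
#'
#' @param spike_times Numeric vector of one neuron's spike times (s).
#' @param trials `trial_table` (uses `change_time`).
#' @param window Window (s) around each change, default `c(-0.5, 2.5)`.
#' @param bin_width Bin width (s), default 0.01.
#' @return Integer vector of counts, trials stacked in order; attributes
#'   `row_trial` and `row_time` give each row's trial index and bin centre.
#' @export
bin_spike_counts <- function(spike_times, trials, window = c(-0.5, 2.5),
                             bin_width = 0.01) {
  n_bins <- round(diff(window) / bin_width)
  centers <- window[1] + bin_width * (seq_len(n_bins) - 0.5)
  n_tr <- nrow(trials)
  Y <- integer(n_tr * n_bins)
  for (j in seq_len(n_tr)) {
    rel <- spike_times - trials$change_time[j]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      cnt <- tabulate(floor((rel - window[1]) / bin_width) + 1L,
                      nbins = n_bins)
      Y[(j - 1) * n_bins + seq_len(n_bins)] <- cnt
    }
  }
  attr(Y, "row_trial") <- rep(seq_len(n_tr), each = n_bins)
  attr(Y, "row_time") <- rep(centers, n_tr)
  Y
}

.scale_max1 <- function(X) {
  m <- apply(abs(X), 2, max)
  m[m == 0] <- 1
  sweep(X, 2, m, "/")
}

#' Build the kernel-based design matrix
#'
#' Predictor families over 10-ms bins of concatenated per-trial windows
#' (default -0.5 to 2.5 s around each change):
#' \describe{
#'   \item{sensory (96)}{per modality (2) x change level (2) x grouped
#'     post-change feature pair AB/CD (2): 2 early raised cosines spanning
#'     0-200 ms plus 10 late ones spanning 0-2000 ms, stimulus-aligned on
#'     the qualifying trials;}
#'   \item{hit (20)}{10 stimulus-aligned cosines (0-2000 ms) on hit trials
#'     (shared across modalities, or split 5/5 with
#'     `split_hit_by_modality = TRUE`) plus 10 reward-aligned cosines
#'     (-500 to 1500 ms);}
#'   \item{movement (6)}{3 cosines spanning -200 to +400 ms around each
#'     lick, per lick side;}
#'   \item{pupil (3)}{z-scored pupil area at lags 0, -400, -800 ms;}
#'   \item{trial_number (1)}{within-session trial index.}
#' }
#' All 126 columns are scaled to maximum absolute value 1.  A null model
#' uses a single standard-normal random column instead.
#'
#' @param trials `trial_table` with outcomes.
#' @param licks Data frame `time_s`, `side`; may be empty.
#' @param pupil Data frame `time_s`, `z`, or `NULL` (pupil family zeroed and
#'   flagged).
#' @param window,bin_width Window (s) and bin width (s) of the row grid.
#' @param split_hit_by_modality Use 5 visual + 5 auditory stimulus-aligned
#'   hit kernels instead of 10 shared ones.
#' @param null_model If `TRUE`, return the one-random-column null design.
#' @param seed Seed for the null-model column.
#' @return A `design_matrix`: list with `X`, `family` (factor per column),
#'   `row_trial`, `row_time`, `window`, `bin_width`, `pupil_missing`.
#' @export
build_design <- function(trials, licks = NULL, pupil = NULL,
                         window = c(-0.5, 2.5), bin_width = 0.01,
                         split_hit_by_modality = FALSE, null_model = FALSE,
                         seed = 1) {
  n_bins <- round(diff(window) / bin_width)
  centers <- window[1] + bin_width * (seq_len(n_bins) - 0.5)
  n_tr <- nrow(trials)
  row_trial <- rep(seq_len(n_tr), each = n_bins)
  row_time <- rep(centers, n_tr)
  n_row <- n_tr * n_bins

  if (null_model) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    X <- matrix(stats::rnorm(n_row), ncol = 1,
                dimnames = list(NULL, "null"))
    return(structure(list(X = .scale_max1(X), family = factor("null"),
                          row_trial = row_trial, row_time = row_time,
                          window = window, bin_width = bin_width,
                          pupil_missing = TRUE),
                     class = "design_matrix"))
  }

  vset <- make_stimulus_set("visual", 100, 7)
  in_ab_vis <- function(f) {
    !is.na(f) & pmin(abs(orientation_diff(vset$A, f)),
                     abs(orientation_diff(vset$B, f))) < 1e-6
  }
  aset <- make_stimulus_set("auditory", 13.25, 1 / 32)
  in_ab_aud <- function(f) {
    !is.na(f) & pmin(abs(f - aset$A), abs(f - aset$B)) < 1e-9
  }

  early <- raised_cosine_basis(2, c(0, 0.2))
  late <- raised_cosine_basis(10, c(0, 2))
  Bearly <- early$eval(centers)   # n_bins x 2
  Blate <- late$eval(centers)     # n_bins x 10
  Bsens <- cbind(Bearly, Blate)   # n_bins x 12

  cols <- list(); fams <- character(0)
  add <- function(block, fam, names_) {
    cols[[length(cols) + 1]] <<- block
    fams <<- c(fams, rep(fam, ncol(block)))
    colnames(cols[[length(cols)]]) <<- names_
  }

  # sensory family: 8 condition sets x 12 bases = 96
  for (mod in c("visual", "auditory")) {
    for (lev in c("thr", "max")) {
      for (grp in c("AB", "CD")) {
        is_ab <- if (mod == "visual") in_ab_vis(trials$post_feature)
          else in_ab_aud(trials$post_feature)
        sel <- trials$trial_type == mod & trials$saliency == lev &
          (if (grp == "AB") is_ab else !is_ab)
        block <- matrix(0, n_row, 12)
        if (any(sel)) {
          rows <- row_trial %in% which(sel)
          block[rows, ] <- Bsens[rep(seq_len(n_bins), sum(sel)), ]
        }
        add(block, "sensory",
            sprintf("sens_%s_%s_%s_b%02d", mod, lev, grp, 1:12))
      }
    }
  }

  # hit family: 10 stimulus-aligned + 10 reward-aligned = 20
  hit_tr <- which(trials$outcome == "hit" &
                    trials$trial_type %in% c("visual", "auditory"))
  if (!split_hit_by_modality) {
    block <- matrix(0, n_row, 10)
    if (length(hit_tr)) {
      rows <- row_trial %in% hit_tr
      block[rows, ] <- Blate[rep(seq_len(n_bins), length(hit_tr)), ]
    }
    add(block, "hit", sprintf("hit_stim_b%02d", 1:10))
  } else {
    b5 <- raised_cosine_basis(5, c(0, 2))$eval(centers)
    for (mod in c("visual", "auditory")) {
      sel <- hit_tr[trials$trial_type[hit_tr] == mod]
      block <- matrix(0, n_row, 5)
      if (length(sel)) {
        rows <- row_trial %in% sel
        block[rows, ] <- b5[rep(seq_len(n_bins), length(sel)), ]
      }
      add(block, "hit", sprintf("hit_stim_%s_b%02d", mod, 1:5))
    }
  }
  rew <- raised_cosine_basis(10, c(-0.5, 1.5))
  block <- matrix(0, n_row, 10)
  for (j in hit_tr) {
    rt <- trials$reward_time[j]
    if (is.na(rt)) next
    rows <- which(row_trial == j)
    block[rows, ] <- rew$eval(centers - (rt - trials$change_time[j]))
  }
  add(block, "hit", sprintf("hit_rew_b%02d", 1:10))

  # movement family: 3 bases x 2 sides = 6
  mv <- raised_cosine_basis(3, c(-0.2, 0.4))
  for (side in c("left", "right")) {
    block <- matrix(0, n_row, 3)
    lt <- if (!is.null(licks) && nrow(licks)) {
      licks$time_s[licks$side == side]
    } else numeric(0)
    if (length(lt)) {
      for (j in seq_len(n_tr)) {
        rel <- lt - trials$change_time[j]
        rel <- rel[rel > window[1] - 0.4 & rel < window[2] + 0.2]
        if (!length(rel)) next
        rows <- which(row_trial == j)
        for (l in rel) block[rows, ] <- block[rows, ] + mv$eval(centers - l)
      }
    }
    add(block, "movement", sprintf("lick_%s_b%d", side, 1:3))
  }

  # pupil family: z-scored area at lags 0, -400, -800 ms
  pupil_missing <- is.null(pupil) || nrow(pupil) == 0
  block <- matrix(0, n_row, 3)
  if (!pupil_missing) {
    abs_time <- trials$change_time[row_trial] + row_time
    for (k in seq_along(c(0, -0.4, -0.8))) {
      lag <- c(0, -0.4, -0.8)[k]
      block[, k] <- stats::approx(pupil$time_s, pupil$z, abs_time + lag,
                                  rule = 2)$y
    }
  }
  add(block, "pupil", sprintf("pupil_lag%d", c(0, 400, 800)))

  # within-session trial number
  add(matrix(row_trial, ncol = 1), "trial_number", "trial_number")

  X <- do.call(cbind, cols)
  structure(list(X = .scale_max1(X), family = factor(fams),
                 row_trial = row_trial, row_time = row_time,
                 window = window, bin_width = bin_width,
                 pupil_missing = pupil_missing),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d rows x %d columns\n", nrow(x$X), ncol(x$X)))
  print(table(x$family))
  invisible(x)
}

#' Fit a per-neuron Poisson elastic-net encoding model
#'
#' Minimises the Poisson deviance with an elastic-net penalty
#' (`alpha = 0.95`: nearly lasso, favouring a small set of informative
#' kernels) over a regularisation path via `glmnet`, with per-trial
#' cross-validation folds (all bins of a trial share a fold, so no leakage
#' across the trial's time course).  The reported model uses the largest
#' lambda whose cross-validated deviance is within one standard error of the
#' minimum (`"1se"`), or the minimiser (`"min"`).
#'
#' @param design A `design_matrix`.
#' @param Y Spike counts from [bin_spike_counts()] on the same row grid.
#' @param alpha Elastic-net mixing parameter.
#' @param folds Number of CV folds.
#' @param lambda_rule `"1se"` or `"min"`.
#' @param seed Seed fixing the fold assignment.
#' @return An `encoding_fit`: coefficients at the chosen lambda, the CV
#'   path, held-out (pre-validated) predictions `Yhat_cv`, in-sample
#'   predictions `Yhat`, and fold ids.
#' @export
fit_poisson_elasticnet <- function(design, Y, alpha = 0.95, folds = 5,
                                   lambda_rule = c("1se", "min"), seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(length(Y) == nrow(design$X))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trials <- unique(design$row_trial)
  fold_of_trial <- sample(rep_len(seq_len(folds), length(trials)))
  foldid <- fold_of_trial[match(design$row_trial, trials)]
  cv <- try(glmnet::cv.glmnet(design$X, as.numeric(Y), family = "poisson",
                              alpha = alpha, foldid = foldid, keep = TRUE,
                              nlambda = 100, standardize = FALSE),
            silent = TRUE)
  if (inherits(cv, "try-error")) {
    return(structure(list(converged = FALSE,
                          diagnostics = as.character(cv)),
                     class = "encoding_fit"))
  }
  lambda <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  ilam <- which.min(abs(cv$lambda - lambda))
  beta <- as.numeric(stats::coef(cv, s = lambda))
  names(beta) <- c("(Intercept)", colnames(design$X))
  eta_cv <- cv$fit.preval[, ilam]
  Yhat <- as.numeric(stats::predict(cv, design$X, s = lambda,
                                    type = "response"))
  structure(list(beta = beta, lambda = lambda, lambda_rule = lambda_rule,
                 cv = cv, foldid = foldid, Yhat = Yhat,
                 Yhat_cv = exp(eta_cv), family = design$family,
                 converged = TRUE),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("encoding fit: NOT converged\n")
    return(invisible(x))
  }
  nz <- sum(x$beta[-1] != 0)
  cat(sprintf("Poisson elastic-net fit: lambda(%s)=%.4g, %d of %d nonzero coefficients\n",
              x$lambda_rule, x$lambda, nz, length(x$beta) - 1))
  invisible(x)
}

#' @export
coef.encoding_fit <- function(object, ...) object$beta

#' @export
predict.encoding_fit <- function(object, design, family_set = NULL, ...) {
  X <- design$X
  beta <- object$beta[-1]
  if (!is.null(family_set)) {
    keep <- design$family %in% family_set
    X <- X[, keep, drop = FALSE]
    beta <- beta[keep]
  }
  as.numeric(exp(object$beta[1] + X %*% beta))
}

#' Cross-validated explained variance
#'
#' `EV = 1 - var(Y - Yhat) / var(Y)`.  Modes: `"overall"` concatenates all
#' single-trial bins; `"per_bin"` computes EV across trials separately for
#' each time bin; `"condition_avg"` computes EV on the concatenated
#' condition-averaged time courses of the five most frequent
#' trial-type-by-choice combinations.  EV can be negative (prediction worse
#' than the mean); it is 1 for a perfect prediction and 0 for predicting the
#' mean.
#'
#' @param Y,Yhat Observed and predicted counts on the same row grid.
#' @param mode `"overall"`, `"per_bin"` or `"condition_avg"`.
#' @param row_trial,row_time Row structure (needed for `per_bin` and
#'   `condition_avg`).
#' @param condition Character per trial (e.g. trial-type x choice), needed
#'   for `condition_avg`.
#' @return For `overall` a single fraction; `per_bin` a named vector per
#'   bin time; `condition_avg` a single fraction plus attribute
#'   `"conditions"`.
#' @export
explained_variance <- function(Y, Yhat,
                               mode = c("overall", "per_bin",
                                        "condition_avg"),
                               row_trial = NULL, row_time = NULL,
                               condition = NULL) {
  mode <- match.arg(mode)
  ev <- function(y, yh) {
    v <- stats::var(y)
    if (!is.finite(v) || v == 0) return(NA_real_)
    1 - stats::var(y - yh) / v
  }
  if (mode == "overall") return(ev(as.numeric(Y), as.numeric(Yhat)))
  stopifnot(!is.null(row_trial), !is.null(row_time))
  if (mode == "per_bin") {
    times <- sort(unique(row_time))
    out <- vapply(times, function(tt) {
      sel <- row_time == tt
      ev(Y[sel], Yhat[sel])
    }, numeric(1))
    names(out) <- signif(times, 6)
    return(out)
  }
  # condition_avg
  stopifnot(!is.null(condition))
  tab <- sort(table(condition), decreasing = TRUE)
  top <- names(tab)[seq_len(min(5, length(tab)))]
  times <- sort(unique(row_time))
  ybar <- yhbar <- numeric(0)
  for (cc in top) {
    tr <- which(condition == cc)
    sel <- row_trial %in% tr
    ym <- tapply(Y[sel], row_time[sel], mean)
    yhm <- tapply(Yhat[sel], row_time[sel], mean)
    ybar <- c(ybar, ym); yhbar <- c(yhbar, yhm)
  }
  out <- ev(ybar, yhbar)
  attr(out, "conditions") <- top
  out
}

#' Explained variance of a predictor-family subset
#'
#' Prediction using only the named families' columns (all other
#' coefficients zeroed, intercept kept), evaluated by
#' [explained_variance()].
#'
#' @param design A `design_matrix`.
#' @param fit An `encoding_fit`.
#' @param family_set Character vector of family names (subset of
#'   `levels(design$family)`), or `character(0)` for the intercept-only
#'   prediction.
#' @param Y Observed counts.
#' @param ... Passed to [explained_variance()].
#' @export
subset_ev <- function(design, fit, family_set, Y, ...) {
  known <- levels(design$family)
  if (length(family_set) && !all(family_set %in% known)) {
    stop("unknown predictor family: ",
         paste(setdiff(family_set, known), collapse = ", "))
  }
  Yhat <- if (length(family_set) == 0) {
    rep(exp(fit$beta[1]), nrow(design$X))
  } else {
    predict(fit, design, family_set = family_set)
  }
  explained_variance(Y, Yhat, ...)
}
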