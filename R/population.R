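## Population-level statistics: residual rates, pairwise noise correlations
## (stimulus- and lick-aligned), reaction-time-tertile decorrelation onsets,
## pre-photostimulation state contrasts and random-forest orientation
## decoding.

#' Residual rates after removing condition means
#'
#' Per neuron and condition, subtracts the condition's trial-mean time
#' course, leaving trial-to-trial fluctuations.  For lick-aligned analyses
#' pass a lick-aligned tensor: the subtracted mean is then the lick-aligned
#' mean.  Conditions with fewer than `min_trials` trials are excluded.
#'
#' @param tensor A `rate_tensor`.
#' @param condition_labels Character/factor per trial (e.g. post-change
#'   orientation); `NA` trials are dropped.
#' @param min_trials Minimum trials per condition (default 10).
#' @return A `rate_tensor` of residuals covering the kept trials, with
#'   attribute `kept_trials` (indices into the input).
#' @export
residual_rates <- function(tensor, condition_labels, min_trials = 10) {
  stopifnot(inherits(tensor, "rate_tensor"),
            dim(tensor$values)[2] == length(condition_labels))
  condition_labels <- as.character(condition_labels)
  tab <- table(condition_labels[!is.na(condition_labels)])
  keep_conds <- names(tab)[tab >= min_trials]
  kept <- which(condition_labels %in% keep_conds)
  if (!length(kept)) stop("no condition reaches the minimum trial count")
  v <- tensor$values[, kept, , drop = FALSE]
  lab <- condition_labels[kept]
  for (cc in keep_conds) {
    sel <- lab == cc
    mu <- apply(v[, sel, , drop = FALSE], c(1, 3), mean)
    v[, sel, ] <- sweep(v[, sel, , drop = FALSE], c(1, 3), mu, "-")
  }
  out <- tensor
  out$values <- v
  out$unit <- paste0(tensor$unit, " (residual)")
  attr(out, "kept_trials") <- kept
  out
}

.fisher_z <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
.fisher_z_inv <- function(z) tanh(z)

#' Pairwise noise correlations over time
#'
#' Pearson correlation of residual rates across trials, per neuron pair and
#' time bin.  Pair summaries (the mean NC time course, baseline statistics
#' and the post-stimulus change) average Fisher-z-transformed correlations
#' and back-transform.  Bins where either neuron has zero variance are
#' masked (`NA`).
#'
#' @param residuals Residual `rate_tensor` from [residual_rates()]
#'   (smoothing SD 100 ms recommended: slow comodulation survives, fast
#'   Poisson noise averages out).
#' @param baseline Baseline window (s), default `c(-0.5, 0)`.
#' @param late_window Post-stimulus window for the NC change, default
#'   `c(0.2, 1)`.
#' @return An `nc_result`: `r_per_bin` (pairs x bins), `pair_ids`,
#'   `mean_r` (per bin, Fisher-z averaged), `baseline_mean`, `baseline_sd`,
#'   `delta_nc`, `times`.
#' @export
noise_correlations <- function(residuals, baseline = c(-0.5, 0),
                               late_window = c(0.2, 1)) {
  stopifnot(inherits(residuals, "rate_tensor"))
  v <- residuals$values
  n_neu <- dim(v)[1]; n_bins <- dim(v)[3]
  if (n_neu < 2) stop("need at least 2 neurons")
  pairs <- which(upper.tri(matrix(0, n_neu, n_neu)), arr.ind = TRUE)
  r <- matrix(NA_real_, nrow(pairs), n_bins)
  for (b in seq_len(n_bins)) {
    m <- t(v[, , b])                       # trials x neurons
    cm <- suppressWarnings(stats::cor(m))
    r[, b] <- cm[pairs]
  }
  times <- residuals$bin_centers
  mean_r <- .fisher_z_inv(colMeans(.fisher_z(r), na.rm = TRUE))
  bsel <- times >= baseline[1] & times <= baseline[2]
  lsel <- times >= late_window[1] & times <= late_window[2]
  structure(list(
    r_per_bin = r, pair_ids = pairs, mean_r = mean_r, times = times,
    baseline_mean = mean(mean_r[bsel]), baseline_sd = stats::sd(mean_r[bsel]),
    delta_nc = mean(mean_r[lsel]) - mean(mean_r[bsel]),
    baseline = baseline, late_window = late_window),
    class = "nc_result")
}

#' @export
print.nc_result <- function(x, ...) {
  cat(sprintf(
    "noise correlations: %d pairs x %d bins; baseline %.3f +/- %.3f, delta %.3f\n",
    nrow(x$r_per_bin), ncol(x$r_per_bin), x$baseline_mean, x$baseline_sd,
    x$delta_nc))
  invisible(x)
}

#' Decorrelation onsets per reaction-time tertile
#'
#' Splits hit trials into reaction-time tertiles; per tertile, recomputes
#' the mean NC time course and finds the first bin where it falls below the
#' tertile's baseline mean minus 2 baseline SDs.  Also reports the Pearson
#' correlation between tertile median RT and onset.
#'
#' @param residuals Residual `rate_tensor` of hit trials (stimulus- or
#'   lick-aligned).
#' @param rts Reaction times (s) of the same trials.
#' @param baseline Baseline window (s) for the threshold.
#' @param z_thresh Threshold in baseline SDs (default 2).
#' @param baseline_stats Optional 3 x 2 matrix (`mean`, `sd` per tertile)
#'   fixing the threshold externally.  For lick-aligned series pass the
#'   stimulus-aligned pre-stimulus statistics: in lick-aligned time the
#'   stimulus transient sweeps through the pre-lick window at a
#'   reaction-time-dependent position and would contaminate a baseline
#'   estimated there.
#' @return List with `onsets_s` (per tertile), `median_rt_s`, `r`, `p`,
#'   `mean_r` (tertile x bin), `baseline_stats`, `times`.
#' @export
tertile_decorrelation <- function(residuals, rts, baseline = c(-0.5, 0),
                                  z_thresh = 2, baseline_stats = NULL) {
  stopifnot(inherits(residuals, "rate_tensor"),
            dim(residuals$values)[2] == length(rts))
  if (length(rts) < 30) stop("need at least 30 hit trials")
  ter <- cut(rts, stats::quantile(rts, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("fast", "medium", "slow"))
  times <- residuals$bin_centers
  onsets <- med_rt <- numeric(3)
  bstats <- matrix(NA_real_, 3, 2, dimnames = list(levels(ter),
                                                   c("mean", "sd")))
  curves <- matrix(NA_real_, 3, length(times),
                   dimnames = list(levels(ter), NULL))
  for (k in seq_len(3)) {
    sel <- which(ter == levels(ter)[k])
    sub <- residuals
    sub$values <- residuals$values[, sel, , drop = FALSE]
    nc <- noise_correlations(sub, baseline = baseline)
    curves[k, ] <- nc$mean_r
    if (is.null(baseline_stats)) {
      bstats[k, ] <- c(nc$baseline_mean, nc$baseline_sd)
    } else {
      bstats[k, ] <- baseline_stats[k, ]
    }
    thr <- bstats[k, 1] - z_thresh * bstats[k, 2]
    idx <- which(times > baseline[2] & nc$mean_r < thr)
    onsets[k] <- if (length(idx)) times[min(idx)] else NA_real_
    med_rt[k] <- stats::median(rts[sel])
  }
  ok <- !is.na(onsets)
  ct <- if (sum(ok) >= 3) {
    suppressWarnings(stats::cor.test(med_rt[ok], onsets[ok]))
  } else NULL
  list(onsets_s = stats::setNames(onsets, levels(ter)),
       median_rt_s = stats::setNames(med_rt, levels(ter)),
       r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       p = if (is.null(ct)) NA_real_ else ct$p.value,
       mean_r = curves, baseline_stats = bstats, times = times)
}

#' Pre-photostimulation state contrasts
#'
#' Mean z-scored rate and mean NC in a window just before late
#' photostimulation (default 100-200 ms after the change), split by the
#' trial's eventual outcome (hit vs miss).
#'
#' @param z_tensor Z-scored `rate_tensor` of late-photostim visual trials.
#' @param residuals Residual `rate_tensor` of the same trials (for NC).
#' @param outcomes Character per trial: `"hit"` / `"miss"` (others dropped).
#' @param window Analysis window (s), default `c(0.1, 0.2)`.
#' @param min_trials Minimum trials per outcome (default 10).
#' @return List with `rate_hit`, `rate_miss`, `rate_diff`, `nc_hit`,
#'   `nc_miss`, `nc_diff`, `n_hit`, `n_miss`, `flagged`.
#' @export
prestim_state <- function(z_tensor, residuals, outcomes,
                          window = c(0.1, 0.2), min_trials = 10) {
  stopifnot(inherits(z_tensor, "rate_tensor"))
  keep <- outcomes %in% c("hit", "miss")
  wsel <- z_tensor$bin_centers >= window[1] &
    z_tensor$bin_centers <= window[2]
  mean_rate <- function(sel) {
    mean(z_tensor$values[, which(keep)[sel], wsel], na.rm = TRUE)
  }
  oc <- outcomes[keep]
  n_hit <- sum(oc == "hit"); n_miss <- sum(oc == "miss")
  flagged <- n_hit < min_trials || n_miss < min_trials
  nc_in <- function(sel) {
    sub <- residuals
    sub$values <- residuals$values[, which(keep)[sel], , drop = FALSE]
    nc <- noise_correlations(sub)
    wsel2 <- nc$times >= window[1] & nc$times <= window[2]
    mean(nc$mean_r[wsel2])
  }
  rate_hit <- mean_rate(oc == "hit"); rate_miss <- mean_rate(oc == "miss")
  nc_hit <- nc_in(oc == "hit"); nc_miss <- nc_in(oc == "miss")
  list(rate_hit = rate_hit, rate_miss = rate_miss,
       rate_diff = rate_hit - rate_miss,
       nc_hit = nc_hit, nc_miss = nc_miss, nc_diff = nc_hit - nc_miss,
       n_hit = n_hit, n_miss = n_miss, flagged = flagged)
}

## stratified fold assignment: each class split evenly across folds
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.rf_cv_accuracy <- function(X, y, k = 5, repeats = 1, num_trees = 200) {
  colnames(X) <- paste0("n", seq_len(ncol(X)))
  accs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(y, k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      fit <- ranger::ranger(
        x = X[tr, , drop = FALSE], y = factor(y[tr]),
        num.trees = num_trees, num.threads = 1,
        seed = sample.int(.Machine$integer.max, 1))
      pred <- stats::predict(fit, X[te, , drop = FALSE])$predictions
      accs <- c(accs, mean(as.character(pred) == as.character(y[te])))
    }
  }
  mean(accs)
}

#' Random-forest orientation decoding over time
#'
#' Decodes the grouped post-change orientation pair (AB vs CD) from
#' population spike counts in 200-ms windows sliding by 50 ms, excluding
#' windows that straddle the stimulus change (mixing pre- and post-change
#' spikes).  Sessions need at least `min_neurons` neurons and `min_trials`
#' trials per class; 10 neurons are randomly subsampled from larger
#' populations.  Accuracy comes from a 5x5 stratified cross-validation with
#' a random forest of 200 trees, corrected by the mean accuracy over
#' label-permuted surrogate datasets, so chance maps to 0.
#'
#' @param tensor A `rate_tensor` (Hz; integrated to counts per window).
#' @param labels Two-level factor per trial (orientation pair).
#' @param window_length,step Sliding-window parameters (s).
#' @param n_subsample Neurons used (default 10).
#' @param num_trees Forest size (default 200).
#' @param cv_k,cv_repeats Cross-validation folds and repeats (default 5x5).
#' @param n_surrogates Label permutations for the chance correction
#'   (default 50, each evaluated by one k-fold CV).
#' @param min_neurons,min_trials Session inclusion thresholds (15 and 20).
#' @param seed Seed fixing subsampling, folds and surrogates.
#' @return A `decoding_result`: `accuracy` (corrected, per window),
#'   `raw_accuracy`, `surrogate_mean`, `window_centers`, `n_neurons_used`;
#'   or `NULL` if the session fails the thresholds.
#' @export
decode_orientation <- function(tensor, labels, window_length = 0.2,
                               step = 0.05, n_subsample = 10,
                               num_trees = 200, cv_k = 5, cv_repeats = 5,
                               n_surrogates = 50, min_neurons = 15,
                               min_trials = 20, seed = 1) {
  stopifnot(inherits(tensor, "rate_tensor"))
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2)
  n_neu <- dim(tensor$values)[1]
  if (n_neu < min_neurons) return(NULL)
  if (min(table(labels)) < min_trials) return(NULL)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  use <- if (n_neu > n_subsample) sample(n_neu, n_subsample)
    else seq_len(n_neu)

  t0 <- tensor$window[1]; t1 <- tensor$window[2]
  starts <- seq(t0, t1 - window_length, by = step)
  keep <- !(starts < 0 & starts + window_length > 0)   # drop straddlers
  starts <- starts[keep]
  centers <- starts + window_length / 2
  dt <- tensor$bin_width

  raw <- surr <- numeric(length(starts))
  for (wi in seq_along(starts)) {
    sel <- tensor$bin_centers >= starts[wi] &
      tensor$bin_centers < starts[wi] + window_length
    # counts per trial per neuron in the window
    X <- t(apply(tensor$values[use, , sel, drop = FALSE], c(1, 2),
                 function(v) sum(v) * dt))
    raw[wi] <- .rf_cv_accuracy(X, labels, k = cv_k, repeats = cv_repeats,
                               num_trees = num_trees)
    sa <- numeric(n_surrogates)
    for (s in seq_len(n_surrogates)) {
      sa[s] <- .rf_cv_accuracy(X, sample(labels), k = cv_k, repeats = 1,
                               num_trees = num_trees)
    }
    surr[wi] <- mean(sa)
  }
  structure(list(accuracy = raw - surr, raw_accuracy = raw,
                 surrogate_mean = surr, window_centers = centers,
                 window_length = window_length, step = step,
                 n_neurons_used = length(use), num_trees = num_trees,
                 cv = c(cv_k, cv_repeats), n_surrogates = n_surrogates,
                 seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  post <- x$window_centers > 0
  cat(sprintf(
    "orientation decoding: %d windows, %d neurons; corrected accuracy pre %.3f / post %.3f\n",
    length(x$accuracy), x$n_neurons_used,
    mean(x$accuracy[!post]), mean(x$accuracy[post])))
  invisible(x)
}
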