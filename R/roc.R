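## Time-resolved single-neuron discriminability: per-bin ROC AUC with
## label-permutation significance, coder classification, population coding
## fractions, onset estimation (with bootstrap), laminar maps and the
## onset-versus-reaction-time regression.

#' Per-bin AUC between two trial groups
#'
#' AUC of the firing-rate distributions of two trial classes, per time bin,
#' computed through the Mann-Whitney relation `AUC = U / (n1 * n2)` with
#' midranks for ties, rectified to `[0.5, 1]`.  Significance per bin comes
#' from a permutation test: class labels are shuffled across trials
#' `n_shuffle` times (the same label shuffles reused across bins), the
#' rectified AUC recomputed, and
#' `p = (1 + #\{shuffled >= observed\}) / (1 + n_shuffle)`; a bin is
#' significant at `p < alpha` (default 0.01, i.e. observed above the 99th
#' percentile of the shuffle distribution).
#'
#' @param rates Numeric matrix, trials x bins, one neuron.
#' @param labels Logical or two-level vector per trial; `TRUE` (or the
#'   first level) is the positive class.
#' @param times Optional bin centres (s); defaults to bin index.
#' @param min_per_class Minimum trials per class (default 10); below it the
#'   comparison is skipped (`NULL` returned).
#' @param n_shuffle Number of label shuffles (default 1000).
#' @param alpha Significance level (default 0.01).
#' @param variable,saliency Optional labels carried in the result.
#' @param seed Optional seed for the shuffles.
#' @return An `auc_series`: list with `auc`, `p`, `sig`, `times`, `n1`,
#'   `n2`, `variable`, `saliency`; or `NULL` if a class is too small.
#' @export
auc_timecourse <- function(rates, labels, times = NULL, min_per_class = 10,
                           n_shuffle = 1000, alpha = 0.01, variable = NA,
                           saliency = NA, seed = NULL) {
  if (is.logical(labels)) labels <- factor(labels, levels = c(TRUE, FALSE))
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2, nrow(rates) == length(labels))
  n1 <- sum(labels == levels(labels)[1])
  n2 <- sum(labels == levels(labels)[2])
  if (n1 < min_per_class || n2 < min_per_class) return(NULL)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- n1 + n2
  R <- apply(rates, 2, rank)        # midranks per bin
  pos <- labels == levels(labels)[1]
  u_obs <- colSums(R[pos, , drop = FALSE]) - n1 * (n1 + 1) / 2
  auc_raw <- u_obs / (n1 * n2)
  auc <- pmax(auc_raw, 1 - auc_raw)

  # permutation: n_shuffle random class-1 memberships, one matrix product
  L <- matrix(0, n_shuffle, n)
  for (s in seq_len(n_shuffle)) L[s, sample(n, n1)] <- 1
  u_perm <- L %*% R - n1 * (n1 + 1) / 2
  a_perm <- u_perm / (n1 * n2)
  a_perm <- pmax(a_perm, 1 - a_perm)
  exceed <- colSums(a_perm >= rep(auc, each = n_shuffle))
  p <- (1 + exceed) / (1 + n_shuffle)

  if (is.null(times)) times <- seq_len(ncol(rates))
  structure(list(auc = auc, auc_raw = auc_raw, p = p, sig = p < alpha,
                 times = times, n1 = n1, n2 = n2, variable = variable,
                 saliency = saliency, n_shuffle = n_shuffle, alpha = alpha),
            class = "auc_series")
}

#' @export
print.auc_series <- function(x, ...) {
  cat(sprintf(
    "auc_series (%s, %s): %d bins, n=%d vs %d, %d significant (alpha=%g)\n",
    x$variable, x$saliency, length(x$auc), x$n1, x$n2, sum(x$sig), x$alpha))
  invisible(x)
}

#' Classify a neuron as coding a variable
#'
#' A neuron codes a variable if its AUC is significant for at least `consec`
#' consecutive bins (75 ms at 25-ms bins) inside the analysis window.
#'
#' @param auc_series An `auc_series`.
#' @param window Analysis window (s), default `c(0, 1)`.
#' @param consec Required consecutive significant bins (default 3).
#' @return Logical.
#' @export
classify_coder <- function(auc_series, window = c(0, 1), consec = 3) {
  if (is.null(auc_series)) return(FALSE)
  sel <- auc_series$times >= window[1] & auc_series$times <= window[2]
  s <- auc_series$sig[sel]
  if (!length(s)) return(FALSE)
  r <- rle(s)
  any(r$values & r$lengths >= consec)
}

#' Fraction of neurons coding a variable over time
#'
#' Per-bin fraction of neurons with a significant AUC, optionally normalised
#' (baseline-subtracted, maximum-normalised).  Normalisation is applied only
#' if the fraction rises at least 0.10 above its baseline mean; otherwise
#' the baseline-subtracted series is returned un-normalised.
#'
#' @param series_list List of `auc_series` (NULL entries skipped), on a
#'   common time base.
#' @param baseline Baseline window (s), default `c(-0.5, 0)`.
#' @param cohort Optional label.
#' @return A `coding_fraction`: list with `fraction`, `normalized`,
#'   `times`, `n_neurons`, `normalized_applied`, `cohort`.
#' @export
coding_fraction <- function(series_list, baseline = c(-0.5, 0),
                            cohort = NA) {
  series_list <- Filter(Negate(is.null), series_list)
  if (!length(series_list)) stop("need at least one AUC series")
  times <- series_list[[1]]$times
  sig <- vapply(series_list, function(s) as.numeric(s$sig),
                numeric(length(times)))
  frac <- rowMeans(sig)
  bsel <- times >= baseline[1] & times <= baseline[2]
  b <- mean(frac[bsel])
  centered <- frac - b
  apply_norm <- max(frac) - b >= 0.10
  normalized <- if (apply_norm && max(centered) > 0) {
    centered / max(centered)
  } else centered
  structure(list(fraction = frac, normalized = normalized, times = times,
                 baseline = baseline, baseline_mean = b,
                 n_neurons = length(series_list),
                 normalized_applied = apply_norm, cohort = cohort),
            class = "coding_fraction")
}

#' Onset of a coding-fraction increase
#'
#' First post-stimulus bin at which the fraction exceeds its baseline mean
#' plus `z_thresh` pooled baseline standard deviations.  With a constant
#' baseline (zero variance) any increase crosses.  Robustness at thresholds
#' 1, 2, 3 is reported alongside.
#'
#' @param fraction Numeric fraction series (or a `coding_fraction`).
#' @param times Bin centres (s); taken from the object if given.
#' @param z_thresh Threshold in baseline SDs (default 2).
#' @param baseline Baseline window (s).
#' @param consec Number of consecutive above-threshold bins required at the
#'   crossing (default 1: the first crossing bin itself).  A value of 2
#'   suppresses isolated single-bin spikes of the binomial fraction noise
#'   and is recommended inside bootstrap loops.
#' @return An `onset_estimate`: list with `onset_s` (or `NA` if the series
#'   never crosses), `threshold`, `method`, `robustness`.
#' @export
onset_from_fraction <- function(fraction, times = NULL, z_thresh = 2,
                                baseline = c(-0.5, 0), consec = 1) {
  if (inherits(fraction, "coding_fraction")) {
    times <- fraction$times
    fraction <- fraction$fraction
  }
  stopifnot(length(times) == length(fraction))
  bsel <- times >= baseline[1] & times <= baseline[2]
  if (!any(bsel)) stop("baseline window not covered")
  mu <- mean(fraction[bsel])
  sdv <- stats::sd(fraction[bsel])
  if (!is.finite(sdv) || sdv == 0) sdv <- .Machine$double.eps
  onset_at <- function(z) {
    thr <- mu + z * sdv
    above <- times > 0 & fraction > thr
    idx <- which(above)
    if (consec > 1) {
      idx <- idx[vapply(idx, function(i) {
        i + consec - 1 <= length(above) && all(above[i:(i + consec - 1)])
      }, logical(1))]
    }
    if (!length(idx)) NA_real_ else times[min(idx)]
  }
  structure(list(onset_s = onset_at(z_thresh),
                 threshold = mu + z_thresh * sdv, baseline_mean = mu,
                 baseline_sd = sdv, z_thresh = z_thresh,
                 method = "population_fraction",
                 robustness = vapply(c(1, 2, 3), onset_at, numeric(1))),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  on <- if (is.na(x$onset_s)) "none" else sprintf("%.0f ms", 1000 * x$onset_s)
  cat(sprintf("coding onset (%s): %s", x$method, on))
  if (!is.null(x$ci95)) {
    cat(sprintf("  [95%% CI %.0f, %.0f ms]", 1000 * x$ci95[1],
                1000 * x$ci95[2]))
  }
  cat("\n")
  invisible(x)
}

#' Bootstrap the coding onset over the neuronal population
#'
#' Neurons are resampled with replacement `n_boot` times; the coding
#' fraction and its onset are recomputed per resample.  Returns the
#' bootstrap mean onset and 95% percentile interval.  Flagged unreliable if
#' more than half the resamples yield no onset.
#'
#' @param series_list List of `auc_series` (one per neuron).
#' @param n_boot Number of resamples (default 1000).
#' @param z_thresh,baseline,consec Passed to [onset_from_fraction()];
#'   `consec` defaults to 2 here for stability of the resampled fraction.
#' @param seed Seed for the resampling.
#' @return An `onset_estimate` with `onset_s` (bootstrap mean), `ci95`,
#'   `onsets` (per resample), `flagged`.
#' @export
bootstrap_onset <- function(series_list, n_boot = 1000, z_thresh = 2,
                            baseline = c(-0.5, 0), consec = 2, seed = 1) {
  series_list <- Filter(Negate(is.null), series_list)
  n <- length(series_list)
  stopifnot(n >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  times <- series_list[[1]]$times
  sig <- vapply(series_list, function(s) as.numeric(s$sig),
                numeric(length(times)))
  onsets <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample(n, n, replace = TRUE)
    frac <- rowMeans(sig[, idx, drop = FALSE])
    onsets[b] <- onset_from_fraction(frac, times, z_thresh, baseline,
                                     consec = consec)$onset_s
  }
  ok <- !is.na(onsets)
  structure(list(onset_s = mean(onsets[ok]),
                 ci95 = if (any(ok)) unname(stats::quantile(
                   onsets[ok], c(0.025, 0.975))) else c(NA, NA),
                 onsets = onsets, flagged = mean(!ok) > 0.5,
                 n_neurons = n, method = "bootstrap"),
            class = "onset_estimate")
}

#' Session-level coding onset from the population-averaged rate
#'
#' For sessions with at least ten neurons, the AUC analysis is run on the
#' rate averaged across neurons (per trial and bin); the onset is the first
#' significant bin after the stimulus.
#'
#' @param tensor A `rate_tensor` (neurons x trials x bins) for the session.
#' @param labels Two-class labels per trial (e.g. hit vs miss).
#' @param min_neurons Minimum neurons (default 10); below it `NULL`.
#' @param n_shuffle Label shuffles (default 1000).
#' @param consec Consecutive significant bins required (default 1: the
#'   first significant post-stimulus bin; 2 suppresses isolated
#'   false-positive bins of the permutation test).
#' @param seed Seed for the shuffles.
#' @param ... Passed to [auc_timecourse()].
#' @return An `onset_estimate` (with the session's `auc_series` attached),
#'   or `NULL` if the session is too small.
#' @export
session_onset <- function(tensor, labels, min_neurons = 10,
                          n_shuffle = 1000, consec = 1, seed = NULL, ...) {
  stopifnot(inherits(tensor, "rate_tensor"))
  if (dim(tensor$values)[1] < min_neurons) return(NULL)
  pop <- apply(tensor$values, c(2, 3), mean)
  ser <- auc_timecourse(pop, labels, times = tensor$bin_centers,
                        n_shuffle = n_shuffle, seed = seed, ...)
  if (is.null(ser)) return(NULL)
  above <- ser$times > 0 & ser$sig
  idx <- which(above)
  if (consec > 1) {
    idx <- idx[vapply(idx, function(i) {
      i + consec - 1 <= length(above) && all(above[i:(i + consec - 1)])
    }, logical(1))]
  }
  structure(list(onset_s = if (length(idx)) ser$times[min(idx)] else NA_real_,
                 series = ser, method = "session_population_rate"),
            class = "onset_estimate")
}

#' Laminar map of coding fractions
#'
#' Fraction of significantly coding neurons per 50-um depth bin (0-1150 um,
#' 23 bins) and time bin.  A smoothed copy (2-D Gaussian, SD 1.3 bins in
#' both depth and time) is attached for display.
#'
#' @param series_list List of `auc_series`, one per neuron.
#' @param depths Depth below dura (um) per neuron.
#' @param depth_max,depth_bin Depth range and bin (um).
#' @param smooth_sd Display-smoothing SD in bins.
#' @return List with `map` (depth x time fraction), `smoothed`, `counts`
#'   (neurons per depth bin), `depth_edges`, `times`.
#' @export
laminar_map <- function(series_list, depths, depth_max = 1150,
                        depth_bin = 50, smooth_sd = 1.3) {
  keep <- !vapply(series_list, is.null, logical(1))
  series_list <- series_list[keep]; depths <- depths[keep]
  stopifnot(length(series_list) == length(depths))
  times <- series_list[[1]]$times
  edges <- seq(0, depth_max, by = depth_bin)
  nd <- length(edges) - 1
  dbin <- pmin(pmax(findInterval(depths, edges, rightmost.closed = TRUE),
                    1L), nd)
  sig <- t(vapply(series_list, function(s) as.numeric(s$sig),
                  numeric(length(times))))   # neurons x time
  map <- matrix(NA_real_, nd, length(times))
  counts <- tabulate(dbin, nd)
  for (d in seq_len(nd)) {
    if (counts[d] > 0) map[d, ] <- colMeans(sig[dbin == d, , drop = FALSE])
  }
  # separable Gaussian smoothing, NA-aware (normalised by available mass)
  g <- function(sd) {
    x <- seq(-ceiling(3 * sd), ceiling(3 * sd))
    w <- exp(-0.5 * (x / sd)^2); w / sum(w)
  }
  smooth1 <- function(m, w, along_rows) {
    if (along_rows) m <- t(m)
    filled <- ifelse(is.na(m), 0, m)
    mask <- 1 - is.na(m)
    num <- apply(filled, 2, function(col)
      stats::filter(col, w, sides = 2, circular = FALSE))
    den <- apply(mask, 2, function(col)
      stats::filter(col, w, sides = 2, circular = FALSE))
    out <- num / pmax(den, 1e-12)
    if (along_rows) t(out) else out
  }
  w <- g(smooth_sd)
  sm <- smooth1(smooth1(map, w, FALSE), w, TRUE)
  list(map = map, smoothed = sm, counts = counts, depth_edges = edges,
       times = times)
}

#' Zone statistics of a laminar map
#'
#' Mean coding fraction per laminar zone (SG/G/IG) over a time window,
#' computed from per-neuron significance; zones with fewer than
#' `min_neurons` neurons return `NA`.
#'
#' @param series_list,depths As in [laminar_map()].
#' @param window Time window (s).
#' @param min_neurons Minimum neurons per zone (default 10).
#' @return Named numeric: mean fraction per zone.
#' @export
laminar_zone_stats <- function(series_list, depths, window = c(0.2, 1),
                               min_neurons = 10) {
  keep <- !vapply(series_list, is.null, logical(1))
  series_list <- series_list[keep]; depths <- depths[keep]
  zone <- assign_layer(depths)
  times <- series_list[[1]]$times
  tsel <- times >= window[1] & times <= window[2]
  per_neuron <- vapply(series_list, function(s) mean(s$sig[tsel]),
                       numeric(1))
  vapply(c(SG = "SG", G = "G", IG = "IG"), function(z) {
    sel <- zone == z
    if (sum(sel) < min_neurons) NA_real_ else mean(per_neuron[sel])
  }, numeric(1))
}

#' Regression of coding onset on reaction time
#'
#' Ordinary least squares of onset on reaction time across sessions (or
#' bootstrap conditions).  With `fixed_slope = 1` the offset is the mean of
#' `rt - onset`: how long coding precedes the report.
#'
#' @param onsets,rts Paired onsets and reaction times (s); pairs with `NA`
#'   dropped.
#' @param fixed_slope Optional fixed slope (e.g. 1).
#' @return List with `slope`, `intercept`, `offset_s` (fixed-slope mode),
#'   `r`, `p`, `n`.
#' @export
onset_rt_regression <- function(onsets, rts, fixed_slope = NULL) {
  ok <- !is.na(onsets) & !is.na(rts)
  onsets <- onsets[ok]; rts <- rts[ok]
  if (!is.null(fixed_slope)) {
    # fixed-slope offsets are well defined from two points on (e.g. one
    # summary point per training cohort)
    if (length(onsets) < 2) stop("need at least 2 onset/RT pairs")
    ct <- if (length(onsets) >= 3) {
      suppressWarnings(stats::cor.test(rts, onsets))
    } else NULL
    off <- mean(rts - fixed_slope * onsets)
    return(list(slope = fixed_slope, intercept = -off, offset_s = off,
                r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
                p = if (is.null(ct)) NA_real_ else ct$p.value,
                n = length(onsets)))
  }
  if (length(onsets) < 3) stop("need at least 3 onset/RT pairs")
  ct <- suppressWarnings(stats::cor.test(rts, onsets))
  fit <- stats::lm(onsets ~ rts)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), offset_s = NA,
       r = unname(ct$estimate), p = ct$p.value, n = length(onsets))
}
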