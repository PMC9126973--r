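## Rate estimation and neuron-level metadata: causal half-Gaussian smoothing
## of binned spike counts, baseline z-scoring, waveform-based cell-type
## classification, laminar-zone assignment and inclusion filters.

#' Causal half-Gaussian smoothing kernel
#'
#' Kernel weights over lagged 10-ms bins: a Gaussian restricted to
#' nonnegative lags (causal: the rate estimate at time t uses only spikes at
#' or before t), truncated at 4 SD and renormalised to unit mass so the
#' smoothed counts remain unbiased rate estimates.
#'
#' @param kernel_sd Kernel standard deviation in seconds.
#' @param bin_width Bin width in seconds.
#' @return Numeric vector of weights (lag 0 first), summing to 1.
#' @keywords internal
half_gaussian_kernel <- function(kernel_sd, bin_width) {
  if (kernel_sd <= 0) return(1)
  n <- ceiling(4 * kernel_sd / bin_width)
  lags <- (0:n) * bin_width
  w <- exp(-0.5 * (lags / kernel_sd)^2)
  w / sum(w)
}

#' Smoothed, event-aligned firing-rate tensor
#'
#' Spikes are counted in 10-ms bins aligned to per-trial events, convolved
#' with a causal half-Gaussian kernel (unit mass) and converted to Hz.
#' Causality means no future leakage: a spike cannot raise the rate of bins
#' that end before it.
#'
#' @param spikes A `spike_set` (see [as_spike_set()]) or a list of per-neuron
#'   spike-time vectors (s).
#' @param events Numeric vector of alignment times (s), one per trial.
#' @param window Length-2 numeric, window around each event in seconds,
#'   e.g. `c(-1, 2.5)`.
#' @param kernel_sd Smoothing SD in seconds (default 0.05; use 0.01 for
#'   high-temporal-resolution displays and 0.1 for noise correlations).
#' @param bin_width Bin width in seconds (default 0.01).
#' @return A `rate_tensor`: list with `values` (array neurons x trials x
#'   bins, Hz), `bin_centers` (s relative to event), `bin_width`,
#'   `kernel_sd`, `window`, `unit` = "Hz".
#' @export
compute_rates <- function(spikes, events, window = c(-1, 2.5),
                          kernel_sd = 0.05, bin_width = 0.01) {
  st <- if (inherits(spikes, "spike_set")) spikes$spike_times else spikes
  stopifnot(is.list(st), length(events) >= 1, window[2] > window[1])
  n_bins <- round((window[2] - window[1]) / bin_width)
  edges <- window[1] + bin_width * (0:n_bins)
  centers <- edges[-1] - bin_width / 2
  kern <- half_gaussian_kernel(kernel_sd, bin_width)
  nk <- length(kern)
  n_neu <- length(st); n_tr <- length(events)
  vals <- array(0, dim = c(n_neu, n_tr, n_bins))
  for (i in seq_len(n_neu)) {
    s <- st[[i]]
    if (length(s) == 0) next
    for (j in seq_len(n_tr)) {
      # pad the count window backwards so causal smoothing has full history
      rel <- s - events[j]
      rel <- rel[rel >= window[1] - nk * bin_width & rel < window[2]]
      if (length(rel) == 0) next
      cnt <- tabulate(
        floor((rel - (window[1] - nk * bin_width)) / bin_width) + 1L,
        nbins = n_bins + nk)
      sm <- stats::filter(cnt, kern, method = "convolution", sides = 1)
      vals[i, j, ] <- as.numeric(sm[(nk + 1):(nk + n_bins)]) / bin_width
    }
  }
  structure(list(values = vals, bin_centers = centers, bin_width = bin_width,
                 kernel_sd = kernel_sd, window = window, unit = "Hz",
                 align_event = attr(events, "align_event")),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "rate_tensor: %d neurons x %d trials x %d bins (%s), window [%g, %g] s, kernel SD %g ms\n",
    d[1], d[2], d[3], x$unit, x$window[1], x$window[2], 1000 * x$kernel_sd))
  invisible(x)
}

#' Z-score a rate tensor against its pre-stimulus baseline
#'
#' Per neuron, subtracts the mean and divides by the standard deviation of
#' the baseline period, both computed over all trials x baseline bins.
#' Neurons with zero baseline SD cannot be z-scored and are flagged.
#'
#' @param tensor A `rate_tensor` whose window covers the baseline.
#' @param baseline Length-2 numeric, baseline period in seconds relative to
#'   the alignment event (default `c(-1, -0.2)`).
#' @return A `rate_tensor` in z-units with attributes `baseline_mean`,
#'   `baseline_sd` and `flagged` (logical per neuron; flagged neurons hold
#'   `NA`).
#' @export
zscore_rates <- function(tensor, baseline = c(-1, -0.2)) {
  stopifnot(inherits(tensor, "rate_tensor"))
  bidx <- tensor$bin_centers >= baseline[1] & tensor$bin_centers <= baseline[2]
  if (!any(bidx)) stop("window does not include the baseline period")
  v <- tensor$values
  n_neu <- dim(v)[1]
  mu <- sd <- numeric(n_neu)
  out <- v
  for (i in seq_len(n_neu)) {
    b <- v[i, , bidx]
    mu[i] <- mean(b)
    sd[i] <- stats::sd(as.numeric(b))
    out[i, , ] <- if (sd[i] > 0) (v[i, , ] - mu[i]) / sd[i] else NA_real_
  }
  res <- tensor
  res$values <- out
  res$unit <- "z"
  res$baseline <- baseline
  res$baseline_mean <- mu
  res$baseline_sd <- sd
  res$flagged <- sd == 0
  res
}

#' Classify cell type from waveform peak-to-trough delay
#'
#' Narrow-spiking (putative inhibitory): delay < 0.45 ms; broad-spiking
#' (putative excitatory): delay > 0.55 ms; intermediate values are left
#' unclassified.  Delays are capped at 1 ms upstream.
#'
#' @param peak_to_trough_ms Peak-to-trough delay(s) in ms, in `(0, 1]`.
#' @return Character vector: `"narrow"`, `"broad"` or `"unclassified"`.
#' @export
classify_celltype <- function(peak_to_trough_ms) {
  stopifnot(all(peak_to_trough_ms > 0), all(peak_to_trough_ms <= 1))
  ifelse(peak_to_trough_ms < 0.45, "narrow",
         ifelse(peak_to_trough_ms > 0.55, "broad", "unclassified"))
}

#' Assign laminar zone from recording depth
#'
#' The granular (thalamorecipient) layer is taken to span 400-550 um from
#' the dura, boundaries inclusive; shallower is supragranular, deeper
#' infragranular.
#'
#' @param depth_um Depth(s) below the dura in micrometres (>= 0).
#' @return Character vector: `"SG"`, `"G"` or `"IG"`.
#' @export
assign_layer <- function(depth_um) {
  stopifnot(all(depth_um >= 0))
  ifelse(depth_um < 400, "SG", ifelse(depth_um <= 550, "G", "IG"))
}

#' Neuron inclusion filters
#'
#' Context-specific inclusion rules:
#' \describe{
#'   \item{`glm`}{session-average firing rate > 0.5 Hz (sparser neurons make
#'     the penalised Poisson fit unstable);}
#'   \item{`nc`}{session-average firing rate > 1 Hz;}
#'   \item{`responsive`}{z-scored rate exceeds 2 at some bin of the stimulus
#'     epoch in at least one visual condition, with at least `min_trials`
#'     trials per required condition;}
#'   \item{`stability`}{spikes present in more than 90 of 100 equal time
#'     bins spanning the session.}
#' }
#'
#' @param context One of `"glm"`, `"nc"`, `"responsive"`, `"stability"`.
#' @param session_rate_hz Session-average firing rate (for `glm`/`nc`).
#' @param z_tensor Z-scored `rate_tensor` for one neuron's visual conditions
#'   (`responsive`): list of matrices trials x bins restricted to the
#'   stimulus epoch, one per condition.
#' @param spike_times,session_span Spike times and `c(start, end)` of the
#'   session (`stability`).
#' @param min_trials Minimum trials per condition for `responsive`
#'   (default 3).
#' @return Logical: does the neuron pass?
#' @export
inclusion_filters <- function(context, session_rate_hz = NULL,
                              z_tensor = NULL, spike_times = NULL,
                              session_span = NULL, min_trials = 3) {
  switch(context,
    glm = {
      stopifnot(!is.null(session_rate_hz))
      session_rate_hz > 0.5
    },
    nc = {
      stopifnot(!is.null(session_rate_hz))
      session_rate_hz > 1
    },
    responsive = {
      stopifnot(is.list(z_tensor))
      if (any(vapply(z_tensor, nrow, 1L) < min_trials)) return(FALSE)
      any(vapply(z_tensor, function(m) {
        any(colMeans(m) > 2, na.rm = TRUE)
      }, logical(1)))
    },
    stability = {
      stopifnot(!is.null(spike_times), !is.null(session_span))
      edges <- seq(session_span[1], session_span[2], length.out = 101)
      occ <- tabulate(findInterval(spike_times, edges,
                                   rightmost.closed = TRUE), nbins = 100)
      sum(occ > 0) > 90
    },
    stop("unknown inclusion context: ", context)
  )
}

#' Build a spike set from per-neuron spike times and metadata
#'
#' @param spike_times List of numeric vectors (s), one per neuron, each
#'   sorted ascending.
#' @param neurons Data frame with one row per neuron: `neuron_id`,
#'   `depth_um`, `p2t_ms` and optionally `session_id`.
#' @return A `spike_set` object.
#' @export
as_spike_set <- function(spike_times, neurons) {
  stopifnot(length(spike_times) == nrow(neurons),
            all(c("neuron_id", "depth_um", "p2t_ms") %in% names(neurons)))
  for (s in spike_times) {
    if (is.unsorted(s)) stop("spike times must be sorted ascending")
  }
  if (any(neurons$depth_um < 0)) stop("depths must be >= 0")
  neurons$p2t_ms <- pmin(neurons$p2t_ms, 1)  # cap at 1 ms
  names(spike_times) <- neurons$neuron_id
  structure(list(spike_times = spike_times, neurons = neurons),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  n <- vapply(x$spike_times, length, 1L)
  cat(sprintf("spike_set: %d neurons, %d spikes (median rate span %.0f s)\n",
              length(n), sum(n),
              stats::median(vapply(x$spike_times, function(s)
                if (length(s) > 1) diff(range(s)) else 0, 1))))
  invisible(x)
}

#' Session-average firing rates of a spike set
#'
#' @param spikes A `spike_set`.
#' @param session_span `c(start, end)` in seconds.
#' @return Numeric vector, Hz per neuron.
#' @export
session_rates <- function(spikes, session_span) {
  dur <- diff(session_span)
  vapply(spikes$spike_times, function(s)
    sum(s >= session_span[1] & s <= session_span[2]) / dur, numeric(1))
}
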