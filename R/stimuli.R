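#' Shepard-style harmonic stimulus
#'
#' Constructs a complex tone of five octave-spaced harmonics with a fixed
#' Gaussian weight profile over log2-frequency.  The weight profile is
#' anchored at a fixed centre of 13.5 octaves (2^13.5 = 11585 Hz) for every
#' stimulus, so stimuli with a higher centre tone receive decreasing weights
#' for the upper harmonics and increasing weights for the lower ones, making
#' the stimulus space circular.
#'
#' Frequencies are literal powers of two (2^13 = 8192 Hz), not musical-pitch
#' approximations.
#'
#' @param center_exponent Centre tone as a log2-frequency exponent (octaves),
#'   must lie in `[13, 14]`.
#' @param weight_sigma Standard deviation (octaves) of the Gaussian weight
#'   profile over log2-frequency.  Default 1 octave.
#' @return An object of class `"shepard_stimulus"` with fields
#'   `center_exponent`, `harmonic_exponents`, `harmonic_frequencies` (Hz) and
#'   `weights` (nonnegative, summing to 1).
#' @examples
#' s <- make_shepard(13.5)
#' round(s$harmonic_frequencies)
#' @export
make_shepard <- function(center_exponent, weight_sigma = 1) {
  if (!is.numeric(center_exponent) || length(center_exponent) != 1L ||
      center_exponent < 13 || center_exponent > 14) {
    stop("`center_exponent` must be a single value in [13, 14]")
  }
  if (!is.numeric(weight_sigma) || weight_sigma <= 0) {
    stop("`weight_sigma` must be positive")
  }
  k <- -2:2
  exponents <- center_exponent + k
  freqs <- 2^exponents
  # fixed profile centred at 13.5 octaves, independent of the stimulus centre
  w <- exp(-0.5 * ((exponents - 13.5) / weight_sigma)^2)
  w <- w / sum(w)
  structure(
    list(center_exponent = center_exponent,
         harmonic_exponents = exponents,
         harmonic_frequencies = freqs,
         weights = w),
    class = "shepard_stimulus")
}

#' @export
print.shepard_stimulus <- function(x, ...) {
  cat(sprintf("Shepard stimulus, centre 2^%.4g = %.0f Hz\n",
              x$center_exponent, 2^x$center_exponent))
  tab <- data.frame(harmonic = -2:2,
                    frequency_hz = round(x$harmonic_frequencies, 1),
                    weight = round(x$weights, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Four-point stimulus set for a change-detection session
#'
#' Recording sessions use only four stimulus values A, B, C, D per modality:
#' AB and CD are separated by roughly the animal's detection threshold, while
#' AC and BD are maximally separated (90 degrees for orientation, half an
#' octave for the auditory centre tone).  Orientation arithmetic is circular
#' (modulo 360).
#'
#' @param modality `"visual"` or `"auditory"`.
#' @param base_feature Value of stimulus A: orientation in degrees (visual)
#'   or centre-tone exponent in octaves (auditory).
#' @param threshold_change Threshold-level change: degrees or partial octave.
#' @return Object of class `"stimulus_set"` with fields `modality`, `A`, `B`,
#'   `C`, `D`, `threshold_change`, `maximal_change`.
#' @examples
#' make_stimulus_set("visual", 100, 7)   # A=100, B=107, C=190, D=197
#' @export
make_stimulus_set <- function(modality = c("visual", "auditory"),
                              base_feature, threshold_change) {
  modality <- match.arg(modality)
  maximal <- if (modality == "visual") 90 else 0.5
  if (threshold_change <= 0 || threshold_change >= maximal) {
    stop("`threshold_change` must be in (0, ", maximal, ") for ", modality)
  }
  wrap <- function(x) if (modality == "visual") x %% 360 else x
  A <- wrap(base_feature)
  B <- wrap(base_feature + threshold_change)
  C <- wrap(base_feature + maximal)
  D <- wrap(base_feature + maximal + threshold_change)
  structure(
    list(modality = modality, A = A, B = B, C = C, D = D,
         threshold_change = threshold_change, maximal_change = maximal),
    class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  unit <- if (x$modality == "visual") "deg" else "oct"
  cat(sprintf("%s stimulus set (%s): A=%.4g B=%.4g C=%.4g D=%.4g (thr %.4g, max %.4g)\n",
              x$modality, unit, x$A, x$B, x$C, x$D,
              x$threshold_change, x$maximal_change))
  invisible(x)
}

#' Circular difference between two orientations
#'
#' Smallest absolute angular distance, in degrees, on the 180-degree-periodic
#' orientation circle is not what change detection uses: grating changes
#' preserve drift direction so the space is 360-periodic.  Returns the
#' difference `b - a` wrapped to `(-180, 180]`.
#'
#' @param a,b Orientations in degrees.
#' @return Signed circular difference in degrees.
#' @export
orientation_diff <- function(a, b) {
  d <- (b - a) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Sample a task-A trial sequence (stimuli only)
#'
#' Trial types are pseudorandomly presented, block-shuffled per 10 trials
#' with proportions 10% catch, 41% visual, 41% auditory, 8% multimodal.
#' Inter-trial (inter-change) intervals are drawn from an exponential
#' distribution with mean 6 s truncated by rejection to `[3, 20]` s.
#' Within visual/auditory trials, saliency alternates between threshold and
#' maximal change and the post-change feature moves around the 4-point
#' stimulus set.
#'
#' @param n_trials Number of trials (at least 10).
#' @param visual_set,auditory_set `stimulus_set` objects.
#' @param iti_mean,iti_min,iti_max ITI distribution parameters in seconds
#'   (exponential rate `1/iti_mean` before truncation).
#' @param rng_seed Optional integer seed; if supplied the sequence is
#'   reproducible.
#' @return A `trial_table` data frame (stimuli only: `choice`, `outcome`,
#'   `reaction_time` are `NA`) with one row per trial.
#' @export
sample_trial_sequence <- function(n_trials, visual_set = make_stimulus_set("visual", 100, 7),
                                  auditory_set = make_stimulus_set("auditory", 13.25, 1 / 32),
                                  iti_mean = 6, iti_min = 3, iti_max = 20,
                                  rng_seed = NULL) {
  if (n_trials < 10) stop("`n_trials` must be at least 10")
  if (!is.null(rng_seed)) set.seed(rng_seed)

  # block-shuffle per 10 trials: each block holds 1 catch, 4 visual (.41 -> 4.1),
  # 4 auditory, 1 multimodal on average; fractional parts carried across blocks
  props <- c(catch = 0.10, visual = 0.41, auditory = 0.41, multimodal = 0.08)
  n_blocks <- ceiling(n_trials / 10)
  types <- character(0)
  carry <- rep(0, 4)
  for (b in seq_len(n_blocks)) {
    want <- props * 10 + carry
    n_int <- floor(want)
    rem <- want - n_int
    short <- 10 - sum(n_int)
    if (short > 0) {
      extra <- order(rem, decreasing = TRUE)[seq_len(short)]
      n_int[extra] <- n_int[extra] + 1
      rem[extra] <- rem[extra] - 1
    }
    carry <- rem
    block <- sample(rep(names(props), times = n_int))
    types <- c(types, block)
  }
  types <- types[seq_len(n_trials)]

  itis <- replicate(n_trials, {
    repeat {
      x <- stats::rexp(1, rate = 1 / iti_mean)
      if (x >= iti_min && x <= iti_max) return(x)
    }
  })
  change_time <- cumsum(itis)

  # walk the 4-point set: threshold steps (A<->B, C<->D) and maximal jumps
  pick_change <- function(set, saliency) {
    pts <- c(A = set$A, B = set$B, C = set$C, D = set$D)
    pre <- sample(names(pts), 1L)
    post <- switch(pre,
      A = if (saliency == "thr") "B" else "C",
      B = if (saliency == "thr") "A" else "D",
      C = if (saliency == "thr") "D" else "A",
      D = if (saliency == "thr") "C" else "B")
    c(pts[[pre]], pts[[post]])
  }

  saliency <- ifelse(types %in% c("visual", "auditory"),
                     sample(c("thr", "max"), n_trials, replace = TRUE), "none")
  pre_feature <- post_feature <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    if (types[i] == "visual") {
      f <- pick_change(visual_set, saliency[i])
    } else if (types[i] == "auditory") {
      f <- pick_change(auditory_set, saliency[i])
    } else next
    pre_feature[i] <- f[1]; post_feature[i] <- f[2]
  }

  correct_side <- c(catch = "none", visual = "left", auditory = "right",
                    multimodal = "none")[types]

  tt <- data.frame(
    trial_index = seq_len(n_trials),
    trial_type = types,
    pre_feature = pre_feature,
    post_feature = post_feature,
    saliency = saliency,
    change_time = change_time,
    choice = NA_character_,
    correct_side = unname(correct_side),
    outcome = NA_character_,
    reaction_time = NA_real_,
    photostim = "none",
    reward_time = NA_real_,
    stringsAsFactors = FALSE)
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Modality bias rule for online trial selection
#'
#' If one spout received more than 90% of the licks over the last 10 trials,
#' the next trial is the other modality with probability 0.95 (strict
#' inequality: exactly 90% does not trigger the rule).
#'
#' @param recent_choices Character vector of the last 10 trials' lick sides
#'   (`"left"`, `"right"`, `"none"`).  Left is the visual spout, right the
#'   auditory spout.
#' @param candidate_type Proposed next trial type.
#' @return The (possibly replaced) trial type.
#' @export
apply_bias_rule <- function(recent_choices, candidate_type) {
  licks <- recent_choices[recent_choices %in% c("left", "right")]
  if (length(licks) == 0) return(candidate_type)
  p_left <- mean(licks == "left")
  biased <- if (p_left > 0.9) "auditory" else if (1 - p_left > 0.9) "visual" else NULL
  if (is.null(biased)) return(candidate_type)
  if (stats::runif(1) < 0.95) biased else candidate_type
}
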