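## Convenience layer chaining the primitive analyses at the session and
## cohort level: hit/miss AUC series for every neuron of a session, and
## onset-versus-reaction-time summaries across sessions.

#' Group post-change orientations into the AB / CD pairs
#'
#' @param post_feature Post-change features (deg or octave exponent).
#' @param set The session's `stimulus_set`.
#' @return Factor `"AB"` / `"CD"` (`NA` where the feature is missing).
#' @export
label_orientation_pair <- function(post_feature,
                                   set = make_stimulus_set("visual", 100, 7)) {
  out <- rep(NA_character_, length(post_feature))
  ok <- !is.na(post_feature)
  if (set$modality == "visual") {
    dab <- pmin(abs(orientation_diff(set$A, post_feature[ok])),
                abs(orientation_diff(set$B, post_feature[ok])))
    dcd <- pmin(abs(orientation_diff(set$C, post_feature[ok])),
                abs(orientation_diff(set$D, post_feature[ok])))
  } else {
    dab <- pmin(abs(post_feature[ok] - set$A), abs(post_feature[ok] - set$B))
    dcd <- pmin(abs(post_feature[ok] - set$C), abs(post_feature[ok] - set$D))
  }
  out[ok] <- ifelse(dab <= dcd, "AB", "CD")
  factor(out, levels = c("AB", "CD"))
}

#' Per-neuron hit/miss AUC series for one session
#'
#' Computes 25-ms-bin rate tensors (10-ms smoothing) aligned to the change,
#' restricts to visual hit and miss trials, and runs [auc_timecourse()] for
#' every neuron.
#'
#' @param session A `session`.
#' @param window Analysis window (s), default `c(-0.5, 1.5)`.
#' @param saliency Saliency levels pooled (default both `thr` and `max`, to
#'   keep class counts workable at session size).
#' @param n_shuffle Permutations per neuron.
#' @param min_per_class Minimum trials per class.
#' @param seed Base seed (neuron i uses `seed + i`).
#' @return List with `series` (per neuron; `NULL` where skipped), `rts`
#'   (hit reaction times), `tensor`, `trial_idx`, `labels`.
#' @export
session_hitmiss_series <- function(session, window = c(-0.5, 1.5),
                                   saliency = c("thr", "max"),
                                   n_shuffle = 1000, min_per_class = 10,
                                   seed = 1) {
  tr <- session$trials
  idx <- which(tr$trial_type == "visual" & tr$saliency %in% saliency &
                 tr$outcome %in% c("hit", "miss") & tr$photostim == "none")
  tensor <- compute_rates(session$spikes, tr$change_time[idx],
                          window = window, kernel_sd = 0.01,
                          bin_width = 0.025)
  labels <- tr$outcome[idx] == "hit"
  n_neu <- dim(tensor$values)[1]
  series <- lapply(seq_len(n_neu), function(i) {
    auc_timecourse(tensor$values[i, , ], labels,
                   times = tensor$bin_centers, n_shuffle = n_shuffle,
                   min_per_class = min_per_class, variable = "hitmiss",
                   seed = seed + i)
  })
  list(series = series, rts = tr$reaction_time[idx][labels],
       tensor = tensor, trial_idx = idx, labels = labels)
}

#' Onset-versus-reaction-time summary across sessions
#'
#' For every session, computes the hit/miss coding onset of the
#' population-averaged rate ([session_onset()]) and the mean hit reaction
#' time; returns the paired vectors together with the pooled per-neuron AUC
#' series (for cohort-level bootstrap onsets).
#'
#' @param sessions List of `session` objects.
#' @param n_shuffle Permutations (default 1000).
#' @param min_neurons Minimum neurons per session for the population-rate
#'   onset.
#' @param consec Consecutive significant bins required for a session onset
#'   (default 2: robust against isolated permutation false positives).
#' @param seed Base seed.
#' @param ... Passed to [session_hitmiss_series()].
#' @return List with `onsets_s`, `mean_rt_s` (per session), `series`
#'   (pooled neurons), `depths` (pooled).
#' @export
cohort_onset_summary <- function(sessions, n_shuffle = 1000,
                                 min_neurons = 10, consec = 2, seed = 1,
                                 ...) {
  onsets <- rts <- numeric(length(sessions))
  all_series <- list(); depths <- numeric(0)
  for (s in seq_along(sessions)) {
    se <- sessions[[s]]
    hm <- session_hitmiss_series(se, n_shuffle = n_shuffle,
                                 seed = seed + 100 * s, ...)
    all_series <- c(all_series, hm$series)
    depths <- c(depths, se$spikes$neurons$depth_um)
    rts[s] <- mean(hm$rts, na.rm = TRUE)
    on <- session_onset(hm$tensor, hm$labels, min_neurons = min_neurons,
                        n_shuffle = n_shuffle, consec = consec,
                        seed = seed + s)
    onsets[s] <- if (is.null(on)) NA_real_ else on$onset_s
  }
  list(onsets_s = onsets, mean_rt_s = rts, series = all_series,
       depths = depths)
}
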