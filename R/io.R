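## Session bundle on disk and pipeline orchestration.  A session directory
## holds manifest.json, trials.csv, spikes.csv, neurons.csv, licks.csv and
## (optionally) pupil.csv; times in seconds, 1-based trial indices, UTF-8
## CSV with header row and '.' decimal.

#' Write a session bundle to a directory
#'
#' @param session A `session` object (see [simulate_session()]).
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(path, f),
                                        row.names = FALSE)
  w(session$trials, "trials.csv")
  st <- session$spikes$spike_times
  spikes_df <- data.frame(
    neuron_id = rep(names(st), vapply(st, length, 1L)),
    time_s = unlist(st, use.names = FALSE))
  w(spikes_df, "spikes.csv")
  w(session$spikes$neurons, "neurons.csv")
  w(session$licks, "licks.csv")
  if (!is.null(session$pupil)) w(session$pupil, "pupil.csv")
  jsonlite::write_json(session$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' Validates the schema strictly: required files and columns must be
#' present, every `neuron_id` in spikes.csv must exist in neurons.csv, and
#' spike times must fall inside the session span.  pupil.csv is optional;
#' without it the session loads with `pupil = NULL`.
#'
#' @param path Session directory.
#' @return A `session` object (without ground truth).
#' @export
read_session <- function(path) {
  need <- c("manifest.json", "trials.csv", "spikes.csv", "neurons.csv",
            "licks.csv")
  missing_f <- need[!file.exists(file.path(path, need))]
  if (length(missing_f)) {
    stop("session bundle invalid, missing: ", paste(missing_f, collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  r <- function(f, cols) {
    df <- utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
    bad <- setdiff(cols, names(df))
    if (length(bad)) stop(f, " lacks required columns: ",
                          paste(bad, collapse = ", "))
    df
  }
  trials <- r("trials.csv", c("trial_index", "trial_type", "saliency",
                              "change_time", "choice", "outcome",
                              "reaction_time", "photostim"))
  class(trials) <- c("trial_table", "data.frame")
  spikes_df <- r("spikes.csv", c("neuron_id", "time_s"))
  neurons <- r("neurons.csv", c("neuron_id", "depth_um", "p2t_ms"))
  unknown <- setdiff(unique(spikes_df$neuron_id), neurons$neuron_id)
  if (length(unknown)) {
    bad_rows <- which(spikes_df$neuron_id %in% unknown)
    stop("spikes.csv references unknown neuron ids (",
         paste(utils::head(unknown, 5), collapse = ", "),
         ") at rows ", paste(utils::head(bad_rows, 5), collapse = ", "))
  }
  span_end <- max(trials$change_time) + 10
  if (any(spikes_df$time_s < 0 | spikes_df$time_s > span_end + 60)) {
    stop("spikes.csv contains times outside the session span")
  }
  st <- split(spikes_df$time_s, factor(spikes_df$neuron_id,
                                       levels = neurons$neuron_id))
  st <- lapply(st, sort)
  licks <- r("licks.csv", c("time_s"))
  pupil <- if (file.exists(file.path(path, "pupil.csv"))) {
    r("pupil.csv", c("time_s", "z"))
  } else NULL
  structure(list(trials = trials,
                 spikes = as_spike_set(st, neurons),
                 licks = licks, pupil = pupil, ground_truth = NULL,
                 manifest = manifest),
            class = "session")
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Simulates `n_sessions` sessions under `cfg`, then runs the behavioural
#' fit, rate extraction, encoding model (first neuron passing the rate
#' filter), hit/miss ROC analysis and noise correlations, writing a
#' provenance-stamped summary JSON plus per-stage outputs under `out_dir`.
#' Rerunning with the same config yields a byte-identical summary.
#'
#' @param config List with elements `cfg` (a [cohort_config()]),
#'   `n_sessions`, `n_trials`, `out_dir`, and optional `stages` (subset of
#'   `c("simulate", "fit-behavior", "rates", "glm", "roc", "noisecorr")`).
#' @return Path of the summary JSON, invisibly.
#' @export
run_pipeline <- function(config) {
  stages_all <- c("simulate", "fit-behavior", "rates", "glm", "roc",
                  "noisecorr")
  stages <- if (is.null(config$stages)) stages_all else config$stages
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop("unknown stage name: ", paste(bad, collapse = ", "))
  cfg <- config$cfg %||% cohort_config("MST")
  n_sessions <- config$n_sessions %||% 2L
  n_trials <- config$n_trials %||% 150L
  out_dir <- config$out_dir %||% tempfile("latewave_report_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  summary <- list(
    package_version = as.character(utils::packageVersion("latewave")),
    config = list(cohort = cfg$cohort, seed = cfg$seed,
                  n_sessions = n_sessions, n_trials = n_trials),
    stages = stages)

  sessions <- NULL
  if ("simulate" %in% stages) {
    sessions <- lapply(seq_len(n_sessions), function(s) {
      cfg$seed <- cfg$seed + s - 1L
      simulate_session(cfg, n_trials = n_trials)
    })
    for (s in seq_along(sessions)) {
      write_session(sessions[[s]], file.path(out_dir, sprintf("session%02d", s)))
    }
    summary$simulate <- list(n_sessions = length(sessions))
  }
  if (is.null(sessions)) stop("pipeline stages after 'simulate' need sessions")

  if ("fit-behavior" %in% stages) {
    fits <- lapply(sessions, function(se) {
      fit <- fit_madc(count_responses(se$trials))
      lapply(fit$by_saliency, function(f)
        f[c("d_visual", "d_auditory", "c_visual", "c_auditory")])
    })
    summary$behavior <- fits
  }

  tensors <- NULL
  if (any(c("rates", "glm", "roc", "noisecorr") %in% stages)) {
    tensors <- lapply(sessions, function(se) {
      compute_rates(se$spikes, se$trials$change_time, window = c(-1, 2))
    })
    summary$rates <- list(
      dims = lapply(tensors, function(t) dim(t$values)))
  }

  if ("glm" %in% stages) {
    se <- sessions[[1]]
    span <- c(0, max(se$trials$change_time) + 3)
    rates_hz <- session_rates(se$spikes, span)
    neuron <- which(rates_hz > 0.5)[1]
    des <- build_design(se$trials, se$licks, se$pupil)
    Y <- bin_spike_counts(se$spikes$spike_times[[neuron]], se$trials,
                          des$window, des$bin_width)
    fit <- fit_poisson_elasticnet(des, Y, seed = cfg$seed)
    summary$glm <- list(
      n_predictors = ncol(des$X),
      ev_overall = explained_variance(Y, fit$Yhat_cv))
  }

  if ("roc" %in% stages) {
    onsets <- vapply(seq_along(sessions), function(s) {
      se <- sessions[[s]]
      vis <- which(se$trials$trial_type == "visual" &
                     se$trials$outcome %in% c("hit", "miss"))
      on <- session_onset(
        subset_tensor(tensors[[s]], trials = vis),
        se$trials$outcome[vis] == "hit", n_shuffle = 200,
        seed = cfg$seed)
      if (is.null(on)) NA_real_ else on$onset_s
    }, numeric(1))
    summary$roc <- list(session_onsets_s = onsets)
  }

  if ("noisecorr" %in% stages) {
    se <- sessions[[1]]
    nc_tensor <- compute_rates(se$spikes, se$trials$change_time,
                               window = c(-1, 1.5), kernel_sd = 0.1)
    vis <- which(se$trials$trial_type == "visual")
    res <- residual_rates(subset_tensor(nc_tensor, trials = vis),
                          rep("visual", length(vis)))
    nc <- noise_correlations(res)
    summary$noisecorr <- list(baseline = nc$baseline_mean,
                              delta = nc$delta_nc)
  }

  out <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = 8,
                       pretty = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a rate tensor by neurons and/or trials
#'
#' @param tensor A `rate_tensor`.
#' @param neurons,trials Index vectors (default: keep all).
#' @return The subset `rate_tensor`.
#' @export
subset_tensor <- function(tensor, neurons = NULL, trials = NULL) {
  stopifnot(inherits(tensor, "rate_tensor"))
  v <- tensor$values
  if (!is.null(neurons)) v <- v[neurons, , , drop = FALSE]
  if (!is.null(trials)) v <- v[, trials, , drop = FALSE]
  tensor$values <- v
  tensor
}
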