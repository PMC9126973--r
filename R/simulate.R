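## Synthetic-session generator: choice behaviour from the bivariate-evidence
## detection model, inhomogeneous-Poisson spiking with an early sensory
## transient and a late report-locked component, laminar and cell-type
## structure, a shared slow multiplicative gain process producing noise
## correlations that quench before the first lick, lick bouts, a pupil trace
## and optogenetic-silencing trials.  Ground truth is retained for recovery
## tests.

#' Cohort configuration for synthetic sessions
#'
#' Defaults are the study conditions of the audiovisual change-detection
#' task: threshold/maximal d-primes per modality, criteria, lognormal
#' reaction times (multisensory-trained animals slower than unisensory),
#' a late component whose onset precedes the first lick by 280 ms, laminar
#' gain profiles (early transient strongest in granular/supragranular, late
#' component in supragranular/infragranular), and a shared-gain noise
#' process calibrated to a baseline pairwise correlation of 0.063 that
#' quenches 200 ms before each first lick.
#'
#' @param cohort `"NE"`, `"UST"` or `"MST"`.  NE has zero contingent
#'   d-prime (choices independent of stimuli) and no late component.
#' @param dprime_visual,dprime_auditory Named vectors `c(thr=, max=)`.
#' @param criterion_visual,criterion_auditory Decision criteria.
#' @param rt_lognormal_mu,rt_lognormal_sigma Reaction-time lognormal
#'   parameters (log-seconds).
#' @param late_onset_lag Onset of the late component relative to the first
#'   lick, seconds (negative: precedes the lick).
#' @param early_gain_by_layer,late_gain_by_layer Named `c(SG=, G=, IG=)`
#'   peak amplitudes of the early/late kernels in baseline-SD (z) units.
#' @param late_participation Fraction of neurons carrying the late
#'   component (hit coders); the rest have zero late amplitude.
#' @param late_amp_jitter_sd Lognormal SD of single-trial, per-neuron late
#'   amplitude variability (mean-1 multiplier).
#' @param late_onset_jitter_sd SD (s) of per-neuron, per-trial jitter of
#'   the late-component onset around `reaction_time + late_onset_lag`.
#' @param nc_baseline_target Target baseline pairwise noise correlation; the
#'   gain-process SD is solved from it analytically.
#' @param nc_drop_lead Seconds before the first lick at which the shared
#'   gain quenches.
#' @param n_neurons Neurons per session.
#' @param baseline_meanlog,baseline_sdlog Lognormal across-neuron baseline
#'   firing rates (log-Hz).
#' @param seed Integer seed making the session reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(cohort = c("MST", "UST", "NE"),
                          dprime_visual = NULL, dprime_auditory = NULL,
                          criterion_visual = NULL, criterion_auditory = NULL,
                          rt_lognormal_mu = NULL, rt_lognormal_sigma = 0.15,
                          late_onset_lag = -0.28,
                          early_gain_by_layer = c(SG = 2.5, G = 3, IG = 1.2),
                          late_gain_by_layer = NULL,
                          late_participation = 0.5,
                          late_amp_jitter_sd = 0.8,
                          late_onset_jitter_sd = 0.04,
                          nc_baseline_target = 0.063, nc_drop_lead = 0.2,
                          n_neurons = 32,
                          baseline_meanlog = log(5), baseline_sdlog = 0.5,
                          seed = 1) {
  cohort <- match.arg(cohort)
  if (is.null(dprime_visual)) {
    dprime_visual <- switch(cohort,
      NE = c(thr = 0, max = 0), c(thr = 0.8, max = 1.5))
  }
  if (is.null(dprime_auditory)) {
    dprime_auditory <- switch(cohort,
      MST = c(thr = 1.2, max = 2.5), c(thr = 0, max = 0))
  }
  if (is.null(criterion_visual)) {
    criterion_visual <- if (cohort == "NE") 1.5 else 0.5
  }
  if (is.null(criterion_auditory)) {
    criterion_auditory <- if (cohort == "MST") 0.5 else 1.5
  }
  if (is.null(rt_lognormal_mu)) {
    # medians chosen so that median RT + late_onset_lag reproduces the
    # reported cohort onsets (~160 ms unisensory, ~290 ms multisensory)
    rt_lognormal_mu <- switch(cohort, UST = log(0.44), MST = log(0.57),
                              NE = log(0.45))
  }
  if (is.null(late_gain_by_layer)) {
    late_gain_by_layer <- if (cohort == "NE") c(SG = 0, G = 0, IG = 0)
      else c(SG = 2.5, G = 1.2, IG = 3)
  }
  stopifnot(late_onset_lag < 0)
  structure(list(
    cohort = cohort, dprime_visual = dprime_visual,
    dprime_auditory = dprime_auditory, criterion_visual = criterion_visual,
    criterion_auditory = criterion_auditory,
    rt_lognormal_mu = rt_lognormal_mu,
    rt_lognormal_sigma = rt_lognormal_sigma,
    late_onset_lag = late_onset_lag,
    early_gain_by_layer = early_gain_by_layer,
    late_gain_by_layer = late_gain_by_layer,
    late_participation = late_participation,
    late_amp_jitter_sd = late_amp_jitter_sd,
    late_onset_jitter_sd = late_onset_jitter_sd,
    nc_baseline_target = nc_baseline_target, nc_drop_lead = nc_drop_lead,
    n_neurons = n_neurons, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Simulate choices, reaction times and outcomes
#'
#' Per trial, bivariate standard-normal evidence is drawn with the
#' stimulated modality's d-prime added on its axis; the animal responds to
#' modality m iff `Psi_m >= c_m` and `Psi_m - c_m >= Psi_other - c_other`
#' (the decision rule of [madc_rates()], used generatively).  Reaction times
#' of responses are lognormal, truncated to the response window
#' (0.1, 1.5] s.  Visual responses are left licks, auditory ones right.
#'
#' @param trials `trial_table` with stimuli only.
#' @param cfg A [cohort_config()].
#' @return The `trial_table` with `choice`, `outcome`, `reaction_time` and
#'   `reward_time` filled.
#' @export
simulate_behavior <- function(trials, cfg) {
  n <- nrow(trials)
  mu_v <- mu_a <- numeric(n)
  vis <- trials$trial_type %in% c("visual", "multimodal")
  aud <- trials$trial_type %in% c("auditory", "multimodal")
  mu_v[vis] <- cfg$dprime_visual[trials$saliency[vis]]
  mu_a[aud] <- cfg$dprime_auditory[trials$saliency[aud]]
  mu_v[is.na(mu_v)] <- cfg$dprime_visual[["max"]]  # multimodal carry max
  mu_a[is.na(mu_a)] <- cfg$dprime_auditory[["max"]]
  psi_v <- stats::rnorm(n, mu_v)
  psi_a <- stats::rnorm(n, mu_a)
  ev_v <- psi_v - cfg$criterion_visual
  ev_a <- psi_a - cfg$criterion_auditory
  resp_v <- psi_v >= cfg$criterion_visual & ev_v >= ev_a
  resp_a <- psi_a >= cfg$criterion_auditory & ev_a > ev_v
  choice <- ifelse(resp_v, "left", ifelse(resp_a, "right", "none"))

  rt <- rep(NA_real_, n)
  responded <- choice != "none"
  if (any(responded)) {
    draw <- function(k) {
      out <- numeric(k)
      for (i in seq_len(k)) {
        repeat {
          x <- stats::rlnorm(1, cfg$rt_lognormal_mu, cfg$rt_lognormal_sigma)
          if (x > 0.1 && x <= 1.5) break
        }
        out[i] <- x
      }
      out
    }
    rt[responded] <- draw(sum(responded))
  }

  outcome <- character(n)
  for (i in seq_len(n)) {
    outcome[i] <- switch(trials$trial_type[i],
      visual = if (choice[i] == "left") "hit"
               else if (choice[i] == "right") "error" else "miss",
      auditory = if (choice[i] == "right") "hit"
                 else if (choice[i] == "left") "error" else "miss",
      catch = if (choice[i] == "none") "CR" else "FA",
      multimodal = if (choice[i] == "none") "miss" else "hit")
  }
  trials$choice <- choice
  trials$outcome <- outcome
  trials$reaction_time <- rt
  trials$reward_time <- ifelse(outcome == "hit",
                               trials$change_time + rt, NA_real_)
  trials
}

## late-component time course: half-Gaussian rise (sigma 100 ms) starting at
## t0, sustained until the choice, half-Gaussian decay afterwards
.late_shape <- function(t, t0, t_choice, rise_sd = 0.1, fall_sd = 0.2) {
  peak <- t0 + 2 * rise_sd
  out <- numeric(length(t))
  rising <- t >= t0 & t < peak
  out[rising] <- exp(-0.5 * ((t[rising] - peak) / rise_sd)^2)
  sustained <- t >= peak & t <= t_choice + 0.3
  out[sustained] <- 1
  falling <- t > t_choice + 0.3
  out[falling] <- exp(-0.5 * ((t[falling] - (t_choice + 0.3)) / fall_sd)^2)
  out
}

## early sensory transient: alpha-like bump peaking ~60 ms, support 0-200 ms
.early_shape <- function(t, peak_t = 0.06) {
  out <- numeric(length(t))
  on <- t >= 0 & t <= 0.2
  x <- t[on] / peak_t
  out[on] <- x * exp(1 - x)
  out
}

## analytic mean pairwise correlation of smoothed counts under a shared
## multiplicative OU gain; used to solve the gain SD from the NC target
.solve_gain_sd <- function(target, baselines, tau = 1, kernel_sd = 0.1,
                           bin_width = 0.01) {
  w <- half_gaussian_kernel(kernel_sd, bin_width)
  S2 <- sum(w^2)
  lagmat <- abs(outer(seq_along(w), seq_along(w), "-")) * bin_width
  K <- sum(outer(w, w) * exp(-lagmat / tau))
  lam <- baselines
  mean_r <- function(sg2) {
    v <- lam * bin_width * S2 + lam^2 * bin_width^2 * sg2 * K
    cv <- outer(lam, lam) * bin_width^2 * sg2 * K
    r <- cv / sqrt(outer(v, v))
    mean(r[upper.tri(r)])
  }
  f <- function(sg) mean_r(sg^2) - target
  if (f(2) < 0) return(2)  # cap: extremely low rates cannot reach the target
  stats::uniroot(f, c(1e-4, 2))$root
}

## Ornstein-Uhlenbeck deviations, mean 0, sd sigma, time constant tau,
## simulated exactly on a regular grid
.ou_path <- function(n, dt, sigma, tau) {
  a <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- a * x[i - 1] + eps[i - 1]
  x
}

#' Simulate spiking, licks and pupil for a behaviourally-complete session
#'
#' Inhomogeneous-Poisson spike trains on 10-ms bins within per-trial windows
#' (default -1 to 2.5 s around each change), plus homogeneous baseline
#' spiking between trials.  Per neuron the rate is
#' `gain(t) * (baseline + early(t) + late(t))`: an orientation-tuned early
#' transient on visual-change trials (0-200 ms, scaled by saliency and the
#' laminar early gain), a late component on hit trials only, starting at
#' `reaction_time + late_onset_lag` (scaled by the laminar late gain), and a
#' shared slow multiplicative gain (OU, time constant 1 s) whose SD is
#' solved from the target baseline noise correlation and which quenches from
#' `nc_drop_lead` s before each first lick.  Kernel amplitudes are expressed
#' in units of the neuron's analytic baseline rate SD (50-ms smoothing), so
#' a gain of 3 yields a ~3 z trial-averaged response.  Photostimulation
#' trials (`photostim` `"early"`/`"late"`) reduce the rate to 5% of baseline
#' from 0 / 200 ms after the change until the choice.  Lick bouts at ~7 Hz
#' follow each response; the pupil trace is a low-pass filtered copy of the
#' gain process plus noise.
#'
#' @param trials `trial_table` with outcomes and reaction times filled.
#' @param cfg A [cohort_config()].
#' @param window Per-trial simulation window (s relative to change).
#' @return List with `spikes` (a `spike_set`), `licks` (data frame `time_s`,
#'   `side`), `pupil` (data frame `time_s`, `z`), and `ground_truth`.
#' @export
simulate_spikes <- function(trials, cfg, window = c(-1, 2.5)) {
  n_tr <- nrow(trials)
  n_neu <- cfg$n_neurons
  dt <- 0.01
  n_bins <- round(diff(window) / dt)
  tgrid <- window[1] + dt * (seq_len(n_bins) - 0.5)

  # neuron properties
  depth <- stats::runif(n_neu, 100, 1000)
  layer <- assign_layer(depth)
  p2t <- ifelse(stats::runif(n_neu) < 0.4,
                stats::rnorm(n_neu, 0.30, 0.04),
                stats::rnorm(n_neu, 0.75, 0.07))
  p2t <- pmin(pmax(p2t, 0.05), 1)
  baseline <- stats::rlnorm(n_neu, cfg$baseline_meanlog, cfg$baseline_sdlog)
  # analytic baseline SD of 50-ms-smoothed rates (Hz), the z-unit reference
  w50 <- half_gaussian_kernel(0.05, dt)
  sd0 <- sqrt(baseline * sum(w50^2) / dt)
  pref <- sample(c("AB", "CD"), n_neu, replace = TRUE)
  tuning_depth <- 0.6
  amp_early <- cfg$early_gain_by_layer[layer] * sd0 *
    stats::rlnorm(n_neu, 0, 0.25)
  participates <- stats::runif(n_neu) < cfg$late_participation
  amp_late <- ifelse(participates, 1, 0) *
    cfg$late_gain_by_layer[layer] * sd0 * stats::rlnorm(n_neu, 0, 0.25)

  sigma_g <- .solve_gain_sd(cfg$nc_baseline_target, baseline)

  # per-trial structures
  sal_scale <- c(thr = 0.6, max = 1, none = 0)
  vset <- make_stimulus_set("visual", 100, 7)
  ab <- c(vset$A, vset$B)

  gain <- matrix(1, n_tr, n_bins)
  spike_times <- vector("list", n_neu)
  for (i in seq_len(n_neu)) spike_times[[i]] <- vector("list", n_tr + 1L)

  late_onsets <- rep(NA_real_, n_tr)
  for (j in seq_len(n_tr)) {
    g <- 1 + .ou_path(n_bins, dt, sigma_g, 1)
    rt_j <- trials$reaction_time[j]
    if (!is.na(rt_j)) {
      quench <- tgrid >= rt_j - cfg$nc_drop_lead
      g[quench] <- 1
    }
    g <- pmax(g, 0.05)
    gain[j, ] <- g

    is_vis <- trials$trial_type[j] %in% c("visual", "multimodal")
    sal <- sal_scale[[trials$saliency[j]]]
    early_t <- .early_shape(tgrid)
    is_hit <- identical(trials$outcome[j], "hit")
    has_late <- is_hit && !is.na(rt_j) && any(amp_late > 0)
    if (has_late) late_onsets[j] <- rt_j + cfg$late_onset_lag
    post_ab <- if (is_vis && !is.na(trials$post_feature[j])) {
      min(abs(orientation_diff(ab, trials$post_feature[j]))) < 1e-6
    } else NA

    ps <- trials$photostim[j]
    ps_mask <- rep(1, n_bins)
    if (ps %in% c("early", "late")) {
      t_on <- if (ps == "early") 0 else 0.2
      t_off <- if (!is.na(rt_j)) rt_j else 1.5
      ps_mask[tgrid >= t_on & tgrid <= t_off] <- 0.05
    }

    for (i in seq_len(n_neu)) {
      tune <- if (isTRUE(post_ab)) {
        if (pref[i] == "AB") 1 else 1 - tuning_depth
      } else if (isFALSE(post_ab)) {
        if (pref[i] == "CD") 1 else 1 - tuning_depth
      } else 0
      lam <- baseline[i] +
        (if (is_vis) amp_early[i] * sal * tune * early_t else 0)
      if (has_late && amp_late[i] > 0) {
        # heterogeneous late component: per-neuron-trial amplitude and
        # onset jitter keep pairwise residual correlations realistic
        jit <- stats::rlnorm(1, -cfg$late_amp_jitter_sd^2 / 2,
                             cfg$late_amp_jitter_sd)
        t0_i <- late_onsets[j] + stats::rnorm(1, 0, cfg$late_onset_jitter_sd)
        lam <- lam + amp_late[i] * jit * .late_shape(tgrid, t0_i, rt_j)
      }
      lam <- lam * g * ps_mask
      cnt <- stats::rpois(n_bins, pmax(lam, 0) * dt)
      nz <- which(cnt > 0)
      if (length(nz)) {
        tt <- rep(tgrid[nz] - dt / 2, cnt[nz]) +
          stats::runif(sum(cnt[nz]), 0, dt)
        spike_times[[i]][[j]] <- trials$change_time[j] + tt
      }
    }
  }

  # homogeneous baseline spiking in the gaps between trial windows
  span_end <- max(trials$change_time) + window[2] + 5
  for (i in seq_len(n_neu)) {
    t_sp <- cumsum(stats::rexp(ceiling(span_end * baseline[i] * 1.3) + 20,
                               baseline[i]))
    t_sp <- t_sp[t_sp < span_end]
    in_window <- rep(FALSE, length(t_sp))
    for (j in seq_len(n_tr)) {
      in_window <- in_window |
        (t_sp >= trials$change_time[j] + window[1] &
           t_sp < trials$change_time[j] + window[2])
    }
    spike_times[[i]][[n_tr + 1L]] <- t_sp[!in_window]
    spike_times[[i]] <- sort(unlist(spike_times[[i]]))
  }

  # licks: response bout at ~7 Hz for 1.5 s, plus sparse spontaneous licks
  lick_t <- numeric(0); lick_side <- character(0)
  for (j in seq_len(n_tr)) {
    rt_j <- trials$reaction_time[j]
    if (is.na(rt_j)) next
    t0 <- trials$change_time[j] + rt_j
    iv <- stats::rgamma(12, shape = 8, rate = 8 * 7)
    bout <- t0 + c(0, cumsum(iv))
    bout <- bout[bout <= t0 + 1.5]
    lick_t <- c(lick_t, bout)
    lick_side <- c(lick_side, rep(trials$choice[j], length(bout)))
  }
  n_spont <- stats::rpois(1, 0.1 * span_end)
  if (n_spont > 0) {
    lick_t <- c(lick_t, stats::runif(n_spont, 0, span_end))
    lick_side <- c(lick_side, sample(c("left", "right"), n_spont,
                                     replace = TRUE))
  }
  ord <- order(lick_t)
  licks <- data.frame(time_s = lick_t[ord], side = lick_side[ord],
                      stringsAsFactors = FALSE)

  # pupil: low-pass filtered gain deviations placed at trial windows + noise
  pup_t <- seq(0, span_end, by = 0.04)
  pup <- numeric(length(pup_t))
  for (j in seq_len(n_tr)) {
    idx <- which(pup_t >= trials$change_time[j] + window[1] &
                   pup_t < trials$change_time[j] + window[2])
    if (!length(idx)) next
    rel <- pup_t[idx] - trials$change_time[j]
    pup[idx] <- stats::approx(tgrid, gain[j, ] - 1, rel, rule = 2)$y
  }
  k <- half_gaussian_kernel(0.5, 0.04)
  pup <- as.numeric(stats::filter(pup, k, sides = 1))
  pup[is.na(pup)] <- 0
  pup <- pup + stats::rnorm(length(pup), 0, 0.05)
  pup <- (pup - mean(pup)) / stats::sd(pup)

  neurons <- data.frame(
    neuron_id = sprintf("n%03d", seq_len(n_neu)),
    depth_um = depth, p2t_ms = p2t, session_id = "synthetic",
    stringsAsFactors = FALSE)
  gt <- list(baseline_hz = baseline, depth_um = depth, layer = layer,
             p2t_ms = p2t, pref_orientation = pref,
             tuning_depth = tuning_depth, late_participant = participates,
             amp_early_hz = unname(amp_early), amp_late_hz = unname(amp_late),
             sd0_hz = sd0, sigma_gain = sigma_g,
             late_onsets = late_onsets, gain = gain, window = window,
             config = cfg)
  list(spikes = as_spike_set(spike_times, neurons),
       licks = licks,
       pupil = data.frame(time_s = pup_t, z = pup),
       ground_truth = gt)
}

## behavioural consequences of silencing: early silencing abolishes most
## visual detections; late silencing converts a visual hit to a miss iff the
## trial's late component would have started at or after the silencing onset
## (200 ms), so its behavioural effect grows with reaction time
.apply_photostim_behavior <- function(trials, cfg, p_early_block = 0.85) {
  vis <- which(trials$trial_type == "visual" & trials$outcome == "hit")
  to_miss <- integer(0)
  for (j in vis) {
    ps <- trials$photostim[j]
    if (ps == "early") {
      if (stats::runif(1) < p_early_block) to_miss <- c(to_miss, j)
    } else if (ps == "late") {
      t0 <- trials$reaction_time[j] + cfg$late_onset_lag
      if (!is.na(t0) && t0 >= 0.2) to_miss <- c(to_miss, j)
    }
  }
  if (length(to_miss)) {
    trials$choice[to_miss] <- "none"
    trials$outcome[to_miss] <- "miss"
    trials$reaction_time[to_miss] <- NA_real_
    trials$reward_time[to_miss] <- NA_real_
  }
  trials
}

#' Simulate a complete synthetic session
#'
#' Chains [sample_trial_sequence()], photostimulation assignment,
#' [simulate_behavior()] and [simulate_spikes()] under the configuration's
#' seed: the whole session (trials, spikes, licks, pupil) is reproducible.
#'
#' @param cfg A [cohort_config()].
#' @param n_trials Number of trials.
#' @param photostim_frac Fraction of trials receiving photostimulation
#'   (split evenly between early and late); default 0 (no silencing).
#' @param window Per-trial spiking window.
#' @return A `session` object: list with `trials`, `spikes`, `licks`,
#'   `pupil`, `ground_truth`, `manifest`.
#' @export
simulate_session <- function(cfg, n_trials = 300, photostim_frac = 0,
                             window = c(-1, 2.5)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  trials <- sample_trial_sequence(n_trials)
  if (photostim_frac > 0) {
    n_ps <- round(n_trials * photostim_frac)
    idx <- sample(n_trials, n_ps)
    half <- seq_len(floor(n_ps / 2))
    trials$photostim[idx[half]] <- "early"
    trials$photostim[idx[-half]] <- "late"
  }
  trials <- simulate_behavior(trials, cfg)
  trials <- .apply_photostim_behavior(trials, cfg)
  sp <- simulate_spikes(trials, cfg, window)
  structure(list(trials = trials, spikes = sp$spikes, licks = sp$licks,
                 pupil = sp$pupil, ground_truth = sp$ground_truth,
                 manifest = list(session_id = paste0(cfg$cohort, "-",
                                                     cfg$seed),
                                 cohort = cfg$cohort, seed = cfg$seed,
                                 n_trials = n_trials,
                                 photostim_frac = photostim_frac)),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("session %s: %d trials, %d neurons, %d licks\n",
              x$manifest$session_id, nrow(x$trials),
              nrow(x$spikes$neurons), nrow(x$licks)))
  invisible(x)
}

#' Simulate paired unisensory- and multisensory-trained cohorts
#'
#' UST-like sessions have faster reaction times and hence earlier late
#' components; MST-like sessions slower.  Used for onset-versus-reaction-time
#' analyses across sessions.
#'
#' @param cfg_ust,cfg_mst Configurations; `cfg_mst$rt_lognormal_mu` must
#'   exceed `cfg_ust$rt_lognormal_mu`.
#' @param n_sessions Sessions per cohort.
#' @param n_trials Trials per session.
#' @param seed Base seed; session s of cohort k uses `seed + 1000*k + s`.
#' @param ... Passed to [simulate_session()].
#' @return List with elements `ust` and `mst`, each a list of sessions.
#' @export
simulate_cohort_pair <- function(cfg_ust = cohort_config("UST"),
                                 cfg_mst = cohort_config("MST"),
                                 n_sessions = 10, n_trials = 250, seed = 1,
                                 ...) {
  if (cfg_mst$rt_lognormal_mu <= cfg_ust$rt_lognormal_mu) {
    stop("the MST configuration must have slower reaction times than UST")
  }
  gen <- function(cfg, k) {
    lapply(seq_len(n_sessions), function(s) {
      cfg$seed <- as.integer(seed + 1000 * k + s)
      simulate_session(cfg, n_trials = n_trials, ...)
    })
  }
  list(ust = gen(cfg_ust, 1L), mst = gen(cfg_mst, 2L))
}
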