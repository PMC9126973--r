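# Shared synthetic sessions, generated once per test run and memoised.

.session_cache <- new.env(parent = emptyenv())

# small multisensory-trained session: behaviour + spikes for most unit tests
demo_session <- function() {
  if (is.null(.session_cache$demo)) {
    .session_cache$demo <- simulate_session(
      cohort_config("MST", seed = 31, n_neurons = 8), n_trials = 150)
  }
  .session_cache$demo
}

# larger session for noise-correlation work (50 neurons, 350 trials)
nc_session <- function() {
  if (is.null(.session_cache$nc)) {
    .session_cache$nc <- simulate_session(
      cohort_config("MST", seed = 21, n_neurons = 50), n_trials = 350)
  }
  .session_cache$nc
}

# response counts drawn by applying the bivariate decision rule directly
# (independent of the quadrature in madc_rates)
draw_madc_counts <- function(d_v, d_a, c_v, c_a,
                             n_vis = 240, n_aud = 240, n_catch = 120) {
  sim_row <- function(mu_v, mu_a, n) {
    pv <- stats::rnorm(n, mu_v); pa <- stats::rnorm(n, mu_a)
    rv <- pv >= c_v & (pv - c_v) >= (pa - c_a)
    ra <- pa >= c_a & (pa - c_a) > (pv - c_v)
    c(visual = sum(rv), auditory = sum(ra), nogo = sum(!rv & !ra))
  }
  k <- rbind(visual = sim_row(d_v, 0, n_vis),
             auditory = sim_row(0, d_a, n_aud),
             catch = sim_row(0, 0, n_catch))
  data.frame(
    trial_type = rep(rownames(k), each = 3),
    saliency = rep(c("thr", "thr", "none"), each = 3),
    response = rep(colnames(k), times = 3),
    n = as.vector(t(k)))
}
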