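## shared fixtures: all built in code at test time.

## scale trial-level RT noise (sigma, tau) by a common factor
scale_rt_noise <- function(rt_base, f) {
  lapply(rt_base, function(p)
    c(mu = unname(p[["mu"]]), sigma = unname(p[["sigma"]]) * f,
      tau = unname(p[["tau"]]) * f))
}

## study conditions for the end-to-end recovery suite: generating loadings
## 0.6, factor correlation 0.67, and low trial noise, so that observed
## scores carry mostly true-score variance (per-task true-score variance
## fraction >= ~0.9 by the power computation in the methods vignette):
## * RT noise scaled to 0.2x (0.4x for the stop-signal task, whose SSD
##   grid needs a go-RT distribution wide enough to keep two SSDs away
##   from degenerate response probabilities),
## * no fast guesses, weak speed-accuracy coupling,
## * antisaccade effect mean .22 / SD .13 (clear of the probability floor;
##   its 90 Bernoulli trials are the irreducible noise source),
## * between-subject SSRT SD 60 ms against ~10 ms estimation noise,
## * speed-trait SD 30 ms so baselines stay clear of the fixed trimming
##   bounds (bound clamping would otherwise convert speed variance into
##   difference-score variance).
low_noise_config <- function(n_subjects, seed) {
  rt_base <- scale_rt_noise(default_rt_base(), 0.2)
  rt_base$stop_signal <- scale_rt_noise(default_rt_base(), 0.4)$stop_signal
  generator_config(
    n_subjects = n_subjects,
    rho = 0.67,
    loadings = rep(0.6, 6),
    effect_means = c(antisaccade = 0.22, stroop = 48, stop_signal = 322,
                     flanker = 47, shape_matching = 160, word_naming = 25),
    effect_sds = c(antisaccade = 0.13, stroop = 40, stop_signal = 40,
                   flanker = 30, shape_matching = 95, word_naming = 20),
    rt_base = rt_base,
    speed_trait_sd = 30,
    speed_accuracy_slope = 0.1,
    guess_rate = 0,
    ssrt_sd = 60,
    seed = seed
  )
}

## hand-built trial table
make_trials <- function(subject_id, task, condition, rt_ms, correct,
                        ssd_ms = NA_real_, responded = NA) {
  n <- max(length(condition), length(rt_ms), length(correct))
  data.frame(
    subject_id = rep_len(subject_id, n),
    task = rep_len(task, n),
    condition = rep_len(condition, n),
    trial_index = seq_len(n),
    rt_ms = rep_len(rt_ms, n),
    correct = rep_len(correct, n),
    ssd_ms = rep_len(ssd_ms, n),
    responded = rep_len(responded, n)
  )
}

## random admissible two-related-factor parameter set
random_admissible_params <- function() {
  list(lambda = runif(6, 0.3, 0.9),
       theta = runif(6, 0.3, 1.2),
       phi = runif(1, -0.8, 0.8))
}

## random well-conditioned PD covariance matrix
random_pd_cov <- function(p = 6, n = 40) {
  A <- matrix(rnorm(n * p), n, p)
  crossprod(A) / n + diag(runif(p, 0.2, 0.8))
}
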