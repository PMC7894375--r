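## task synthesis: trial-level simulation of the six-task battery from a
## known two-factor latent model.

#' The six inhibitory control tasks
#'
#' Canonical task names, in battery order. The first three (antisaccade,
#' Stroop, stop-signal) indicate prepotent response inhibition; the last
#' three (flanker, shape-matching, word-naming) resistance to distractor
#' interference.
#'
#' @return character vector of six task names.
#' @export
inhibition_tasks <- function() {
  c("antisaccade", "stroop", "stop_signal", "flanker",
    "shape_matching", "word_naming")
}

#' Default trial plan
#'
#' Per-task condition-by-count tables reproducing the battery's standard
#' trial numbers: antisaccade 90; Stroop 240 (80 per condition); stop-signal
#' 440 (330 go, 110 stop = 25%); flanker 160 (40 per condition);
#' shape-matching and word-naming 168 each (1/3 no-distractor).
#'
#' @return named list of data.frames with columns `condition`, `n`.
#' @export
default_trial_plan <- function() {
  list(
    antisaccade = data.frame(condition = "target", n = 90L),
    stroop = data.frame(
      condition = c("congruent", "incongruent", "neutral"),
      n = c(80L, 80L, 80L)),
    stop_signal = data.frame(
      condition = c("go", "stop"),
      n = c(330L, 110L)),
    flanker = data.frame(
      condition = c("no_noise", "noise_same", "noise_compatible",
                    "noise_incompatible"),
      n = c(40L, 40L, 40L, 40L)),
    shape_matching = data.frame(
      condition = c("no_distractor", "distractor"),
      n = c(56L, 112L)),
    word_naming = data.frame(
      condition = c("no_distractor", "distractor"),
      n = c(56L, 112L))
  )
}

## how strongly each condition expresses the subject's true interference
## effect delta (RT shift = weight * delta)
condition_effect_weights <- function() {
  list(
    antisaccade = c(target = 0),
    stroop = c(congruent = 0, incongruent = 1, neutral = 0),
    stop_signal = c(go = 0, stop = 0),
    flanker = c(no_noise = 0, noise_same = 0.35, noise_compatible = 0.15,
                noise_incompatible = 1),
    shape_matching = c(no_distractor = 0, distractor = 1),
    word_naming = c(no_distractor = 0, distractor = 1)
  )
}

#' Default per-task ex-Gaussian RT parameters
#'
#' Baseline `c(mu, sigma, tau)` in ms per task; the baseline-condition mean
#' RT is `mu + tau`. Calibrated once to realistic group means for this
#' battery.
#'
#' @return named list of numeric vectors.
#' @export
default_rt_base <- function() {
  list(
    antisaccade    = c(mu = 370, sigma = 60, tau = 90),
    stroop         = c(mu = 500, sigma = 70, tau = 105),
    stop_signal    = c(mu = 540, sigma = 70, tau = 100),
    flanker        = c(mu = 460, sigma = 60, tau = 90),
    shape_matching = c(mu = 680, sigma = 90, tau = 130),
    word_naming    = c(mu = 300, sigma = 40, tau = 65)
  )
}

#' Generator configuration for the synthetic battery
#'
#' Defines the ground-truth latent model and trial-level noise model from
#' which [generate_battery()] simulates data. Defaults are calibrated once so
#' that group-level summaries fall in the realistic range for this battery
#' (Stroop effect near 50 ms, antisaccade error rate near .16, mean SSRT near
#' 322 ms); see the methods vignette.
#'
#' The latent structure: each subject has two factor scores (RI = response
#' inhibition, DI = distractor interference) drawn from a standard bivariate
#' normal with correlation `rho`. The true interference effect for task t is
#' `delta_t = effect_mean_t + effect_sd_t * (lambda_t * F + sqrt(1 -
#' lambda_t^2) * u)`, with `F` the task's factor and `u` independent standard
#' normal. The antisaccade effect is an error proportion; the stop-signal
#' "effect" is the subject's true SSRT (mean `ssrt_mean`, SD `ssrt_sd`).
#'
#' @param n_subjects number of subjects.
#' @param rho latent factor correlation in (-1, 1).
#' @param loadings 6 task loadings in `[0, 1]`, battery order.
#' @param effect_means 6 baseline interference effects (ms; proportion for
#'   antisaccade; ignored for stop-signal, see `ssrt_mean`).
#' @param effect_sds between-subject SDs of the true effects.
#' @param rt_base named list of per-task ex-Gaussian parameters
#'   `c(mu, sigma, tau)` in ms; baseline-condition mean RT is `mu + tau`.
#' @param speed_trait_sd SD (ms) of the subject speed trait added to all of a
#'   subject's baseline RTs.
#' @param speed_accuracy_slope per-task logit slope coupling a fast speed
#'   trait to higher error probability (scalar recycled to 6); produces
#'   negative subject-level RT-error correlations.
#' @param error_intercepts per-task baseline error logits (antisaccade entry
#'   unused: its error probability is the latent effect itself).
#' @param error_effect_bumps per-task logit increments applied in
#'   interference conditions (scaled by the condition weight).
#' @param error_effect_slope logit slope linking a subject's standardized
#'   true effect to interference-condition error probability.
#' @param antisaccade_rt_scale ms of RT slowing per unit antisaccade error
#'   proportion (gives the IES scheme an RT signal as well).
#' @param guess_rate proportion of fast-guess trials (uniform 80-350 ms RT,
#'   50% accuracy), exercising the sub-200 ms trimming step.
#' @param ssrt_mean,ssrt_sd mean and between-subject SD (ms) of the true
#'   stop-signal reaction time (floored at 50 ms).
#' @param trial_plan per-task condition-by-count tables; see
#'   [default_trial_plan()].
#' @param seed integer global seed, expanded into per-(subject, task)
#'   substreams.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects,
                             rho = 0.67,
                             loadings = rep(0.6, 6),
                             effect_means = c(antisaccade = 0.16,
                                              stroop = 48,
                                              stop_signal = 322,
                                              flanker = 47,
                                              shape_matching = 160,
                                              word_naming = 25),
                             effect_sds = c(antisaccade = 0.10,
                                            stroop = 40,
                                            stop_signal = 40,
                                            flanker = 30,
                                            shape_matching = 95,
                                            word_naming = 20),
                             rt_base = default_rt_base(),
                             speed_trait_sd = 80,
                             speed_accuracy_slope = 0.5,
                             error_intercepts = c(antisaccade = NA,
                                                  stroop = -3.0,
                                                  stop_signal = -2.2,
                                                  flanker = -2.6,
                                                  shape_matching = -2.8,
                                                  word_naming = -1.3),
                             error_effect_bumps = c(antisaccade = 0,
                                                    stroop = 0.2,
                                                    stop_signal = 0,
                                                    flanker = 0.3,
                                                    shape_matching = 0.2,
                                                    word_naming = 0.6),
                             error_effect_slope = 0.4,
                             antisaccade_rt_scale = 200,
                             guess_rate = 0.02,
                             ssrt_mean = 322,
                             ssrt_sd = 40,
                             trial_plan = default_trial_plan(),
                             seed = 1L) {
  tasks <- inhibition_tasks()
  stopifnot(length(n_subjects) == 1L, n_subjects >= 1)
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
    stop("latent factor correlation matrix is not positive definite: ",
         "rho must lie strictly inside (-1, 1), got ", rho)
  loadings <- stats::setNames(rep_len(loadings, 6L), tasks)
  if (any(loadings < 0 | loadings > 1))
    stop("loadings must lie in [0, 1]")
  name6 <- function(x) stats::setNames(rep_len(unname(x), 6L), tasks)
  effect_means <- name6(effect_means)
  effect_sds <- name6(effect_sds)
  error_intercepts <- name6(error_intercepts)
  error_effect_bumps <- name6(error_effect_bumps)
  speed_accuracy_slope <- name6(speed_accuracy_slope)
  stopifnot(setequal(names(rt_base), tasks))
  for (t in tasks) {
    p <- rt_base[[t]]
    if (any(p[c("mu", "sigma", "tau")] <= 0))
      stop("RT parameters must all be positive (task ", t, ")")
  }
  stopifnot(setequal(names(trial_plan), tasks))
  for (t in tasks) {
    needed <- names(condition_effect_weights()[[t]])
    if (!all(needed %in% trial_plan[[t]]$condition))
      stop("trial_plan for ", t, " is missing condition(s): ",
           paste(setdiff(needed, trial_plan[[t]]$condition), collapse = ", "))
  }
  stopifnot(speed_trait_sd >= 0, ssrt_mean > 0, ssrt_sd >= 0,
            guess_rate >= 0, guess_rate < 1,
            all(effect_sds >= 0))
  structure(list(
    n_subjects = as.integer(n_subjects), rho = rho, loadings = loadings,
    effect_means = effect_means, effect_sds = effect_sds, rt_base = rt_base,
    speed_trait_sd = speed_trait_sd,
    speed_accuracy_slope = speed_accuracy_slope,
    error_intercepts = error_intercepts,
    error_effect_bumps = error_effect_bumps,
    error_effect_slope = error_effect_slope,
    antisaccade_rt_scale = antisaccade_rt_scale,
    guess_rate = guess_rate,
    ssrt_mean = ssrt_mean, ssrt_sd = ssrt_sd,
    trial_plan = trial_plan, seed = as.integer(seed)
  ), class = "generator_config")
}

task_factor <- function(task) {
  if (task %in% c("antisaccade", "stroop", "stop_signal"))
    "RI" else "DI"
}

#' Draw ground-truth subject traits
#'
#' Samples factor scores (RI, DI) from a standard bivariate normal with
#' correlation `rho`, a speed trait, true interference effects for each task,
#' and a true SSRT. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `subject_id`, `RI`, `DI`, `speed`,
#'   `true_ssrt` and `effect_<task>` for the six tasks.
#' @export
draw_subject_traits <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  set.seed(substream_seed(config$seed, 0L, 0L))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  RI <- z1
  DI <- config$rho * z1 + sqrt(1 - config$rho^2) * z2
  speed <- stats::rnorm(n, 0, config$speed_trait_sd)
  out <- data.frame(subject_id = seq_len(n), RI = RI, DI = DI, speed = speed)
  for (t in inhibition_tasks()) {
    lam <- config$loadings[[t]]
    f <- if (task_factor(t) == "RI") RI else DI
    u <- stats::rnorm(n)
    common <- lam * f + sqrt(1 - lam^2) * u
    if (t == "stop_signal") {
      delta <- pmax(config$ssrt_mean + config$ssrt_sd * common, 50)
      out$true_ssrt <- delta
    } else {
      delta <- config$effect_means[[t]] + config$effect_sds[[t]] * common
      if (t == "antisaccade") delta <- clamp(delta, 0.005, 0.95)
    }
    out[[paste0("effect_", t)]] <- delta
  }
  out
}

## ex-Gaussian sampler: normal(mu, sigma) + exponential(tau); floored at 1 ms
rexgauss <- function(n, mu, sigma, tau) {
  pmax(stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau), 1)
}

## core single-(subject, task) generator; returns a list of columns.
## Uses the current RNG state (generate_battery seeds per-cell substreams).
gen_task_core <- function(traits, task, config) {
  plan <- config$trial_plan[[task]]
  weights <- condition_effect_weights()[[task]]
  base <- config$rt_base[[task]]
  speed_z <- traits$speed / max(config$speed_trait_sd, 1e-9)
  delta <- traits[[paste0("effect_", task)]]
  slope <- config$speed_accuracy_slope[[task]]

  n_total <- sum(plan$n)
  cond <- rep(plan$condition, plan$n)
  w <- unname(weights[cond])

  if (task == "stop_signal") {
    is_stop <- cond == "stop"
    n_stop <- sum(is_stop)
    ## even SSD split, remainder randomly assigned
    grid <- seq(0, 500, by = 100)
    per <- n_stop %/% length(grid)
    ssd_pool <- c(rep(grid, per), sample(grid, n_stop - per * length(grid)))
    ssd <- rep(NA_real_, n_total)
    ssd[is_stop] <- sample(ssd_pool)
    ## every trial races a latent go process
    go_rt <- rexgauss(n_total, base[["mu"]] + traits$speed,
                      base[["sigma"]], base[["tau"]])
    responded <- rep(NA, n_total)
    responded[is_stop] <- go_rt[is_stop] < ssd[is_stop] + traits$true_ssrt
    rt <- go_rt
    rt[is_stop & !responded] <- NA_real_
    p_err <- stats::plogis(config$error_intercepts[[task]] - slope * speed_z)
    correct <- stats::runif(n_total) >= p_err
    ## go-trial fast guesses
    guess <- !is_stop & stats::runif(n_total) < config$guess_rate
    rt[guess] <- stats::runif(sum(guess), 80, 350)
    correct[guess] <- stats::runif(sum(guess)) < 0.5
    correct[is_stop] <- !responded[is_stop]
  } else {
    ssd <- rep(NA_real_, n_total)
    responded <- rep(NA, n_total)
    if (task == "antisaccade") {
      rt_shift <- config$antisaccade_rt_scale * delta
      mu_eff <- base[["mu"]] + traits$speed + rt_shift
      rt <- rexgauss(n_total, mu_eff, base[["sigma"]], base[["tau"]])
      p_err <- stats::plogis(stats::qlogis(delta) - slope * speed_z)
      correct <- stats::runif(n_total) >= p_err
    } else {
      mu_eff <- base[["mu"]] + traits$speed + w * delta
      rt <- rexgauss(n_total, mu_eff, base[["sigma"]], base[["tau"]])
      delta_z <- (delta - config$effect_means[[task]]) /
        max(config$effect_sds[[task]], 1e-9)
      logit <- config$error_intercepts[[task]] +
        config$error_effect_bumps[[task]] * w +
        config$error_effect_slope * w * delta_z -
        slope * speed_z
      correct <- stats::runif(n_total) >= stats::plogis(logit)
    }
    guess <- stats::runif(n_total) < config$guess_rate
    rt[guess] <- stats::runif(sum(guess), 80, 350)
    correct[guess] <- stats::runif(sum(guess)) < 0.5
  }

  ord <- sample.int(n_total)
  list(subject_id = rep(traits$subject_id, n_total),
       task = rep(task, n_total),
       condition = cond[ord],
       trial_index = seq_len(n_total),
       rt_ms = rt[ord],
       correct = correct[ord],
       ssd_ms = ssd[ord],
       responded = responded[ord])
}

#' Generate trials for one subject and one task
#'
#' Trial counts and condition mix follow `config$trial_plan`. RTs are
#' ex-Gaussian around the subject's baseline, shifted by the subject's true
#' interference effect in interference conditions; per-trial errors are
#' Bernoulli with a logistic model coupling a fast speed trait to higher
#' error rates. Stop trials respond iff the sampled latent go RT beats
#' `ssd + true_ssrt` (independent horse race). Uses the current RNG state;
#' for seeded, order-independent generation use [generate_battery()].
#'
#' @param traits a one-row data.frame from [draw_subject_traits()].
#' @param task one of [inhibition_tasks()].
#' @param config a [generator_config()].
#' @return data.frame of trials (one row per trial) with columns
#'   `subject_id`, `task`, `condition`, `trial_index`, `rt_ms`, `correct`,
#'   `ssd_ms`, `responded`.
#' @export
generate_task_trials <- function(traits, task, config) {
  if (!task %in% inhibition_tasks())
    stop("unknown task: ", task)
  stopifnot(nrow(traits) == 1L)
  as.data.frame(gen_task_core(as.list(traits), task, config),
                stringsAsFactors = FALSE)
}

#' Generate a full synthetic battery
#'
#' Concatenates [generate_task_trials()] over all subjects and tasks, with
#' the global seed expanded into per-(subject, task) substreams so the
#' result is reproducible and independent of iteration order.
#'
#' @param config a [generator_config()].
#' @param traits optional pre-drawn traits (defaults to
#'   [draw_subject_traits()] under the config seed).
#' @return data.frame of all trials.
#' @export
generate_battery <- function(config, traits = draw_subject_traits(config)) {
  tasks <- inhibition_tasks()
  acc <- vector("list", nrow(traits) * length(tasks))
  k <- 0L
  for (i in seq_len(nrow(traits))) {
    tr <- as.list(traits[i, ])
    for (j in seq_along(tasks)) {
      set.seed(substream_seed(config$seed, tr$subject_id, j))
      k <- k + 1L
      acc[[k]] <- gen_task_core(tr, tasks[j], config)
    }
  }
  out <- data.table::rbindlist(acc)
  data.table::setDF(out)
  out
}

#' Ground-truth outcome scores
#'
#' Returns each subject's true interference effect per task (the quantity
#' the scoring module estimates) and true SSRT, for recovery testing.
#'
#' @param traits data.frame from [draw_subject_traits()].
#' @param config the generating [generator_config()].
#' @return data.frame with `subject_id`, one column per task, `true_ssrt`.
#' @export
true_scores <- function(traits, config) {
  out <- data.frame(subject_id = traits$subject_id)
  for (t in inhibition_tasks())
    out[[t]] <- traits[[paste0("effect_", t)]]
  out$true_ssrt <- traits$true_ssrt
  out
}
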