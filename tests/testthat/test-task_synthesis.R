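test_that("battery reproduces the standard trial counts and condition mix", {
  cfg <- generator_config(n_subjects = 2, seed = 11)
  bat <- generate_battery(cfg)
  expect_equal(nrow(bat), 2 * (90 + 240 + 440 + 160 + 168 + 168))

  s1 <- bat[bat$subject_id == 1, ]
  expect_equal(sum(s1$task == "stop_signal"), 440)
  expect_equal(sum(!is.na(s1$ssd_ms)), 110)  # 25% stop trials
  expect_true(all(s1$ssd_ms[!is.na(s1$ssd_ms)] %in% seq(0, 500, 100)))
  fl <- table(s1$condition[s1$task == "flanker"])
  expect_equal(as.integer(fl), rep(40L, 4))
  expect_equal(sum(s1$task == "antisaccade"), 90)
  expect_equal(as.integer(table(s1$condition[s1$task == "shape_matching"])),
               c(112L, 56L))
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  cfg <- generator_config(n_subjects = 3, seed = 5)
  b1 <- generate_battery(cfg)
  b2 <- generate_battery(cfg)
  expect_identical(b1, b2)
  cfg2 <- generator_config(n_subjects = 3, seed = 6)
  b3 <- generate_battery(cfg2)
  expect_false(isTRUE(all.equal(b1$rt_ms, b3$rt_ms)))
})

test_that("latent factor moments are recovered at large n", {
  # independence case
  t0 <- draw_subject_traits(generator_config(50000, rho = 0, seed = 2))
  expect_lt(abs(cor(t0$RI, t0$DI)), 0.02)
  # generating correlation recovered
  t1 <- draw_subject_traits(generator_config(50000, rho = 0.67, seed = 3))
  expect_equal(cor(t1$RI, t1$DI), 0.67, tolerance = 0.015)
  # loading identity: lambda = 1, effect_sd = 1 makes the true effect the
  # factor itself
  t2 <- draw_subject_traits(generator_config(
    20000, loadings = rep(1, 6),
    effect_sds = c(antisaccade = 1, stroop = 1, stop_signal = 1,
                   flanker = 1, shape_matching = 1, word_naming = 1),
    seed = 4))
  expect_gt(cor(t2$effect_stroop, t2$RI), 0.999)
  # empirical loading of the true effect on its factor approaches lambda
  t3 <- draw_subject_traits(generator_config(50000, loadings = rep(0.6, 6),
                                             seed = 5))
  z <- (t3$effect_flanker - mean(t3$effect_flanker)) / sd(t3$effect_flanker)
  expect_equal(cor(z, t3$DI), 0.6, tolerance = 0.02)
})

test_that("non-admissible latent correlation is rejected", {
  expect_error(generator_config(10, rho = 1.0), "positive definite")
  expect_error(generator_config(10, rho = -1.2), "positive definite")
})

test_that("unknown task and missing plan conditions are rejected", {
  cfg <- generator_config(n_subjects = 1, seed = 1)
  tr <- draw_subject_traits(cfg)
  expect_error(generate_task_trials(tr[1, ], "simon", cfg), "unknown task")
  plan <- default_trial_plan()
  plan$stroop <- plan$stroop[plan$stroop$condition != "congruent", ]
  expect_error(generator_config(5, trial_plan = plan), "missing condition")
})

test_that("stop-trial response probability is nondecreasing in SSD", {
  cfg <- generator_config(n_subjects = 300, seed = 21)
  traits <- draw_subject_traits(cfg)
  acc <- vector("list", 300)
  for (i in seq_len(300)) {
    set.seed(1000 + i)
    acc[[i]] <- generate_task_trials(traits[i, ], "stop_signal", cfg)
  }
  st <- do.call(rbind, acc)
  st <- st[st$condition == "stop", ]
  p <- tapply(st$responded, st$ssd_ms, mean)
  expect_true(all(diff(p[order(as.numeric(names(p)))]) >= -0.01))
})

test_that("a zero-length stop process always wins a race it can reach", {
  cfg <- generator_config(
    n_subjects = 1, guess_rate = 0,
    rt_base = within_base <- modifyList(default_rt_base(), list(
      stop_signal = c(mu = 2000, sigma = 1, tau = 1))),
    seed = 9)
  tr <- draw_subject_traits(cfg)
  tr$true_ssrt <- 0   # stop process finishes at the SSD itself
  set.seed(42)
  st <- generate_task_trials(tr[1, ], "stop_signal", cfg)
  stop_trials <- st[st$condition == "stop", ]
  expect_true(all(!stop_trials$responded))
  expect_true(all(is.na(stop_trials$rt_ms)))
})

test_that("speed-accuracy coupling yields negative subject-level RT-error correlations", {
  signs <- vapply(1:5, function(s) {
    cfg <- generator_config(n_subjects = 60, seed = 100 + s)
    traits <- draw_subject_traits(cfg)
    acc <- lapply(seq_len(60), function(i) {
      set.seed(5000 + 60 * s + i)
      generate_task_trials(traits[i, ], "stroop", cfg)
    })
    tr <- do.call(rbind, acc)
    agg <- aggregate(cbind(rt_ms, err = !correct) ~ subject_id, tr, mean)
    sign(cor(agg$rt_ms, agg$err))
  }, numeric(1))
  expect_true(all(signs < 0))
})

test_that("true scores expose the generating ground truth", {
  cfg <- generator_config(
    n_subjects = 8,
    effect_sds = c(antisaccade = 0, stroop = 0, stop_signal = 0,
                   flanker = 0, shape_matching = 0, word_naming = 0),
    ssrt_sd = 0, seed = 3)
  ts <- true_scores(draw_subject_traits(cfg), cfg)
  expect_equal(ts$stroop, rep(48, 8))
  expect_equal(ts$flanker, rep(47, 8))
  expect_equal(ts$antisaccade, rep(0.16, 8))
  expect_equal(ts$true_ssrt, rep(322, 8))
})

test_that("estimated effects track true effects on synthetic data", {
  cfg <- low_noise_config(n_subjects = 200, seed = 31)
  traits <- draw_subject_traits(cfg)
  bat <- generate_battery(cfg, traits)
  om <- build_outcome_matrix(bat, "RT")
  ts <- true_scores(traits, cfg)
  m <- merge(om, ts, by = "subject_id", suffixes = c("_est", "_true"))
  expect_gt(cor(m$stroop_est, m$stroop_true), 0.5)
  expect_gt(cor(m$stop_signal_est, m$true_ssrt, use = "complete.obs"), 0.5)
})
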