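test_that("condition summaries report mean correct RT and error rate", {
  tr <- make_trials(1, "stroop", "congruent",
                    rt_ms = c(rep(500, 9), 450),
                    correct = c(rep(TRUE, 9), FALSE))
  s <- condition_summary(tr)
  expect_equal(s$mean_rt_correct, 500)
  expect_equal(s$error_rate, 0.1)
  expect_equal(s$n_trials, 10)

  # hand-computed 5-trial mean; all correct gives zero error rate
  tr2 <- make_trials(2, "flanker", "no_noise",
                     rt_ms = c(420, 510, 480, 505, 630), correct = TRUE)
  s2 <- condition_summary(tr2)
  expect_equal(s2$mean_rt_correct, (420 + 510 + 480 + 505 + 630) / 5)
  expect_equal(s2$error_rate, 0)
})

test_that("RT difference scores apply the task-specific contrasts", {
  tr <- rbind(
    make_trials(1, "stroop", rep(c("incongruent", "congruent"), each = 4),
                rt_ms = rep(c(655, 607), each = 4), correct = TRUE),
    make_trials(1, "shape_matching",
                rep(c("distractor", "no_distractor"), each = 4),
                rt_ms = rep(c(974, 809), each = 4), correct = TRUE))
  s <- condition_summary(tr)
  expect_equal(rt_difference_score(s, "stroop")$score, 655 - 607)
  expect_equal(rt_difference_score(s, "shape_matching")$score, 974 - 809)
  # equal condition means give zero
  tr0 <- make_trials(3, "flanker",
                     rep(c("noise_incompatible", "no_noise"), each = 3),
                     rt_ms = 500, correct = TRUE)
  expect_equal(rt_difference_score(condition_summary(tr0), "flanker")$score, 0)
  expect_error(rt_difference_score(s, "antisaccade"), "no RT difference")
})

test_that("antisaccade score is the error proportion of target trials", {
  tr <- make_trials(1, "antisaccade", "target",
                    rt_ms = 500,
                    correct = c(rep(FALSE, 13), rep(TRUE, 77)))
  sc <- antisaccade_error_score(condition_summary(tr))
  expect_equal(sc$score, 13 / 90)
  tr2 <- make_trials(2, "antisaccade", "target", rt_ms = 500,
                     correct = rep(TRUE, 90))
  expect_equal(antisaccade_error_score(condition_summary(tr2))$score, 0)
})

test_that("inverse efficiency is RT over proportion correct", {
  expect_equal(inverse_efficiency(500, 0), 500)
  expect_equal(inverse_efficiency(500, 0.2), 625)
  expect_equal(inverse_efficiency(600, 0.5), 1200)
  expect_true(is.na(inverse_efficiency(500, 1)))
})

test_that("IES is never below mean RT, with equality only at zero errors", {
  set.seed(12)
  rt <- runif(50, 300, 900)
  er <- runif(50, 0, 0.9)
  expect_true(all(inverse_efficiency(rt, er) >= rt))
  expect_true(all(inverse_efficiency(rt, er)[er > 0] > rt[er > 0]))
  expect_equal(inverse_efficiency(rt, rep(0, 50)), rt)
})

test_that("IES difference scores contrast per-condition IES", {
  tr <- rbind(
    make_trials(1, "stroop", rep("incongruent", 10),
                rt_ms = 600, correct = c(rep(TRUE, 9), FALSE)),
    make_trials(1, "stroop", rep("congruent", 10),
                rt_ms = 500, correct = TRUE))
  s <- condition_summary(tr)
  expect_equal(ies_difference_score(s, "stroop")$score,
               600 / 0.9 - 500, tolerance = 1e-12)
  # identical conditions give zero
  tr0 <- make_trials(2, "word_naming",
                     rep(c("distractor", "no_distractor"), each = 5),
                     rt_ms = 400, correct = TRUE)
  expect_equal(ies_difference_score(condition_summary(tr0),
                                    "word_naming")$score, 0)
  # antisaccade: single-condition IES
  tra <- make_trials(3, "antisaccade", "target", rt_ms = 458,
                     correct = c(rep(FALSE, 4), rep(TRUE, 21)))
  expect_equal(ies_difference_score(condition_summary(tra),
                                    "antisaccade")$score,
               458 / (1 - 4 / 25))
})

test_that("SSRT rank procedure matches the hand trace", {
  go <- c(300, 400, 500, 600, 700)
  # p(respond | SSD=100) = 0.4 -> n = 2 -> 2nd RT 400 minus 100
  est <- estimate_ssrt(go, rep(100, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(est$ssrt, 300)
  expect_false(est$flagged)
  # non-integer rank interpolates between order statistics
  est2 <- estimate_ssrt(go, rep(100, 4), c(TRUE, FALSE, FALSE, FALSE))
  # n = 5 * 0.25 = 1.25 -> 0.75*300 + 0.25*400 = 325
  expect_equal(est2$ssrt, 325 - 100)
  expect_equal(estimate_ssrt(go, rep(100, 4), c(TRUE, FALSE, FALSE, FALSE),
                             rank_mode = "floor")$ssrt, 300 - 100)
  expect_equal(estimate_ssrt(go, rep(100, 4), c(TRUE, FALSE, FALSE, FALSE),
                             rank_mode = "ceiling")$ssrt, 400 - 100)
})

test_that("degenerate response probabilities yield a flagged missing SSRT", {
  go <- c(300, 400, 500)
  est <- estimate_ssrt(go, c(100, 100, 200), c(FALSE, FALSE, FALSE))
  expect_true(is.na(est$ssrt))
  expect_true(est$flagged)
  expect_false(any(est$per_ssd$eligible))
  expect_error(estimate_ssrt(numeric(0), 100, TRUE), "at least one go RT")
})

test_that("the SSRT estimate is nondecreasing in the response probability", {
  set.seed(8)
  go <- sort(rnorm(400, 600, 100))
  ests <- vapply(seq(0.1, 0.9, 0.1), function(p) {
    resp <- c(rep(TRUE, round(20 * p)), rep(FALSE, 20 - round(20 * p)))
    estimate_ssrt(go, rep(200, 20), resp)$ssrt
  }, numeric(1))
  expect_true(all(diff(ests) >= 0))
})

test_that("SSRT estimator bias vanishes with many go trials", {
  set.seed(101)
  true_ssrt <- 250
  go <- pmax(rnorm(10000, 540, 70) + rexp(10000, 1 / 100), 1)
  ssd <- rep(seq(0, 500, 100), each = 400)
  go_draw <- pmax(rnorm(length(ssd), 540, 70) + rexp(length(ssd), 1 / 100), 1)
  resp <- go_draw < ssd + true_ssrt
  est <- estimate_ssrt(go, ssd, resp)
  expect_equal(est$ssrt, true_ssrt, tolerance = 5 / true_ssrt)
})

test_that("outcome matrix has six columns and a shared stop-signal column", {
  cfg <- generator_config(n_subjects = 5, seed = 17)
  bat <- generate_battery(cfg)
  rt <- build_outcome_matrix(bat, "RT")
  ies <- build_outcome_matrix(bat, "IES")
  expect_equal(dim(rt), c(5, 7))  # subject_id + 6 scores
  expect_named(rt, c("subject_id", inhibition_tasks()))
  expect_equal(rt$stop_signal, ies$stop_signal)
  expect_equal(attr(rt, "scheme"), "RT")
  expect_s3_class(attr(rt, "trim_report"), "data.frame")
  expect_true(all(c("ssd_ms", "p_respond") %in%
                    names(attr(rt, "ssrt_per_ssd"))))
})

test_that("toy fixture scores match hand computation end to end", {
  # two subjects, stroop only; all RTs inside bounds, no outliers
  tr <- rbind(
    make_trials(1, "stroop", rep(c("incongruent", "congruent"), each = 5),
                rt_ms = rep(c(700, 600), each = 5), correct = TRUE),
    make_trials(2, "stroop", rep(c("incongruent", "congruent"), each = 5),
                rt_ms = rep(c(680, 650), each = 5), correct = TRUE))
  om <- build_outcome_matrix(tr, "RT")
  expect_equal(om$stroop, c(100, 30))
})
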