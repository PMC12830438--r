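# The generator's calibration and determinism contracts.

test_that("profile calibration hits the configured propensity moments", {
  pr <- gen_profiles(cohort_config(n_participants = 10000, seed = 5))
  expect_lt(abs(mean(pr$p_intrusion) - 0.296), 0.01)
  expect_lt(abs(sd(pr$p_intrusion) - 0.200), 0.01)
  expect_true(all(abs(pr$p_correct + pr$p_intrusion + pr$p_other - 1) < 1e-12))
  expect_true(all(pr$p_correct >= 0 & pr$p_correct <= 1))
  expect_true(all(pr$mu_rt > 0))
})

test_that("zero dispersion gives every participant the same propensity", {
  pr <- gen_profiles(cohort_config(n_participants = 50, di_sd = 0, seed = 1))
  expect_equal(pr$p_intrusion, rep(0.296, 50))
})

test_that("infeasible propensity dispersion is a configuration error", {
  expect_error(cohort_config(di_mean = 0.296, di_sd = 0.47),
               "infeasible")
  expect_error(cohort_config(di_mean = 1.2), "\\(0, 1\\)")
})

test_that("configured loadings are realised in the profile population", {
  pr <- gen_profiles(cohort_config(n_participants = 10000, seed = 8))
  expect_lt(abs(cor(pr$p_intrusion, pr$mu_time_error) - 0.40), 0.05)
  expect_lt(abs(cor(pr$p_intrusion, pr$t1_acc_true) - (-0.68)), 0.05)
  ab <- pr$t2_lag7_true - pr$t2_lag3_true
  expect_lt(abs(cor(pr$p_intrusion, ab)), 0.05)
  expect_lt(abs(cor(pr$p_intrusion, pr$reading_swe)), 0.05)
})

test_that("degenerate category probabilities force the response identity", {
  pr <- gen_profiles(small_config(n = 4))
  pr$p_intrusion <- 1; pr$p_correct <- 0; pr$p_other <- 0
  tr <- gen_di_trials(pr, 30, seed = 3)
  expect_true(all(tr$response_id == tr$posttarget_id))
  pr$p_intrusion <- 0; pr$p_other <- 1
  tr2 <- gen_di_trials(pr, 30, seed = 3)
  expect_true(all(tr2$response_id != tr2$target_id))
  expect_true(all(tr2$response_id != tr2$posttarget_id))
  expect_true(all(tr2$target_id %in% 2:9 & tr2$posttarget_id %in% 2:9 &
                    tr2$target_id != tr2$posttarget_id))
})

test_that("observed DI-rate dispersion follows the law of total variance", {
  pr <- gen_profiles(cohort_config(n_participants = 5000, seed = 12))
  tr <- gen_di_trials(pr, 60, seed = 12)
  obs <- di_rate(tr)
  expected_sd <- sqrt(var(pr$p_intrusion) +
                        mean(pr$p_intrusion * (1 - pr$p_intrusion)) / 60)
  expect_lt(abs(sd(obs$di_rate) - expected_sd), 0.01)
  expect_lt(abs(mean(obs$di_rate) - mean(pr$p_intrusion)), 0.01)
})

test_that("AB design splits and magnitude calibration behave", {
  pr <- gen_profiles(cohort_config(n_participants = 2000, seed = 4))
  expect_error(gen_ab_trials(pr, 41), "even")
  ab <- gen_ab_trials(pr, 40, seed = 4)
  counts <- table(ab$trial_type)
  expect_equal(unname(counts[["single"]]), unname(counts[["double"]]))
  expect_true(all(is.na(ab$lag[ab$trial_type == "single"])))
  expect_true(all(ab$lag[ab$trial_type == "double"] %in% c(3, 7)))
  sc <- ab_scores(ab)
  expect_lt(abs(mean(sc$ab_magnitude) - 0.403), 0.02)
  # equal lag accuracies imply zero expected magnitude
  pr2 <- pr[1:500, ]; pr2$t2_lag3_true <- pr2$t2_lag7_true
  attr(pr2, "config") <- attr(pr, "config")
  sc2 <- ab_scores(gen_ab_trials(pr2, 60, seed = 9))
  expect_lt(abs(mean(sc2$ab_magnitude)), 0.02)
})

test_that("zero-noise time trials carry the exact wrapped mean error", {
  cfg <- small_config(n = 5, time_trial_sd = 0, wild_frac = 0)
  pr <- gen_profiles(cfg)
  pr$mu_time_error <- 60
  attr(pr, "config") <- cfg
  tt <- gen_time_trials(pr, 20, seed = 2)
  err <- circular_error(tt$cue_angle_deg, tt$response_angle_deg)
  expect_equal(err, rep(60, nrow(tt)))
})

test_that("wild responses drive the +/-160 discard rate as the mixture predicts", {
  cfg <- cohort_config(n_participants = 100, wild_frac = 0.02, seed = 33)
  pr <- gen_profiles(cfg)
  tt <- gen_time_trials(pr, 100, seed = 33)
  err <- circular_error(tt$cue_angle_deg, tt$response_angle_deg)
  discard <- mean(abs(err) >= 160)
  # wild fraction x band width plus the (small) main-distribution tail
  expect_gt(discard, 0.02 * (40 / 360) * 0.3)
  expect_lt(discard, 0.02 * (40 / 360) + 0.01)
})

test_that("RT condition offsets and frequencies are recovered", {
  pr <- gen_profiles(cohort_config(n_participants = 3000, seed = 6))
  expect_error(gen_rt_trials(pr, "stroop", 10), "unknown task|arg")
  rt <- gen_rt_trials(pr, "cueing", 100, seed = 6)
  cm <- tapply(rt$rt_ms, rt$condition, mean)
  expect_lt(abs((cm[["different"]] - cm[["absent"]]) - 37), 3)
  expect_lt(abs((cm[["same"]] - cm[["absent"]]) - (-36)), 3)
  frac <- table(rt$condition) / nrow(rt)
  expect_lt(abs(frac[["absent"]] - 0.20), 0.01)
  sm <- gen_rt_trials(pr, "simon", 100, seed = 6)
  cms <- tapply(sm$rt_ms, sm$condition, mean)
  expect_lt(abs((cms[["incompatible"]] - cms[["compatible"]]) - 81), 3)
  expect_lt(abs(mean(sm$condition == "compatible") - 0.75), 0.01)
})

test_that("zero noise and zero offsets collapse RTs onto the profile mean", {
  cfg <- small_config(n = 5, rt_trial_sd = 0,
                      cue_offsets = c(different = 0, same = 0))
  pr <- gen_profiles(cfg)
  rt <- gen_rt_trials(pr, "cueing", 20, seed = 2)
  expect_equal(rt$rt_ms, pr$mu_rt[match(rt$participant_id, pr$participant_id)])
})

test_that("mean RT correlates with DI rate at the configured loading", {
  pr <- gen_profiles(cohort_config(n_participants = 2000, seed = 21))
  rt <- gen_rt_trials(pr, "cueing", 200, seed = 21)
  di <- di_rate(gen_di_trials(pr, 200, seed = 21))
  mrt <- tapply(rt$rt_ms, rt$participant_id, mean)
  expect_lt(abs(cor(di$di_rate, mrt[di$participant_id]) - 0.25), 0.07)
})

test_that("identical seed and config give byte-identical trial tables", {
  cfg <- small_config(seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$di_trials, c2$di_trials)
  expect_identical(c1$ab_trials, c2$ab_trials)
  expect_identical(c1$time_trials, c2$time_trials)
  expect_identical(c1$rt_trials, c2$rt_trials)
  c3 <- simulate_cohort(small_config(seed = 78))
  expect_false(identical(c1$di_trials$response_id, c3$di_trials$response_id))
})
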