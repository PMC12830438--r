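# Classification, rate arithmetic, AB scores, RT preprocessing, exclusions.

test_that("response classification follows the target / post-target rule", {
  expect_equal(classify_response(3, 6, 6), "intrusion")
  expect_equal(classify_response(3, 6, 3), "correct")
  expect_equal(classify_response(3, 6, 8), "other")
  expect_equal(classify_response(c(3, 3), c(6, 6), c(6, 2)),
               c("intrusion", "other"))
  expect_error(classify_response(4, 4, 4), "target equals post-target")
})

test_that("DI and guess rates are simple proportions that partition trials", {
  mk <- function(resp) data.frame(participant_id = "p1", target_id = 3,
                                  posttarget_id = 6, response_id = resp)
  s <- di_rate(mk(c(rep(6, 24), rep(3, 56))))
  expect_equal(s$di_rate, 0.30)
  expect_equal(s$guess_rate, 0)
  s2 <- di_rate(mk(c(rep(6, 18), rep(8, 3), rep(3, 39))))
  expect_equal(s2$di_rate, 0.30)
  expect_equal(s2$guess_rate, 0.05)
  expect_equal(s2$di_rate + s2$guess_rate + s2$accuracy, 1)
  s3 <- di_rate(mk(rep(3, 10)))
  expect_equal(s3$di_rate, 0)
  expect_equal(s3$guess_rate, 0)
  empty <- data.frame(participant_id = character(0), target_id = integer(0),
                      posttarget_id = integer(0), response_id = integer(0))
  expect_error(di_rate(empty), "no trials")
})

test_that("high guess rates are flagged with a strict boundary", {
  sc <- data.frame(guess_rate = c(0.26, 0.25, 0))
  out <- flag_high_guess(sc)
  expect_equal(out$excluded_guess, c(TRUE, FALSE, FALSE))
})

test_that("AB magnitude is the lag-7 minus lag-3 difference, sign and all", {
  mk_ab <- function(acc7, acc3, n = 40) {
    lag <- rep(c(3L, 7L), each = n)
    ok <- c(runif(n) < acc3, runif(n) < acc7)
    data.frame(participant_id = "p1", trial_type = "double", lag = lag,
               trial_index = seq_len(2 * n) - 1L,
               t1_id = 3L, t1_response = 3L,
               t2_id = 5L, t2_response = ifelse(ok, 5L, 8L))
  }
  set.seed(1)
  sc <- ab_scores(mk_ab(1, 0))      # deterministic accuracies
  expect_equal(sc$ab_magnitude, 1)
  sc2 <- ab_scores(mk_ab(0.5, 0.5))
  expect_equal(sc2$ab_magnitude, sc2$t2_acc_lag7 - sc2$t2_acc_lag3)
  # exact paper-scale arithmetic on constructed proportions
  tr <- mk_ab(1, 1, n = 1000)
  tr$t2_response[tr$lag == 7][1:189] <- 9L   # lag-7 accuracy .811
  tr$t2_response[tr$lag == 3][1:592] <- 9L   # lag-3 accuracy .408
  sc3 <- ab_scores(tr)
  expect_equal(sc3$t2_acc_lag7, 0.811)
  expect_equal(sc3$t2_acc_lag3, 0.408)
  expect_equal(sc3$ab_magnitude, 0.403)
  # negative AB is allowed
  tr2 <- mk_ab(1, 1, n = 10)
  tr2$t2_response[tr2$lag == 7][1:5] <- 9L
  tr2$t2_response[tr2$lag == 3][1:3] <- 9L
  expect_equal(ab_scores(tr2)$ab_magnitude, 0.5 - 0.7)
  # a lag with zero trials is undefined, not zero
  tr3 <- mk_ab(1, 1, n = 5)
  tr3 <- tr3[tr3$lag == 3, ]
  sc4 <- ab_scores(tr3)
  expect_true(sc4$ab_undefined)
  expect_true(is.na(sc4$ab_magnitude))
})

test_that("RT absolute window retains its boundaries and drops outside", {
  tr <- data.frame(participant_id = "p1", task = "simon",
                   condition = "compatible",
                   trial_index = 0:4,
                   rt_ms = c(100, 150, 400, 1000, 1200), correct = TRUE)
  out <- rt_preprocess(tr)
  expect_equal(sort(out$trials$rt_ms), c(150, 400, 1000))
  expect_equal(out$ledger$n_excluded[out$ledger$stage == "absolute_window"], 2)
})

test_that("RT preprocessing is idempotent and trims per condition", {
  set.seed(42)
  tr <- data.frame(
    participant_id = rep(sprintf("p%d", 1:8), each = 100),
    task = "simon",
    condition = rep(rep(c("compatible", "incompatible"), each = 50), 8),
    trial_index = rep(0:99, 8),
    rt_ms = pmin(pmax(rnorm(800, 450, 80), 151), 999),
    correct = runif(800) > 0.05)
  out1 <- rt_preprocess(tr)
  out2 <- rt_preprocess(out1$trials)
  expect_equal(out2$trials$rt_ms, out1$trials$rt_ms)
  expect_equal(out2$ledger$n_excluded, c(0, 0, 0))
  # identical RTs: the SD pass trims nothing
  flat <- tr; flat$rt_ms <- 500
  expect_equal(rt_preprocess(flat)$ledger$n_excluded[3], 0)
  expect_error(rt_preprocess(transform(tr, condition = "weird")),
               "unknown condition")
})

test_that("condition means give the published-scale Simon effect", {
  tr <- data.frame(
    participant_id = "p1", task = "simon",
    condition = rep(c("incompatible", "compatible"), each = 4),
    trial_index = 0:7,
    rt_ms = c(497, 497, 497, 497, 416, 416, 416, 416), correct = TRUE)
  out <- rt_preprocess(tr)
  expect_equal(out$effects$simon_effect_ms, 81)
})

test_that("participant outliers use a strict 3-SD rule including the candidate", {
  sc <- data.frame(di_rate = c(rnorm(60, 0.296, 0.02), 0.933))
  out <- flag_outlier_participants(sc, "di_rate")
  expect_true(out$excluded_di_rate[61])
  expect_equal(sum(out$excluded_di_rate), 1)
  # construct a sample whose extreme value sits just at / just over 3 SD
  base <- c(rep(0, 20), 1)
  zof <- function(x) { v <- c(base, x); abs(x - mean(v)) / sd(v) }
  x3 <- uniroot(function(x) zof(x) - 3, c(0.1, 50), tol = 1e-10)$root
  under <- data.frame(v = c(base, x3 - 1e-6))
  over <- data.frame(v = c(base, x3 + 1e-4))
  expect_false(tail(flag_outlier_participants(under, "v")$excluded_v, 1))
  expect_true(tail(flag_outlier_participants(over, "v")$excluded_v, 1))
  # a value exactly at the mean is never flagged
  expect_false(flag_outlier_participants(
    data.frame(v = c(1, 2, 3, 2)), "v")$excluded_v[4])
})

test_that("score_cohort merges all task families per participant-session", {
  coh <- simulate_cohort(small_config(n = 15, seed = 5))
  sc <- score_cohort(coh)
  expect_equal(nrow(sc), 30)  # 15 participants x 2 sessions
  expect_true(all(c("di_rate", "guess_rate", "t1_acc", "ab_magnitude",
                    "mean_time_error_deg", "cueing_rt", "simon_rt",
                    "cueing_effect_ms", "simon_effect_ms") %in% names(sc)))
  expect_true(all(sc$di_rate + sc$guess_rate <= 1 + 1e-12))
})
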