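mk_trials <- function(rt, task = "flanker", correct = TRUE,
                      condition = "congruent", id = "P1", answer = "opt1") {
  n <- length(rt)
  correct <- rep_len(correct, n)
  data.frame(participant_id = id, session = 1L, task = task,
             condition = rep_len(condition, n), trial = seq_len(n) - 1L,
             stimulus = "s", answer = answer,
             response = ifelse(correct, answer, "wrong"),
             rt_ms = rt, window_ms = 1500, feedback = "none",
             stringsAsFactors = FALSE)
}

test_that("anticipatory trials are removed first, then the individual SD trim", {
  set.seed(1)
  rt <- c(stats::runif(93, 300, 800), stats::runif(7, 50, 199))
  res <- clean_trials(mk_trials(rt))
  expect_equal(res$tally$n[res$tally$stage == "anticipatory"], 7L)
  # all identical RTs: sd = 0 handled as no removal
  res2 <- clean_trials(mk_trials(rep(500, 20)))
  expect_equal(res2$tally$n[res2$tally$stage == "individual_sd"], 0L)
  expect_equal(nrow(res2$records), 20L)
})

test_that("cleaning matches a brute-force two-pass filter and conserves counts", {
  set.seed(2)
  trials <- rbind(
    mk_trials(exp(stats::rnorm(200, log(500), 0.8)), id = "P1"),
    mk_trials(exp(stats::rnorm(150, log(700), 0.6)), id = "P2",
              task = "stroop"))
  res <- clean_trials(trials)
  # independent two-pass reference
  keep1 <- trials$rt_ms >= 200
  kept_ref <- trials[keep1, ]
  keep2 <- logical(nrow(kept_ref))
  for (key in unique(paste(kept_ref$participant_id, kept_ref$task))) {
    idx <- paste(kept_ref$participant_id, kept_ref$task) == key
    m <- mean(kept_ref$rt_ms[idx]); s <- stats::sd(kept_ref$rt_ms[idx])
    keep2[idx] <- abs(kept_ref$rt_ms[idx] - m) <= 3 * s
  }
  expect_equal(res$records$rt_ms, kept_ref$rt_ms[keep2])
  expect_equal(nrow(res$records) + nrow(res$removed), nrow(trials))
  tal <- res$tally
  expect_equal(tal$n[tal$stage == "input"],
               tal$n[tal$stage == "kept"] +
                 tal$n[tal$stage == "anticipatory"] +
                 tal$n[tal$stage == "individual_sd"])
})

test_that("rate correct score is correct responses per second of response time", {
  tr <- mk_trials(rep(2000, 10), correct = c(rep(TRUE, 8), rep(FALSE, 2)))
  expect_equal(score_task(tr, "rcs"), 8 / 20)
  tr2 <- mk_trials(rep(1000, 12))
  expect_equal(score_task(tr2, "rcs"), 1)
  # sensitivity reading: divide additionally by the trial count
  cfg <- cleaning_config(rcs_denominator = "literal_product")
  expect_equal(score_task(tr, "rcs", cfg), 0.04)
  # independent spreadsheet-style recomputation on a mixed fixture
  set.seed(3)
  rts <- stats::runif(30, 400, 1200)
  okv <- stats::runif(30) < 0.8
  tr3 <- mk_trials(rts, correct = okv)
  expect_equal(score_task(tr3, "rcs"), sum(okv) / (sum(rts) / 1000))
})

test_that("mean correct RT averages correct trials only (dual block for tap-and-trace)", {
  tr <- mk_trials(c(400, 600, 800), correct = c(TRUE, FALSE, TRUE))
  expect_equal(score_task(tr, "mean_correct_rt"), 600)
  tt <- rbind(
    mk_trials(rep(500, 6), task = "tap_trace", condition = "tap_target",
              answer = "go"),
    mk_trials(rep(900, 6), task = "tap_trace", condition = "dual_target",
              answer = "go"))
  expect_equal(score_task(tt, "mean_correct_rt"), 900)
  expect_true(is.na(score_task(mk_trials(500, correct = FALSE),
                               "mean_correct_rt")))
})

test_that("validity filter enforces minimum trials and strict below-chance removal", {
  bat <- default_battery()
  # stroop with 4 options: accuracy 0.20 < 0.25 is dropped
  tr <- rbind(mk_trials(rep(700, 20), task = "stroop",
                        condition = "congruent",
                        correct = stats::runif(20) < 0),
              mk_trials(rep(700, 20), task = "stroop",
                        condition = "incongruent", correct = TRUE))
  tr$response[tr$condition == "congruent"] <- "wrong"
  acc02 <- tr
  acc02$response[1:30] <- "wrong"  # 10/40 correct = 0.25 -> boundary
  ok <- validity_filter(acc02, bat$stroop)
  expect_true(ok$keep)  # exactly at chance is retained (strict less-than)
  acc019 <- tr
  acc019$response[1:33] <- "wrong"  # 7/40 < chance
  expect_equal(validity_filter(acc019, bat$stroop)$reason,
               "chance_accuracy")
  # a condition with 4 trials fails the minimum-trials rule
  few <- rbind(mk_trials(rep(500, 4), condition = "congruent"),
               mk_trials(rep(500, 20), condition = "incongruent"))
  expect_equal(validity_filter(few, bat$flanker)$reason, "min_trials")
  full <- rbind(mk_trials(rep(500, 5), condition = "congruent"),
                mk_trials(rep(500, 20), condition = "incongruent"))
  expect_true(validity_filter(full, bat$flanker)$keep)
})

test_that("go/no-go chance rule drops hit-rate <= false-alarm-rate performance", {
  bat <- default_battery()
  mk_cpt <- function(hit, fa) {
    go <- mk_trials(rep(400, 40), task = "cpt_impulsive",
                    condition = "target", answer = "go",
                    correct = c(rep(TRUE, hit), rep(FALSE, 40 - hit)))
    ng <- mk_trials(rep(400, 10), task = "cpt_impulsive",
                    condition = "noresp", answer = "noresp",
                    correct = c(rep(FALSE, fa), rep(TRUE, 10 - fa)))
    ng$response <- ifelse(ng$response == "noresp", NA, "go")
    ng$response[!c(rep(TRUE, fa), rep(FALSE, 10 - fa))] <- NA
    ng$rt_ms[is.na(ng$response)] <- NA
    rbind(go, ng)
  }
  expect_true(validity_filter(mk_cpt(35, 2), bat$cpt_impulsive)$keep)
  expect_equal(validity_filter(mk_cpt(8, 9), bat$cpt_impulsive)$reason,
               "chance_accuracy")
})

test_that("MAD filter drops extreme scores and tolerates degenerate columns", {
  keep <- mad_outlier_filter(c(1, 2, 3, 2, 100))
  expect_identical(unname(which(!keep)), 5L)
  keep2 <- mad_outlier_filter(rep(3, 10))
  expect_true(all(keep2))
  expect_true(attr(keep2, "mad_zero"))
  # a majority-constant column has zero MAD: protected, nothing dropped
  keep3 <- mad_outlier_filter(c(1, 1, 1, 1, 100))
  expect_true(all(keep3))
  expect_true(attr(keep3, "mad_zero"))
  expect_error(mad_outlier_filter(c(1, NA, NA)), "at least 3")
  # Monte-Carlo removal fraction on a normal sample matches the normal
  # tail beyond 3 SD (the 1.4826 constant makes MAD estimate the SD)
  set.seed(4)
  x <- stats::rnorm(10000)
  frac <- mean(!mad_outlier_filter(x))
  expect_lt(abs(frac - 2 * stats::pnorm(-3)), 0.002)
})

test_that("residualization removes the covariate exactly", {
  set.seed(5)
  cov_ <- stats::runif(50, 300, 500)
  expect_equal(residualize(3 + 0.5 * cov_, cov_), rep(0, 50),
               tolerance = 1e-10)
  y <- stats::rnorm(50)
  r <- residualize(y, cov_)
  expect_lt(abs(stats::cor(r, cov_)), 1e-10)
  expect_warning(residualize(y, rep(5, 50)), "constant covariate")
  # orthogonal covariate: residuals are the centered scores
  yc <- y - mean(y)
  covo <- rep(c(-1, 1), 25)
  yo <- yc - covo * sum(yc * covo) / sum(covo^2)
  expect_equal(residualize(yo, covo), yo - mean(yo), tolerance = 1e-10)
})

test_that("RT metrics are oriented so faster is higher", {
  expect_equal(transform_rt_metric(500), -5)
  expect_equal(transform_rt_metric(0), 0)
  expect_gt(transform_rt_metric(400), transform_rt_metric(700))
})

test_that("screening excludes on any high-risk flag or four moderate flags", {
  meta <- data.frame(
    participant_id = paste0("P", 1:4),
    high_risk_ip = c(TRUE, FALSE, FALSE, FALSE),
    moderate_risk_1 = c(FALSE, TRUE, TRUE, FALSE),
    moderate_risk_2 = c(FALSE, TRUE, TRUE, FALSE),
    moderate_risk_3 = c(FALSE, TRUE, TRUE, FALSE),
    moderate_risk_4 = c(FALSE, FALSE, TRUE, FALSE))
  res <- screen_participants(meta)
  expect_identical(res$keep, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(res$reason[1], "high_risk")
  expect_identical(res$reason[3], "moderate_risk_count")
  expect_error(screen_participants(data.frame(participant_id = "P1")),
               "risk-flag")
})

test_that("ICC matches the variance-components oracle and classifies correctly", {
  set.seed(6)
  s1 <- stats::rnorm(40); s2 <- 0.6 * s1 + stats::rnorm(40, 0, 0.7) + 0.2
  r <- icc(s1, s2)
  expect_equal(r$icc, oracle_icc_a1(s1, s2), tolerance = 1e-10)
  same <- icc(s1, s1)
  expect_equal(same$icc, 1)
  expect_identical(same$class, "excellent")
  expect_identical(icc_class(0.65), "good")
  expect_identical(icc_class(0.45), "fair")
  expect_identical(icc_class(0.1), "poor")
  expect_error(icc(1:2, 2:3), "at least 3")
  # consistency variant ignores a constant session shift
  shifted <- icc(s1, s1 + 5, variant = "ICC_C1")
  expect_equal(shifted$icc, 1, tolerance = 1e-10)
  # independent sessions: estimate near zero
  set.seed(7)
  null <- icc(stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(abs(null$icc), 0.07)
})

test_that("score table pipeline attributes every removal to one stage", {
  co <- sample_cohort(default_cohort_model(), 30, seed = 31)
  trials <- administer_battery(co, seed = 32)
  hand <- stats::setNames(co$participants$dominant_hand,
                          co$participants$participant_id)
  st <- build_score_table(trials, dominant_hand = hand)
  expect_equal(ncol(st), 10L)
  expect_setequal(colnames(st), SCORED_TASKS)
  log <- attr(st, "removal_log")
  expect_true(all(log$stage %in% c("min_trials", "chance_accuracy",
                                   "mad_outlier")))
  # no score is removed twice
  expect_false(anyDuplicated(log[c("participant_id", "task")]) > 0)
  # every missing cell is either a logged removal or a failed score
  raw <- attr(st, "raw")
  for (i in seq_len(nrow(log))) {
    expect_true(is.na(raw[log$participant_id[i], log$task[i]]))
  }
  # residualized scores are uncorrelated with the covariate by construction
  tally <- attr(st, "trial_tally")
  expect_equal(tally$n[tally$stage == "input"], nrow(trials))
})
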