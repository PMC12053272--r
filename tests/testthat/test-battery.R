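test_that("schedules honor condition proportions exactly", {
  bat <- default_battery()
  sch <- make_schedule(bat$cpt_impulsive, seed = 2)
  expect_equal(sum(sch$condition == "target"), 40L)
  expect_equal(sum(sch$condition == "noresp"), 10L)
  sch2 <- make_schedule(bat$stroop, seed = 3)
  expect_equal(as.integer(table(sch2$condition)[c("congruent", "incongruent")]),
               c(24L, 24L))
  # largest-remainder rounding on an uneven split
  expect_equal(unname(allocate_counts(c(a = 1/3, b = 1/3, c = 1/3), 50)),
               c(17L, 17L, 16L))
  expect_equal(sum(allocate_counts(c(a = 0.21, b = 0.395, c = 0.395), 37)),
               37L)
  expect_error(task_spec("flanker", list(list(name = "m", n_trials = 10,
                                              proportions = c(a = 0.6,
                                                              b = 0.6)))),
               "sum to 1")
})

test_that("block orders are fixed and schedules are seed-deterministic", {
  bat <- default_battery()
  sch <- make_schedule(bat$boxed, seed = 5)
  expect_equal(rle(sch$block)$values,
               c("feature_4", "feature_12", "conjunction_4",
                 "conjunction_12"))
  expect_equal(rle(make_schedule(bat$basic_rt, seed = 1)$block)$values,
               c("right", "left"))
  expect_equal(rle(make_schedule(bat$tap_trace, seed = 1)$block)$values,
               c("tap", "dual"))
  expect_identical(make_schedule(bat$flanker, seed = 11),
                   make_schedule(bat$flanker, seed = 11))
})

test_that("span controller advances after two in a row and terminates after three misses", {
  st <- span_state()
  st <- span_next(st, TRUE)
  expect_equal(st$current_length, 3L)
  st <- span_next(st, TRUE)
  expect_equal(st$current_length, 4L)
  st <- span_next(st, FALSE); st <- span_next(st, FALSE)
  expect_false(st$terminated)
  st <- span_next(st, FALSE)
  expect_true(st$terminated)
  expect_error(span_next(st, TRUE), "terminated")
})

test_that("span length caps at 9 and continues until the failure criterion", {
  st <- span_state()
  for (i in 1:40) st <- span_next(st, TRUE)
  expect_equal(st$current_length, 9L)
  expect_false(st$terminated)
})

test_that("the three-correct-allow-one-miss variant advances with one interleaved miss", {
  st <- span_state("three_correct_allow_one_miss")
  for (o in c(TRUE, FALSE, TRUE, TRUE)) st <- span_next(st, o)
  expect_equal(st$current_length, 4L)  # 3 successes, 1 miss -> advance
  st2 <- span_state("three_correct_allow_one_miss")
  for (o in c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)) {
    st2 <- span_next(st2, o)
  }
  # two misses interleaved: the first triple does not advance; counters
  # reset and the next clean triple does
  expect_equal(st2$current_length, 4L)
})

test_that("span controller matches the brute-force reference on all outcome strings", {
  # exhaustive up to length 8 here (the acceptance suite goes to 12)
  for (rule in c("two_in_a_row", "three_correct_allow_one_miss")) {
    for (len in 1:8) {
      for (code in 0:(2^len - 1)) {
        outcomes <- as.logical(bitwAnd(bitwShiftR(code, 0:(len - 1)), 1))
        ref <- oracle_span_run(outcomes, rule)
        st <- span_state(rule)
        for (o in outcomes) {
          if (st$terminated) break
          st <- span_next(st, o)
        }
        expect_identical(st$history$length, ref$length)
        expect_identical(st$terminated, ref$terminated)
        expect_identical(st$current_length, as.integer(ref$final_length))
      }
    }
  }
})

test_that("object span is the longest length attempted twice consecutively", {
  expect_equal(span_score(list(length = c(3, 3, 4, 4, 4, 4),
                               success = c(T, T, T, F, F, F))), 4L)
  expect_equal(span_score(list(length = c(3, 3, 3),
                               success = c(F, F, F))), 3L)
  set.seed(8)
  for (r in 1:100) {
    outcomes <- stats::runif(sample(3:14, 1)) < 0.6
    ref <- oracle_span_run(outcomes)
    if (length(ref$length) == 0) next
    expect_equal(span_score(list(length = ref$length,
                                 success = ref$success)),
                 as.integer(oracle_object_span(ref$length)))
  }
  expect_error(span_score(list(length = integer(0), success = logical(0))),
               "empty")
})

test_that("administration composes schedule, respondent, and staircase", {
  calib <- default_calibration()
  bat <- default_battery()
  # a respondent so fast and able that every trial is green
  calib$tasks$flanker$meanlog <- log(10)
  pr <- list(participant_id = "X1", eta = c(flanker = 8), t0 = 5,
             sigma = 0.01, lapse = 0, anticipatory = 0, kappa = 5)
  log <- administer_task(bat$flanker, pr, calib, seed = 2)
  expect_true(all(log$feedback == "green"))
  expect_true(all(diff(log$window_ms) <= 0))

  # continuous performance: no window adaptation, no tri-color feedback
  co <- sample_cohort(default_cohort_model(), 2, seed = 3)
  log2 <- administer_task(bat$cpt_sustained, cohort_profile(co, 1),
                          default_calibration(), seed = 4)
  expect_true(all(log2$feedback == "none"))
  expect_equal(length(unique(log2$window_ms)), 1L)

  # reproducibility of full records
  log3a <- administer_task(bat$taskswitch, cohort_profile(co, 2),
                           default_calibration(), seed = 9)
  log3b <- administer_task(bat$taskswitch, cohort_profile(co, 2),
                           default_calibration(), seed = 9)
  expect_identical(log3a, log3b)
  expect_error(
    administer_task(bat$flanker,
                    list(participant_id = "X", eta = c(flanker = 0),
                         t0 = 100, sigma = 0.3, lapse = 0,
                         anticipatory = 0, kappa = 5),
                    calib = list(tasks = list(), defaults = calib$defaults),
                    seed = 1),
    "no response model")
})

test_that("span administration reflects capacity through the controller", {
  calib <- default_calibration()
  calib$defaults$span_gamma <- 50  # effectively deterministic recall
  bat <- default_battery()
  # capacity 5.5: succeeds at lengths <= 5, fails at 6 and terminates
  pr <- list(participant_id = "X1",
             eta = c(span_fwd = (5.5 - calib$defaults$kappa_mean) /
                       calib$defaults$kappa_sd),
             t0 = 100, sigma = 0.3, lapse = 0, anticipatory = 0)
  log <- administer_task(bat$span_fwd, pr, calib, seed = 5)
  lens <- as.integer(sub("^len", "", log$condition))
  expect_identical(lens, c(3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 6L))
  expect_equal(score_task(log, "object_span"), 6L)
})

test_that("battery administration is reproducible and carries every task", {
  co <- sample_cohort(default_cohort_model(), 3, seed = 21)
  tr1 <- administer_battery(co, seed = 5)
  tr2 <- administer_battery(co, seed = 5)
  expect_identical(tr1, tr2)
  expect_setequal(unique(tr1$task), TASK_IDS)
  expect_setequal(unique(tr1$participant_id),
                  co$participants$participant_id)
})
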