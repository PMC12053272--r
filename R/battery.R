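#' Task identifiers of the eleven-paradigm battery
#' @format Character vector of the eleven task ids.
#' @export
TASK_IDS <- c("basic_rt", "span_fwd", "span_bwd", "flanker",
              "cpt_impulsive", "cpt_sustained", "stroop", "boxed",
              "compass", "taskswitch", "tap_trace")

#' The ten scored task metrics (basic response time is a covariate)
#' @format Character vector of the ten scored task ids.
#' @export
SCORED_TASKS <- setdiff(TASK_IDS, "basic_rt")

#' Construct a task specification
#'
#' A task is a sequence of blocks, each with a trial count and a named
#' vector of condition proportions (realized exactly via largest-remainder
#' rounding). `adaptive` marks tasks driven by the response-window
#' staircase; the two continuous performance tasks are non-adaptive by
#' design (attention tasks exclude the window so the deadline itself does
#' not redirect attention), and the spatial spans adapt through sequence
#' length instead.
#'
#' @param task_id One of [TASK_IDS].
#' @param blocks List of `list(name=, n_trials=, proportions=)` blocks, in
#'   administration order.
#' @param adaptive Logical; response-window staircase on/off.
#' @param n_options Number of response options (drives chance accuracy);
#'   `NA` for go/no-go and span tasks.
#' @param metric_id One of `"rcs"`, `"mean_correct_rt"`, `"object_span"`.
#' @param rt_control `"dominant_hand"` or `"two_hand"`: which basic
#'   response-time average is the processing-speed covariate for this task.
#' @param advancement_rule Span tasks only: `"two_in_a_row"` (advance after
#'   2 consecutive successes) or `"three_correct_allow_one_miss"`.
#' @param go_nogo Logical; `TRUE` for detection tasks where distractor
#'   trials require withholding a response.
#' @return A `task_spec` object.
#' @export
task_spec <- function(task_id, blocks, adaptive = TRUE, n_options = 2,
                      metric_id = "rcs", rt_control = "dominant_hand",
                      advancement_rule = "two_in_a_row", go_nogo = FALSE) {
  task_id <- match.arg(task_id, TASK_IDS)
  metric_id <- match.arg(metric_id, c("rcs", "mean_correct_rt", "object_span"))
  rt_control <- match.arg(rt_control, c("dominant_hand", "two_hand"))
  advancement_rule <- match.arg(advancement_rule,
                                c("two_in_a_row", "three_correct_allow_one_miss"))
  if (grepl("^cpt_", task_id) && adaptive) {
    stop("continuous performance tasks are non-adaptive")
  }
  for (b in blocks) {
    if (abs(sum(b$proportions) - 1) > 1e-8) {
      stop("condition proportions must sum to 1 in block '", b$name, "'")
    }
  }
  structure(list(task_id = task_id, blocks = blocks, adaptive = adaptive,
                 n_options = n_options, metric_id = metric_id,
                 rt_control = rt_control, advancement_rule = advancement_rule,
                 go_nogo = go_nogo),
            class = "task_spec")
}

#' Default battery configuration
#'
#' Per-block trial counts are plausible 5-10 minute administrations:
#' basic response time 2 blocks (right then left hand) of 20; flanker 40;
#' each continuous performance task 50 (impulsive variant 80% targets,
#' sustained 20%); Stroop 48 (50/50 congruent/incongruent); visual search
#' 4 blocks of 16 in the order feature-4, feature-12, conjunction-4,
#' conjunction-12; cueing 48 (equal neutral/congruent/incongruent);
#' task switching 48 with 50% switch trials; tap-and-trace blocks tap,
#' dual, trace of 30 (the trace-only block involves no detection
#' responses and yields no trial records).
#'
#' @param overrides Optional named list of `task_spec` objects replacing
#'   the defaults per task id.
#' @return Named list of `task_spec` objects, one per task.
#' @export
default_battery <- function(overrides = NULL) {
  blk <- function(name, n, props) list(name = name, n_trials = n, proportions = props)
  battery <- list(
    basic_rt = task_spec("basic_rt",
      list(blk("right", 20, c(target = 1)), blk("left", 20, c(target = 1))),
      adaptive = TRUE, n_options = NA, metric_id = "mean_correct_rt",
      rt_control = "dominant_hand", go_nogo = FALSE),
    span_fwd = task_spec("span_fwd",
      list(blk("span", 40, c(sequence = 1))),
      adaptive = FALSE, n_options = NA, metric_id = "object_span"),
    span_bwd = task_spec("span_bwd",
      list(blk("span", 40, c(sequence = 1))),
      adaptive = FALSE, n_options = NA, metric_id = "object_span"),
    flanker = task_spec("flanker",
      list(blk("main", 40, c(congruent = 0.5, incongruent = 0.5))),
      n_options = 2, metric_id = "rcs", rt_control = "two_hand"),
    cpt_impulsive = task_spec("cpt_impulsive",
      list(blk("main", 50, c(target = 0.8, noresp = 0.2))),
      adaptive = FALSE, n_options = NA, metric_id = "mean_correct_rt",
      go_nogo = TRUE),
    cpt_sustained = task_spec("cpt_sustained",
      list(blk("main", 50, c(target = 0.2, noresp = 0.8))),
      adaptive = FALSE, n_options = NA, metric_id = "mean_correct_rt",
      go_nogo = TRUE),
    stroop = task_spec("stroop",
      list(blk("main", 48, c(congruent = 0.5, incongruent = 0.5))),
      n_options = 4, metric_id = "rcs"),
    boxed = task_spec("boxed",
      list(blk("feature_4", 16, c(feature_4 = 1)),
           blk("feature_12", 16, c(feature_12 = 1)),
           blk("conjunction_4", 16, c(conjunction_4 = 1)),
           blk("conjunction_12", 16, c(conjunction_12 = 1))),
      n_options = 2, metric_id = "rcs"),
    compass = task_spec("compass",
      list(blk("main", 48, c(neutral = 1/3, congruent = 1/3, incongruent = 1/3))),
      n_options = 2, metric_id = "rcs", rt_control = "two_hand"),
    taskswitch = task_spec("taskswitch",
      list(blk("main", 48, c(stay = 0.5, switch = 0.5))),
      n_options = 2, metric_id = "rcs", rt_control = "two_hand"),
    tap_trace = task_spec("tap_trace",
      list(blk("tap", 30, c(tap_target = 0.5, tap_noresp = 0.5)),
           blk("dual", 30, c(dual_target = 0.5, dual_noresp = 0.5))),
      n_options = NA, metric_id = "mean_correct_rt", rt_control = "two_hand",
      go_nogo = TRUE)
  )
  if (!is.null(overrides)) {
    for (id in names(overrides)) battery[[id]] <- overrides[[id]]
  }
  battery
}

#' Generate the ordered trial schedule for a task
#'
#' Condition counts within each block honor the task specification's
#' proportions exactly
#' (largest-remainder rounding); trial order is shuffled within block under
#' the seed, while blocks keep their stated administration order. Span
#' tasks return sequence-slot templates (lengths are decided at run time by
#' the span controller).
#'
#' @param spec A `task_spec`.
#' @param seed Integer seed; the same spec and seed give the identical
#'   template order.
#' @return Data frame of trial templates: `task`, `block`, `trial`
#'   (0-based within task), `condition`, `stimulus`, `answer`,
#'   `requires_response`.
#' @export
make_schedule <- function(spec, seed = 1L) {
  out <- as.data.frame(make_schedule_cols(spec, seed),
                       stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Column-list version of make_schedule (hot path: avoids data.frame
# construction per block).
make_schedule_cols <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "task_spec"))
  set.seed(seed)
  block <- conds <- stim <- answer <- list()
  trial0 <- 0L
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    counts <- allocate_counts(b$proportions, b$n_trials)
    cc <- sample(rep(names(counts), counts))
    n <- length(cc)
    answer[[bi]] <- if (isTRUE(spec$go_nogo)) {
      ifelse(grepl("noresp$", cc), "noresp", "go")
    } else if (spec$task_id == "basic_rt") {
      rep("go", n)
    } else if (identical(names(b$proportions), "sequence")) {
      rep("recall", n)
    } else {
      paste0("opt", sample.int(max(spec$n_options, 1), n, replace = TRUE))
    }
    block[[bi]] <- rep(b$name, n)
    conds[[bi]] <- cc
    stim[[bi]] <- sprintf("%s_%s_%03d", b$name, cc, seq_len(n))
    trial0 <- trial0 + n
  }
  answer <- unlist(answer, use.names = FALSE)
  list(task = rep(spec$task_id, trial0),
       block = unlist(block, use.names = FALSE),
       trial = seq_len(trial0) - 1L,
       condition = unlist(conds, use.names = FALSE),
       stimulus = unlist(stim, use.names = FALSE),
       answer = answer,
       requires_response = answer != "noresp")
}

#' Initialize a spatial-span controller state
#'
#' Sequences start at length 3 and range 3-9. Under `two_in_a_row` the
#' length advances after 2 consecutive successful recalls; under
#' `three_correct_allow_one_miss` it advances once 3 recalls at the
#' current length succeed with at most one interleaved miss. Either way
#' the task terminates after 3 consecutive failed recalls. At the cap the
#' controller stays at length 9 until the failure criterion ends the task.
#'
#' @param advancement_rule Advancement variant.
#' @return A `span_state` object.
#' @export
span_state <- function(advancement_rule = c("two_in_a_row",
                                            "three_correct_allow_one_miss")) {
  advancement_rule <- match.arg(advancement_rule)
  structure(list(current_length = 3L, consec_successes = 0L,
                 consec_failures = 0L, successes_at_length = 0L,
                 failures_at_length = 0L,
                 history = list(length = integer(0), success = logical(0)),
                 terminated = FALSE, advancement_rule = advancement_rule),
            class = "span_state")
}

#' Advance the span controller by one recall attempt
#'
#' @param state A `span_state`; calling after termination is an error.
#' @param trial_success Logical; was the sequence recalled correctly?
#' @return The updated `span_state`.
#' @export
span_next <- function(state, trial_success) {
  stopifnot(inherits(state, "span_state"))
  if (state$terminated) stop("span task already terminated")
  state$history$length <- c(state$history$length, state$current_length)
  state$history$success <- c(state$history$success, trial_success)
  if (trial_success) {
    state$consec_failures <- 0L
    state$consec_successes <- state$consec_successes + 1L
    state$successes_at_length <- state$successes_at_length + 1L
    advance <- switch(state$advancement_rule,
      two_in_a_row = state$consec_successes >= 2L,
      three_correct_allow_one_miss =
        state$successes_at_length >= 3L && state$failures_at_length <= 1L)
    reset <- state$advancement_rule == "three_correct_allow_one_miss" &&
      state$successes_at_length >= 3L && state$failures_at_length > 1L
    if (advance) {
      state$current_length <- min(state$current_length + 1L, 9L)
      state$consec_successes <- 0L
      state$successes_at_length <- 0L
      state$failures_at_length <- 0L
    } else if (reset) {
      state$successes_at_length <- 0L
      state$failures_at_length <- 0L
    }
  } else {
    state$consec_successes <- 0L
    state$consec_failures <- state$consec_failures + 1L
    state$failures_at_length <- state$failures_at_length + 1L
    if (state$consec_failures >= 3L) state$terminated <- TRUE
  }
  state
}

#' Object span: longest sequence length attempted on two consecutive trials
#'
#' @param history Either a `span_state`, or a list/data.frame with elements
#'   `length` (integer) and `success` (logical).
#' @return Integer object span.
#' @export
span_score <- function(history) {
  if (inherits(history, "span_state")) history <- history$history
  len <- history$length
  if (length(len) == 0) stop("empty span history")
  if (length(len) == 1) return(as.integer(len))
  pairs <- len[-length(len)] == len[-1]
  if (!any(pairs)) return(as.integer(max(len)))  # degenerate: no repeated length
  as.integer(max(len[-length(len)][pairs]))
}

#' Administer one task to a virtual respondent
#'
#' Composes the trial schedule, the respondent's generative response model,
#' and (for adaptive tasks) the response-window staircase into a trial log.
#' Non-adaptive tasks carry feedback `"none"` and a constant window. Span
#' tasks emit one record per administered sequence, driven by the span
#' controller until termination (or until the sequence-slot budget is
#' exhausted).
#'
#' @param spec A `task_spec`.
#' @param profile A respondent profile row (see [sample_cohort()]): named
#'   list with `participant_id`, `eta` (named ability vector), `t0`,
#'   `sigma`, `lapse`, `anticipatory`, `kappa`.
#' @param calib Calibration list from [default_calibration()].
#' @param seed Integer seed.
#' @param session Session index recorded in the log (1-based).
#' @param engine_cfg `response_window_state` template for adaptive tasks.
#' @return Data frame of trial records with the pinned column set:
#'   `participant_id`, `session`, `task`, `condition`, `trial`, `stimulus`,
#'   `answer`, `response`, `rt_ms`, `window_ms`, `feedback`.
#' @export
administer_task <- function(spec, profile, calib = default_calibration(),
                            seed = 1L, session = 1L,
                            engine_cfg = response_window_state()) {
  out <- as.data.frame(
    administer_task_cols(spec, profile, calib, seed, session, engine_cfg),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

administer_task_cols <- function(spec, profile, calib, seed, session,
                                 engine_cfg) {
  stopifnot(inherits(spec, "task_spec"))
  task <- spec$task_id
  if (task %in% c("span_fwd", "span_bwd")) {
    return(administer_span(spec, profile, calib, seed, session))
  }
  sched <- make_schedule_cols(spec, seed = seed)
  resp <- respond_cols(profile, task, sched$condition, sched$answer, calib,
                       seed = child_seed(seed, paste0("resp_", task)))
  n <- length(sched$condition)
  feedback <- rep("none", n)
  window <- rep(engine_cfg$window_ms, n)
  if (spec$adaptive) {
    # inlined staircase identical to update_window (tested equivalent)
    w <- engine_cfg$window_ms
    sdn <- engine_cfg$step_down_ms; sup <- engine_cfg$step_up_ms
    wmin <- engine_cfg$min_ms; wmax <- engine_cfg$max_ms
    scaling <- engine_cfg$streak_scaling; cap <- engine_cfg$exponent_cap
    cc <- engine_cfg$consec_correct; cl <- engine_cfg$consec_lapse
    correct <- resp$correct
    rt <- resp$rt_ms
    for (i in seq_len(n)) {
      window[i] <- w
      if (correct[i] && (is.na(rt[i]) || rt[i] <= w)) {
        feedback[i] <- "green"
        w <- w - sdn * 2^(if (scaling) min(cc, cap) else 0L)
        cc <- cc + 1L; cl <- 0L
      } else {
        feedback[i] <- if (correct[i]) "yellow" else "red"
        w <- w + sup * 2^(if (scaling) min(cl, cap) else 0L)
        cl <- cl + 1L; cc <- 0L
      }
      if (w < wmin) w <- wmin else if (w > wmax) w <- wmax
    }
  }
  list(participant_id = rep(profile$participant_id, n),
       session = rep(as.integer(session), n),
       task = sched$task, condition = sched$condition,
       trial = sched$trial, stimulus = sched$stimulus,
       answer = sched$answer, response = resp$response,
       rt_ms = resp$rt_ms, window_ms = window, feedback = feedback)
}

# Span tasks: one record per sequence; the condition label encodes the
# sequence length so per-length trial counts are inspectable downstream.
administer_span <- function(spec, profile, calib, seed, session) {
  set.seed(seed)
  task <- spec$task_id
  gamma <- calib$defaults$span_gamma
  # capacity tracks the task-specific ability of the session being played
  kappa <- calib$defaults$kappa_mean +
    calib$defaults$kappa_sd * unname(profile$eta[task])
  max_seq <- sum(vapply(spec$blocks, function(b) b$n_trials, numeric(1)))
  state <- span_state(spec$advancement_rule)
  len <- integer(max_seq); success <- logical(max_seq); rt <- numeric(max_seq)
  i <- 0L
  while (!state$terminated && i < max_seq) {
    i <- i + 1L
    len[i] <- state$current_length
    success[i] <- stats::runif(1) < stats::plogis(gamma * (kappa - len[i]))
    # per-item presentation + recall time; only the anticipatory floor matters
    rt[i] <- len[i] * (300 + stats::rlnorm(1, 5.0, 0.4))
    state <- span_next(state, success[i])
  }
  idx <- seq_len(i)
  list(participant_id = rep(profile$participant_id, i),
       session = rep(as.integer(session), i),
       task = rep(task, i),
       condition = sprintf("len%d", len[idx]),
       trial = idx - 1L,
       stimulus = sprintf("seq_%02d_len%d", idx, len[idx]),
       answer = rep("recall", i),
       response = ifelse(success[idx], "recall", "recall_error"),
       rt_ms = rt[idx], window_ms = rep(NA_real_, i),
       feedback = rep("none", i))
}

#' Administer the full battery to every cohort member
#'
#' @param cohort An `ef_cohort` from [sample_cohort()].
#' @param battery Named list of `task_spec`s, e.g. [default_battery()].
#' @param calib Calibration list.
#' @param seed Integer seed; fans out per participant and task.
#' @param session Session index recorded in the log.
#' @param eta Optional ability matrix overriding `cohort$eta` (used for
#'   repeat sessions, see [simulate_sessions()]).
#' @return Trial-log data frame across all participants and tasks.
#' @export
administer_battery <- function(cohort, battery = default_battery(),
                               calib = default_calibration(), seed = 1L,
                               session = 1L, eta = NULL) {
  stopifnot(inherits(cohort, "ef_cohort"))
  if (is.null(eta)) eta <- cohort$eta
  engine_cfg <- response_window_state()
  logs <- vector("list", nrow(cohort$participants) * length(battery))
  k <- 0L
  for (i in seq_len(nrow(cohort$participants))) {
    profile <- cohort_profile(cohort, i, eta = eta)
    for (spec in battery) {
      k <- k + 1L
      logs[[k]] <- administer_task_cols(
        spec, profile, calib,
        seed = child_seed(seed, paste(profile$participant_id, spec$task_id,
                                      session, sep = "_")),
        session = session, engine_cfg = engine_cfg)
    }
  }
  cols <- names(logs[[1]])
  out <- lapply(cols, function(cn) {
    unlist(lapply(logs, `[[`, cn), use.names = FALSE)
  })
  names(out) <- cols
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
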