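#' Feedback classes for adaptive trials
#'
#' Every responded trial on an adaptive task is classified into exactly one
#' of three feedback classes shown to the respondent: `"green"` (correct and
#' on time, i.e. within the current response window), `"yellow"` (correct
#' but late), or `"red"` (incorrect). Non-adaptive tasks carry `"none"`.
#'
#' @format Character vector of the three class labels.
#' @export
FEEDBACK_CLASSES <- c("green", "yellow", "red")

#' Construct an adaptive response-window state
#'
#' The response window is the per-trial deadline for a "correct and on
#' time" response. It shortens by `step_down_ms * 2^s` after the s-th
#' consecutive correct-and-on-time trial and lengthens by
#' `step_up_ms * 2^s` after the s-th consecutive incorrect-or-late trial
#' (the streak exponent counts *previous* consecutive outcomes, so the
#' first step of a streak uses 2^0). With `streak_scaling = FALSE` the
#' exponents are fixed at zero and every step is a plain
#' `step_down_ms`/`step_up_ms`.
#'
#' @param window_ms Initial window length in ms.
#' @param step_down_ms Decrement step factor in ms (applied on green).
#' @param step_up_ms Increment step factor in ms (applied on yellow/red).
#' @param min_ms,max_ms Clamp bounds for the window; clamping does not
#'   reset streaks.
#' @param streak_scaling Logical; exponential streak multipliers on/off.
#' @param exponent_cap Maximum streak exponent (numeric safety; with the
#'   default bounds a capped step already exceeds the whole clamp range).
#' @return An object of class `response_window_state`.
#' @export
response_window_state <- function(window_ms = 1500, step_down_ms = 10,
                                  step_up_ms = 40, min_ms = 200,
                                  max_ms = 5000, streak_scaling = TRUE,
                                  exponent_cap = 6L) {
  stopifnot(step_down_ms > 0, step_up_ms > 0, min_ms > 0, max_ms >= min_ms,
            window_ms >= min_ms, window_ms <= max_ms)
  structure(
    list(window_ms = window_ms, step_down_ms = step_down_ms,
         step_up_ms = step_up_ms, consec_correct = 0L, consec_lapse = 0L,
         min_ms = min_ms, max_ms = max_ms,
         streak_scaling = isTRUE(streak_scaling),
         exponent_cap = as.integer(exponent_cap)),
    class = "response_window_state")
}

#' Classify a response against the adaptive window
#'
#' `"green"` iff the response matches the correct answer and `rt_ms <=
#' window_ms`; `"yellow"` iff correct but slower than the window; `"red"`
#' otherwise. An omitted response (`NA`) on a response-required trial is
#' classified `"red"`; the battery defines no separate omission class for
#' adaptive tasks.
#'
#' @param response Response token(s); `NA` for an omission.
#' @param correct_answer Correct-answer token(s).
#' @param rt_ms Response time(s) in ms; `NA` for omissions.
#' @param window_ms Response window(s) in ms at presentation.
#' @return Character vector of feedback classes.
#' @export
classify_response <- function(response, correct_answer, rt_ms, window_ms) {
  if (any(!is.na(rt_ms) & rt_ms <= 0)) stop("rt_ms must be positive")
  if (any(window_ms <= 0)) stop("window_ms must be positive")
  correct <- !is.na(response) & response == correct_answer
  out <- ifelse(!correct, "red",
                ifelse(!is.na(rt_ms) & rt_ms <= window_ms, "green", "yellow"))
  out
}

#' Advance the response-window staircase by one trial
#'
#' Green shortens the window by `step_down_ms * 2^consec_correct` and
#' extends the correct streak; yellow or red lengthens it by
#' `step_up_ms * 2^consec_lapse` and extends the lapse streak ("incorrect
#' or late" share the increment rule). The updated window is clamped to
#' `[min_ms, max_ms]` without resetting streaks.
#'
#' @param state A `response_window_state`.
#' @param feedback One of `"green"`, `"yellow"`, `"red"`.
#' @return The updated `response_window_state`.
#' @export
update_window <- function(state, feedback) {
  stopifnot(inherits(state, "response_window_state"))
  feedback <- match.arg(feedback, FEEDBACK_CLASSES)
  if (feedback == "green") {
    expo <- if (state$streak_scaling)
      min(state$consec_correct, state$exponent_cap) else 0L
    state$window_ms <- state$window_ms - state$step_down_ms * 2^expo
    state$consec_correct <- state$consec_correct + 1L
    state$consec_lapse <- 0L
  } else {
    expo <- if (state$streak_scaling)
      min(state$consec_lapse, state$exponent_cap) else 0L
    state$window_ms <- state$window_ms + state$step_up_ms * 2^expo
    state$consec_lapse <- state$consec_lapse + 1L
    state$consec_correct <- 0L
  }
  state$window_ms <- min(max(state$window_ms, state$min_ms), state$max_ms)
  state
}

#' Run the adaptive staircase against a virtual respondent
#'
#' Drives [update_window()] for `n_trials` trials using responses drawn
#' from `rt_sampler`, a function of one argument `n` returning a data frame
#' with columns `rt_ms` (positive) and `correct` (logical). Responses are
#' drawn up front (the generative respondent does not condition on the
#' current window; the window only classifies timeliness), then the window
#' trajectory is threaded sequentially.
#'
#' @param rt_sampler Function `n -> data.frame(rt_ms, correct)`.
#' @param n_trials Number of trials, at least 1.
#' @param init Initial `response_window_state`.
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with one row per trial: `trial`, `window_ms` (at
#'   presentation), `rt_ms`, `correct`, `feedback`.
#' @export
run_staircase <- function(rt_sampler, n_trials,
                          init = response_window_state(), seed = NULL) {
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- rt_sampler(n_trials)
  if (any(is.na(draws$rt_ms)) || any(draws$rt_ms <= 0)) {
    stop("rt_sampler produced non-positive response times")
  }
  state <- init
  window <- numeric(n_trials)
  feedback <- character(n_trials)
  for (i in seq_len(n_trials)) {
    window[i] <- state$window_ms
    feedback[i] <- if (!draws$correct[i]) {
      "red"
    } else if (draws$rt_ms[i] <= state$window_ms) "green" else "yellow"
    state <- update_window(state, feedback[i])
  }
  data.frame(trial = seq_len(n_trials) - 1L, window_ms = window,
             rt_ms = draws$rt_ms, correct = draws$correct,
             feedback = feedback)
}

#' Stationary green rate of the staircase without streak scaling
#'
#' With streak scaling off the window performs a random walk stepping down
#' `step_down` on green and up `step_up` otherwise; zero drift at the
#' stationary point requires `p * step_down = (1 - p) * step_up`, so the
#' long-run green fraction for a respondent with a continuous RT
#' distribution is `step_up / (step_down + step_up)` (0.8 at the default
#' 10/40 steps).
#'
#' @param step_down,step_up Positive step factors in ms.
#' @return The equilibrium green-feedback rate.
#' @export
equilibrium_rate <- function(step_down, step_up) {
  if (step_down <= 0 || step_up <= 0) stop("step factors must be positive")
  step_up / (step_down + step_up)
}
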