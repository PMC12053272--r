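#' Trial- and score-level cleaning configuration
#'
#' Defaults mirror the battery's published cleaning cascade: anticipatory
#' responses faster than 200 ms, trials beyond 3 individual SDs of the
#' individual mean RT, task scores with fewer than 5 trials in any
#' condition or below-chance accuracy, and score outliers beyond +/-3
#' median absolute deviations of the task median.
#'
#' @param anticipatory_cutoff_ms Anticipation threshold in ms.
#' @param individual_sd_k SD multiplier for the per-participant RT trim.
#' @param min_trials_per_condition Minimum surviving trials per condition.
#' @param mad_k MAD multiplier for score outliers.
#' @param mad_scale_constant MAD consistency constant; 1.4826 makes the
#'   MAD estimate the SD under normality (set 1 for the raw-MAD reading).
#' @param rcs_denominator `"total_rt"` (correct responses per second of
#'   summed response time) or `"literal_product"` (divide additionally by
#'   the trial count; sensitivity reading of the metric's definition).
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(anticipatory_cutoff_ms = 200,
                            individual_sd_k = 3,
                            min_trials_per_condition = 5,
                            mad_k = 3, mad_scale_constant = 1.4826,
                            rcs_denominator = c("total_rt",
                                                "literal_product")) {
  stopifnot(anticipatory_cutoff_ms > 0, individual_sd_k > 0,
            min_trials_per_condition > 0, mad_k > 0,
            mad_scale_constant > 0)
  structure(list(anticipatory_cutoff_ms = anticipatory_cutoff_ms,
                 individual_sd_k = individual_sd_k,
                 min_trials_per_condition = min_trials_per_condition,
                 mad_k = mad_k, mad_scale_constant = mad_scale_constant,
                 rcs_denominator = match.arg(rcs_denominator)),
            class = "cleaning_config")
}

#' Trial-level cleaning: anticipations first, then the individual SD trim
#'
#' Stage 1 removes responded trials with `rt_ms` below the anticipatory
#' cutoff. Stage 2, computed per participant x task on the survivors of
#' stage 1, removes trials beyond `individual_sd_k` SDs of the individual
#' mean RT (a zero or undefined SD removes nothing). Span sequences and
#' unresponded trials are untouched. The stage order is fixed.
#'
#' @param records Trial-log data frame.
#' @param cfg A `cleaning_config`.
#' @return List with `records` (survivors), `removed` (dropped rows with a
#'   `removed_stage` column), and `tally` (counts per stage; conserved:
#'   `kept + removed == input`).
#' @export
clean_trials <- function(records, cfg = cleaning_config()) {
  n0 <- nrow(records)
  responded <- !is.na(records$rt_ms)
  stage1 <- responded & records$rt_ms < cfg$anticipatory_cutoff_ms
  r1 <- records[!stage1, , drop = FALSE]
  key <- interaction(r1$participant_id, r1$task, r1$session, drop = TRUE)
  mu <- tapply(r1$rt_ms, key, mean, na.rm = TRUE)
  sd_ <- tapply(r1$rt_ms, key, stats::sd, na.rm = TRUE)
  z_ok <- is.na(r1$rt_ms) | is.na(sd_[key]) | sd_[key] == 0 |
    abs(r1$rt_ms - mu[key]) <= cfg$individual_sd_k * sd_[key]
  stage2 <- !z_ok
  rm1 <- records[stage1, , drop = FALSE]
  rm1$removed_stage <- rep("anticipatory", nrow(rm1))
  rm2 <- r1[stage2, , drop = FALSE]
  rm2$removed_stage <- rep("individual_sd", nrow(rm2))
  removed <- rbind(rm1, rm2)
  kept <- r1[!stage2, , drop = FALSE]
  tally <- data.frame(stage = c("input", "anticipatory", "individual_sd",
                                "kept"),
                      n = c(n0, sum(stage1), sum(stage2), nrow(kept)))
  list(records = kept, removed = removed, tally = tally)
}

#' Score one participant's records on a task metric
#'
#' Rate correct score (RCS) is the number of correct responses per second
#' of total response time over responded trials - the average number of
#' correct responses per second (correct-but-late responses count as
#' correct; the metric text carries no timeliness qualifier). Mean correct
#' RT averages `rt_ms` over correctly answered trials (for tap-and-trace,
#' over the multitasking block only). Object span applies
#' [span_score()] to the sequence records.
#'
#' @param records Trial records of a single participant x task (x session).
#' @param metric_id One of `"rcs"`, `"mean_correct_rt"`, `"object_span"`.
#' @param cfg A `cleaning_config` (for the RCS denominator reading).
#' @return Numeric score, or `NA` if no scorable trial remains.
#' @export
score_task <- function(records, metric_id, cfg = cleaning_config()) {
  if (nrow(records) == 0) return(NA_real_)
  correct <- trial_correct(records)
  if (metric_id == "rcs") {
    responded <- !is.na(records$rt_ms)
    if (!any(responded)) return(NA_real_)
    total_rt_s <- sum(records$rt_ms[responded]) / 1000
    if (total_rt_s <= 0) return(NA_real_)
    rcs <- sum(correct & responded) / total_rt_s
    if (cfg$rcs_denominator == "literal_product") {
      rcs <- rcs / sum(responded)
    }
    rcs
  } else if (metric_id == "mean_correct_rt") {
    use <- correct & !is.na(records$rt_ms)
    if (records$task[1] == "tap_trace") use <- use & records$condition %in%
        c("dual_target", "dual_noresp")
    if (!any(use)) return(NA_real_)
    mean(records$rt_ms[use])
  } else if (metric_id == "object_span") {
    len <- as.integer(sub("^len", "", records$condition))
    span_score(list(length = len, success = correct))
  } else {
    stop("unknown metric ", metric_id)
  }
}

# Correctness of a trial record: answer matched, or a correctly withheld
# response on a no-go trial.
trial_correct <- function(records) {
  (!is.na(records$response) & records$response == records$answer) |
    (is.na(records$response) & records$answer == "noresp")
}

#' Score-level validity filter: minimum trials per condition and chance accuracy
#'
#' A participant's task score is dropped when any condition retains fewer
#' than `min_trials_per_condition` trials, or when overall accuracy is
#' strictly below chance for the task's response-option count. Go/no-go
#' tasks have no symmetric option count; there, "chance" is performance no
#' better than an always-respond or never-respond baseline (hit rate minus
#' false-alarm rate at or below zero drops the score).
#'
#' @param records Trial records of a single participant x task.
#' @param spec The task's `task_spec`.
#' @param cfg A `cleaning_config`.
#' @return List `keep` (logical) and `reason` (`NA` or the failed rule).
#' @export
validity_filter <- function(records, spec, cfg = cleaning_config()) {
  if (spec$metric_id == "object_span") {
    # span lengths are controller-determined, not design conditions, and
    # recall has no symmetric chance level
    return(list(keep = nrow(records) > 0, reason = NA_character_))
  }
  counts <- table(records$condition)
  expected <- unlist(lapply(spec$blocks, function(b) names(b$proportions)))
  if (any(!expected %in% names(counts)) ||
      any(counts[expected] < cfg$min_trials_per_condition)) {
    return(list(keep = FALSE, reason = "min_trials"))
  }
  correct <- trial_correct(records)
  if (isTRUE(spec$go_nogo)) {
    go <- records$answer == "go"
    hit <- if (any(go)) mean(correct[go]) else 0
    fa <- if (any(!go)) mean(!correct[!go]) else 0
    if (hit - fa <= 0) return(list(keep = FALSE, reason = "chance_accuracy"))
  } else if (!is.na(spec$n_options) && spec$n_options > 1) {
    if (mean(correct) < 1 / spec$n_options) {
      return(list(keep = FALSE, reason = "chance_accuracy"))
    }
  }
  list(keep = TRUE, reason = NA_character_)
}

#' MAD outlier filter on a column of task scores
#'
#' Drops scores beyond `mad_k` (scaled) median absolute deviations of the
#' median. A zero MAD removes nothing (flagged in the attribute
#' `mad_zero`).
#'
#' @param x Numeric scores (may contain `NA`).
#' @param cfg A `cleaning_config`.
#' @return Logical keep mask (same length as `x`; `NA` scores are kept as
#'   missing), with attribute `mad_zero`.
#' @export
mad_outlier_filter <- function(x, cfg = cleaning_config()) {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 non-missing scores")
  med <- stats::median(x[ok])
  mad_raw <- stats::median(abs(x[ok] - med))
  keep <- rep(TRUE, length(x))
  if (mad_raw == 0) {
    attr(keep, "mad_zero") <- TRUE
    return(keep)
  }
  keep[ok] <- abs(x[ok] - med) <=
    cfg$mad_k * mad_raw * cfg$mad_scale_constant
  attr(keep, "mad_zero") <- FALSE
  keep
}

#' Residualize a score column on the basic response-time covariate
#'
#' Simple least-squares regression of the score on the hand-appropriate
#' basic-RT mean; the residuals are exactly uncorrelated with the
#' covariate in-sample. A constant covariate degenerates to centering
#' (with a warning).
#'
#' @param score Numeric scores.
#' @param covariate Basic-RT covariate (same length).
#' @return Residual column (`NA` where either input is missing).
#' @export
residualize <- function(score, covariate) {
  stopifnot(length(score) == length(covariate))
  out <- rep(NA_real_, length(score))
  ok <- !is.na(score) & !is.na(covariate)
  if (sum(ok) < 3) return(out)
  if (stats::sd(covariate[ok]) == 0) {
    warning("constant covariate; returning centered scores")
    out[ok] <- score[ok] - mean(score[ok])
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, covariate[ok]), score[ok])
  out[ok] <- fit$residuals
  out
}

#' Orient a mean-correct-RT metric so that higher is better
#'
#' Mean correct response times are multiplied by -1 and divided by 100,
#' which also tempers extreme variance estimates downstream.
#'
#' @param x Mean correct RT in ms.
#' @return `-x / 100`.
#' @export
transform_rt_metric <- function(x) -x / 100

#' Bad-actor screening on participant metadata
#'
#' Any high-risk indicator (e.g. out-of-region location, shared IP,
#' disposable email) excludes the participant outright; four or more
#' moderate-risk indicators (demographic inconsistencies) also exclude.
#'
#' @param metadata Data frame with logical columns named `high_risk_*`
#'   and `moderate_risk_*`.
#' @return Data frame `participant_id`, `keep`, `reason`.
#' @export
screen_participants <- function(metadata) {
  hi_cols <- grep("^high_risk_", names(metadata), value = TRUE)
  mod_cols <- grep("^moderate_risk_", names(metadata), value = TRUE)
  if (length(hi_cols) + length(mod_cols) == 0) {
    stop("metadata carries no risk-flag columns")
  }
  n_hi <- if (length(hi_cols)) rowSums(metadata[hi_cols], na.rm = TRUE) else 0
  n_mod <- if (length(mod_cols)) rowSums(metadata[mod_cols], na.rm = TRUE) else 0
  keep <- n_hi == 0 & n_mod < 4
  reason <- ifelse(n_hi > 0, "high_risk",
                   ifelse(n_mod >= 4, "moderate_risk_count", NA_character_))
  data.frame(participant_id = metadata$participant_id, keep = keep,
             reason = reason, stringsAsFactors = FALSE)
}

#' Intraclass correlation between two assessment sessions
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC
#' (sessions are a random facet of a test-retest design), from the
#' two-way mean squares of the balanced participant x session table.
#' Qualitative class follows the 0.75 / 0.60 / 0.40 thresholds
#' (excellent / good / fair / poor). The p-value is the one-sided F test
#' of the between-participant against the residual mean square.
#'
#' @param session1,session2 Paired score vectors; pairs with any missing
#'   value are dropped.
#' @param variant `"ICC_A1"` (absolute agreement, default) or `"ICC_C1"`
#'   (consistency, ignores session mean shifts).
#' @return An `icc_result` list: `icc`, `model`, `f`, `df1`, `df2`, `p`,
#'   `class`, `n`.
#' @export
icc <- function(session1, session2, variant = c("ICC_A1", "ICC_C1")) {
  variant <- match.arg(variant)
  ok <- !is.na(session1) & !is.na(session2)
  x <- cbind(session1[ok], session2[ok])
  n <- nrow(x); k <- 2
  if (n < 3) stop("need at least 3 complete pairs")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  est <- if (variant == "ICC_A1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  f <- msr / mse
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  cls <- icc_class(est)
  structure(list(icc = est, model = variant, f = f, df1 = n - 1,
                 df2 = (n - 1) * (k - 1), p = p, class = cls, n = n),
            class = "icc_result")
}

#' Qualitative reliability class of an ICC estimate
#'
#' @param est ICC estimate.
#' @return `"excellent"` (> 0.75), `"good"` (0.60-0.74), `"fair"`
#'   (0.40-0.59), else `"poor"`.
#' @export
icc_class <- function(est) {
  if (est > 0.75) "excellent"
  else if (est >= 0.60) "good"
  else if (est >= 0.40) "fair"
  else "poor"
}

#' Build the cleaned, filtered, prepared score table from a trial log
#'
#' Runs the full scoring pipeline in the published stage order:
#' trial cleaning (anticipatory, then individual SD trim), task scoring,
#' the minimum-trials / chance-accuracy validity filter, the MAD score
#' outlier filter, orientation of mean-RT metrics (x -1/100), and
#' residualization of every scored metric on the hand-appropriate basic
#' response-time average. Basic RT itself enters only as the covariate.
#'
#' @param trials Trial-log data frame (one session).
#' @param battery Battery specification list.
#' @param cfg A `cleaning_config`.
#' @param dominant_hand Optional named vector (participant id ->
#'   `"right"`/`"left"`) for the dominant-hand covariate; defaults to
#'   right-handed.
#' @param residualize_scores Apply the basic-RT residualization (default
#'   `TRUE`).
#' @return A data frame (rows = participants, columns = the ten scored
#'   metrics; rownames = participant ids) with attributes `removal_log`
#'   (per-stage score removals), `trial_tally` (trial-level cleaning
#'   tally), and `raw` (pre-preparation scores).
#' @export
build_score_table <- function(trials, battery = default_battery(),
                              cfg = cleaning_config(),
                              dominant_hand = NULL,
                              residualize_scores = TRUE) {
  cleaned <- clean_trials(trials, cfg)
  rec <- cleaned$records
  ids <- sort(unique(trials$participant_id))
  tasks <- intersect(names(battery), unique(trials$task))
  scored_tasks <- setdiff(tasks, "basic_rt")
  raw <- matrix(NA_real_, length(ids), length(scored_tasks),
                dimnames = list(ids, scored_tasks))
  removal <- list()
  by_pt <- split(rec, list(rec$participant_id, rec$task), drop = TRUE)
  for (chunk in by_pt) {
    task <- chunk$task[1]
    if (!task %in% scored_tasks) next
    id <- chunk$participant_id[1]
    vf <- validity_filter(chunk, battery[[task]], cfg)
    if (!vf$keep) {
      removal[[length(removal) + 1]] <-
        data.frame(participant_id = id, task = task, stage = vf$reason)
      next
    }
    raw[id, task] <- score_task(chunk, battery[[task]]$metric_id, cfg)
  }
  # MAD outlier filter per task column
  for (task in scored_tasks) {
    x <- raw[, task]
    if (sum(!is.na(x)) < 3) next
    keep <- mad_outlier_filter(x, cfg)
    dropped <- which(!keep)
    for (i in dropped) {
      removal[[length(removal) + 1]] <-
        data.frame(participant_id = ids[i], task = task, stage = "mad_outlier")
    }
    raw[!keep, task] <- NA_real_
  }
  # preparation: orient RT metrics, then residualize on basic RT
  prepared <- raw
  for (task in scored_tasks) {
    if (battery[[task]]$metric_id == "mean_correct_rt") {
      prepared[, task] <- transform_rt_metric(prepared[, task])
    }
  }
  if (residualize_scores && "basic_rt" %in% tasks) {
    cov_tab <- basic_rt_covariates(rec, ids, dominant_hand)
    for (task in scored_tasks) {
      covariate <- if (battery[[task]]$rt_control == "two_hand") {
        cov_tab$two_hand
      } else {
        cov_tab$dominant
      }
      prepared[, task] <- residualize(prepared[, task], covariate)
    }
  }
  removal_log <- if (length(removal)) do.call(rbind, removal) else
    data.frame(participant_id = character(0), task = character(0),
               stage = character(0))
  structure(as.data.frame(prepared), removal_log = removal_log,
            trial_tally = cleaned$tally, raw = raw)
}

# Basic-RT covariates: overall two-hand mean across both blocks, and the
# dominant-hand block mean, per participant.
basic_rt_covariates <- function(records, ids, dominant_hand = NULL) {
  br <- records[records$task == "basic_rt" & !is.na(records$rt_ms), ,
                drop = FALSE]
  two_hand <- dominant <- rep(NA_real_, length(ids))
  names(two_hand) <- names(dominant) <- ids
  if (nrow(br)) {
    m_all <- tapply(br$rt_ms, br$participant_id, mean)
    two_hand[names(m_all)] <- m_all
    hand <- if (is.null(dominant_hand)) {
      stats::setNames(rep("right", length(ids)), ids)
    } else {
      dominant_hand
    }
    # blocks are named right/left; condition column holds "target", the
    # stimulus prefix carries the block
    blk <- sub("_.*$", "", br$stimulus)
    use <- blk == hand[br$participant_id]
    if (any(use)) {
      m_dom <- tapply(br$rt_ms[use], br$participant_id[use], mean)
      dominant[names(m_dom)] <- m_dom
    }
  }
  list(two_hand = two_hand, dominant = dominant)
}
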