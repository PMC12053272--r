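#' Load the trait-to-metric calibration
#'
#' Calibration constants map latent task abilities to trial-level behavior:
#' per-task lognormal RT location (`meanlog`, log-ms of the decision
#' component added to the participant's base time `t0`), per-condition
#' log-RT costs, per-condition accuracy offsets `b` on the logit scale,
#' the accuracy discrimination slope `a`, and the ability-to-speed slope
#' `beta` (higher ability shortens log RT). Defaults were chosen so that
#' simulated summary metrics land inside the response-time and accuracy
#' ranges reported across the comparable task literature (e.g. basic
#' response time in 231-518 ms).
#'
#' @param path YAML calibration file; defaults to the file shipped with
#'   the package.
#' @return Nested calibration list.
#' @export
default_calibration <- function(path = system.file("extdata",
                                                   "calibration.yaml",
                                                   package = "efbattery")) {
  yaml::read_yaml(path)
}

#' Planted sparse precision matrix with community structure
#'
#' Builds the inverse-covariance (precision) matrix of the latent ability
#' vector with unit diagonal, so off-diagonal partial correlations read
#' back exactly as `-K[i, j]`. Within each community the tasks are joined
#' in a ring at partial correlation `within_pc`; listed bridge edges get
#' `between_pc`; everything else is exactly zero.
#'
#' @param communities Named list of character vectors partitioning the
#'   task names into communities.
#' @param within_pc Partial correlation on within-community ring edges.
#' @param between_pc Partial correlation on bridge edges.
#' @param bridge_edges Two-column matrix (or list of pairs) of task names
#'   joining different communities.
#' @return Precision matrix `K` with `dimnames` set to the task names and
#'   attributes `communities` (integer labels) and `edges` (edge list).
#' @export
planted_precision <- function(communities, within_pc = 0.3,
                              between_pc = 0.15, bridge_edges = NULL) {
  tasks <- unlist(communities, use.names = FALSE)
  if (anyDuplicated(tasks)) stop("communities must partition the task list")
  p <- length(tasks)
  K <- diag(p)
  dimnames(K) <- list(tasks, tasks)
  ring <- function(members) {
    k <- length(members)
    if (k < 2) return(NULL)
    if (k == 2) return(cbind(members[1], members[2]))
    cbind(members, members[c(2:k, 1)])
  }
  edges <- do.call(rbind, lapply(communities, ring))
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      K[edges[r, 1], edges[r, 2]] <- K[edges[r, 2], edges[r, 1]] <- -within_pc
    }
  }
  if (!is.null(bridge_edges)) {
    bridge_edges <- do.call(rbind, lapply(seq_len(nrow(as.matrix(bridge_edges))),
                                          function(i) as.matrix(bridge_edges)[i, , drop = FALSE]))
    for (r in seq_len(nrow(bridge_edges))) {
      i <- bridge_edges[r, 1]; j <- bridge_edges[r, 2]
      K[i, j] <- K[j, i] <- -between_pc
    }
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("planted precision matrix is not positive definite ",
         "(smallest eigenvalue ", signif(min(ev), 4), ")")
  }
  member <- integer(p); names(member) <- tasks
  for (ci in seq_along(communities)) member[communities[[ci]]] <- ci
  attr(K, "communities") <- member
  attr(K, "edges") <- rbind(edges, bridge_edges)
  K
}

#' Construct a cohort model
#'
#' @param K Planted precision matrix from [planted_precision()].
#' @param mu_g Named list of per-group latent mean shifts (scalars, SD
#'   units) for groups `younger` and `older`.
#' @param s_g Named list of per-group latent scale multipliers.
#' @param r_tt Session-to-session latent stability in `[0, 1]`.
#' @param lambda_cv Comparator-battery attenuation in `[0, 1]`: the true
#'   concurrent correlation between a comparator score and the matching
#'   latent ability.
#' @return A `cohort_model` object.
#' @export
cohort_model <- function(K, mu_g = list(younger = 0, older = -0.4),
                         s_g = list(younger = 1, older = 0.8),
                         r_tt = 0.7, lambda_cv = 0.45) {
  stopifnot(all(unlist(s_g) > 0), r_tt >= 0, r_tt <= 1,
            lambda_cv >= 0, lambda_cv <= 1)
  Sigma0 <- stats::cov2cor(solve(K))
  structure(list(tasks = rownames(K), K = K, Sigma0 = Sigma0,
                 communities = attr(K, "communities"),
                 mu_g = mu_g, s_g = s_g, r_tt = r_tt,
                 lambda_cv = lambda_cv),
            class = "cohort_model")
}

#' The default cohort model behind the validation analyses
#'
#' Ten scored metrics in three planted communities: set reconfiguration
#' (forward/backward span, task switching), attentional control (the two
#' continuous performance tasks), and interference resolution (flanker,
#' Stroop, visual search, cueing, tap-and-trace). Ring edges within
#' communities at partial correlation 0.30 plus eight bridge edges at 0.15
#' give 17 nonzero edges on 10 nodes. The older group sits 0.4 SD lower
#' with scale 0.8 and identical edges, so the invariance ladder has a true
#' equal-edges/different-moments configuration to detect.
#'
#' @return A `cohort_model`.
#' @export
default_cohort_model <- function() {
  communities <- list(
    set_reconfiguration = c("span_fwd", "span_bwd", "taskswitch"),
    attentional_control = c("cpt_impulsive", "cpt_sustained"),
    interference_resolution = c("flanker", "stroop", "boxed", "compass",
                                "tap_trace"))
  bridges <- rbind(
    c("taskswitch", "cpt_sustained"),
    c("taskswitch", "stroop"),
    c("taskswitch", "boxed"),
    c("span_fwd", "flanker"),
    c("span_bwd", "compass"),
    c("cpt_impulsive", "tap_trace"),
    c("span_bwd", "stroop"),
    c("span_fwd", "tap_trace"))
  K <- planted_precision(communities, within_pc = 0.3, between_pc = 0.15,
                         bridge_edges = bridges)
  cohort_model(K)
}

#' Sample a cohort of virtual respondents
#'
#' Latent abilities are multivariate normal with the model's standardized
#' inverse-precision correlation structure, shifted and scaled per group.
#' Nuisance behavioral parameters (base RT, lognormal spread, lapse and
#' anticipation probabilities, span capacity) are drawn from calibrated
#' ranges. Screening flags are planted at low base rates so the bad-actor
#' rules have something to catch.
#'
#' @param model A `cohort_model`.
#' @param n Number of respondents.
#' @param group_split Proportion assigned to the `younger` group.
#' @param calib Calibration list.
#' @param seed Integer seed.
#' @return An `ef_cohort`: list with `participants` (metadata + risk
#'   flags), `eta` (n x 10 ability matrix), `nuisance` (behavioral
#'   parameters), and `model`.
#' @export
sample_cohort <- function(model, n, group_split = 0.5,
                          calib = default_calibration(), seed = 1L) {
  stopifnot(inherits(model, "cohort_model"), n >= 1)
  set.seed(seed)
  tasks <- model$tasks
  n_young <- round(n * group_split)
  group <- c(rep("younger", n_young), rep("older", n - n_young))
  eta <- MASS::mvrnorm(n, rep(0, length(tasks)), model$Sigma0)
  if (n == 1) eta <- matrix(eta, nrow = 1)
  colnames(eta) <- tasks
  for (g in unique(group)) {
    idx <- group == g
    eta[idx, ] <- eta[idx, , drop = FALSE] * model$s_g[[g]] + model$mu_g[[g]]
  }
  d <- calib$defaults
  age <- ifelse(group == "younger", sample(18:39, n, replace = TRUE),
                sample(40:75, n, replace = TRUE))
  flags <- data.frame(
    high_risk_location = stats::runif(n) < d$high_risk_rate,
    high_risk_ip = stats::runif(n) < d$high_risk_rate,
    high_risk_email = stats::runif(n) < d$high_risk_rate)
  for (m in 1:5) {
    flags[[paste0("moderate_risk_", m)]] <- stats::runif(n) < d$moderate_risk_rate
  }
  participants <- cbind(
    data.frame(participant_id = sprintf("P%05d", seq_len(n)),
               group = group, age = age,
               dominant_hand = ifelse(stats::runif(n) < 0.9, "right", "left"),
               stringsAsFactors = FALSE),
    flags)
  span_task <- if ("span_fwd" %in% tasks) "span_fwd" else tasks[1]
  nuisance <- data.frame(
    t0 = stats::runif(n, d$t0_range[1], d$t0_range[2]),
    sigma = stats::runif(n, d$sigma_range[1], d$sigma_range[2]),
    lapse = stats::runif(n, d$lapse_range[1], d$lapse_range[2]),
    anticipatory = stats::runif(n, d$anticipatory_range[1],
                                d$anticipatory_range[2]))
  nuisance$kappa <- d$kappa_mean + d$kappa_sd * eta[, span_task]
  structure(list(participants = participants, eta = eta,
                 nuisance = nuisance, model = model),
            class = "ef_cohort")
}

#' Extract one respondent profile from a cohort
#'
#' @param cohort An `ef_cohort`.
#' @param i Row index.
#' @param eta Optional ability matrix overriding the cohort's (repeat
#'   sessions).
#' @return Named list profile consumed by [administer_task()].
#' @export
cohort_profile <- function(cohort, i, eta = NULL) {
  if (is.null(eta)) eta <- cohort$eta
  list(participant_id = cohort$participants$participant_id[i],
       group = cohort$participants$group[i],
       dominant_hand = cohort$participants$dominant_hand[i],
       eta = eta[i, ], t0 = cohort$nuisance$t0[i],
       sigma = cohort$nuisance$sigma[i],
       lapse = cohort$nuisance$lapse[i],
       anticipatory = cohort$nuisance$anticipatory[i],
       kappa = cohort$nuisance$kappa[i])
}

#' Generative response model for one respondent on a set of trials
#'
#' With probability `anticipatory` the trial is an anticipation: a random
#' guess at a uniform 80-199 ms response time. Otherwise the response time
#' is `t0` plus a lognormal decision component whose log-location is the
#' task's calibrated `meanlog` plus the condition cost minus
#' `beta * eta_task`, and the response is correct with probability
#' `(1 - lapse) * plogis(a * eta_task + b_condition)`. On go/no-go
#' distractor trials a "correct" outcome is a withheld response (no RT).
#' The current response window does not enter the generative model; it
#' only classifies timeliness.
#'
#' @param profile Respondent profile (see [cohort_profile()]).
#' @param task_id Task identifier.
#' @param conditions Character vector of condition labels.
#' @param answers Answer tokens per trial (`"noresp"` marks withhold
#'   trials); defaults to response-required trials.
#' @param calib Calibration list.
#' @param seed Optional seed.
#' @param window_ms Unused by the generative model; accepted so callers
#'   can pass the presentation window through.
#' @return Data frame with `response`, `rt_ms`, `correct`.
#' @export
respond <- function(profile, task_id, conditions, answers = NULL,
                    calib = default_calibration(), seed = NULL,
                    window_ms = NULL) {
  as.data.frame(respond_cols(profile, task_id, conditions, answers, calib,
                             seed),
                stringsAsFactors = FALSE)
}

respond_cols <- function(profile, task_id, conditions, answers = NULL,
                         calib = default_calibration(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(conditions)
  if (is.null(answers)) answers <- rep("opt1", n)
  tc <- calib$tasks[[task_id]]
  if (is.null(tc)) stop("no response model calibrated for task ", task_id)
  uc <- unique(conditions)
  cost_u <- vapply(uc, function(cc) {
    v <- tc$cost[[cc]]; if (is.null(v)) 0 else v
  }, numeric(1))
  b_u <- vapply(uc, function(cc) {
    v <- tc$b[[cc]]; if (is.null(v)) calib$defaults$b_default else v
  }, numeric(1))
  ci <- match(conditions, uc)
  cost <- cost_u[ci]
  b <- b_u[ci]
  eta <- unname(profile$eta[task_id])
  if (is.na(eta)) eta <- 0
  meanlog <- tc$meanlog + cost - calib$defaults$beta * eta
  rt <- profile$t0 + stats::rlnorm(n, meanlog, profile$sigma)
  # a lapsed trial is a blind guess among the response options
  n_opt <- max(tc$n_options %||% 2, 2)
  p_correct <- (1 - profile$lapse) *
    stats::plogis(calib$defaults$a * eta + b) + profile$lapse / n_opt
  correct <- stats::runif(n) < p_correct
  antic <- stats::runif(n) < profile$anticipatory
  nogo <- answers == "noresp"
  rt[antic] <- stats::runif(sum(antic), 80, 199)
  correct[antic & !nogo] <- stats::runif(sum(antic & !nogo)) < 1 / n_opt
  correct[antic & nogo] <- FALSE
  response <- character(n)
  response[!nogo & correct] <- answers[!nogo & correct]
  response[!nogo & !correct] <- "wrong"
  response[nogo & correct] <- NA_character_
  response[nogo & !correct] <- "go"
  # omissions: a lapse on a response-required trial may be a non-response
  omit <- !nogo & !correct & !antic &
    stats::runif(n) < calib$defaults$omission_share
  response[omit] <- NA_character_
  rt[is.na(response)] <- NA_real_
  list(response = response, rt_ms = rt, correct = correct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Latent abilities across repeated sessions
#'
#' Session `s > 1` abilities follow an AR(1)-style stability model around
#' the group structure: `eta_s = r_tt * eta_1 + sqrt(1 - r_tt^2) * zeta`
#' with `zeta` drawn from the same latent covariance, so the latent
#' test-retest correlation is exactly `r_tt` and the marginal
#' distribution is preserved.
#'
#' @param cohort An `ef_cohort`.
#' @param k_sessions Number of sessions (>= 1).
#' @param r_tt Stability in `[0, 1]`; defaults to the cohort model's.
#' @param seed Integer seed.
#' @return List of ability matrices, one per session (session 1 is the
#'   cohort's own).
#' @export
session_abilities <- function(cohort, k_sessions, r_tt = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "ef_cohort"), k_sessions >= 1)
  if (is.null(r_tt)) r_tt <- cohort$model$r_tt
  if (r_tt < 0 || r_tt > 1) stop("r_tt must be in [0, 1]")
  set.seed(seed)
  model <- cohort$model
  group <- cohort$participants$group
  n <- nrow(cohort$eta)
  out <- vector("list", k_sessions)
  out[[1]] <- cohort$eta
  center <- scale_g <- numeric(n)
  for (g in unique(group)) {
    center[group == g] <- model$mu_g[[g]]
    scale_g[group == g] <- model$s_g[[g]]
  }
  for (s in seq_len(k_sessions)[-1]) {
    zeta <- MASS::mvrnorm(n, rep(0, ncol(cohort$eta)), model$Sigma0)
    if (n == 1) zeta <- matrix(zeta, nrow = 1)
    out[[s]] <- center + r_tt * (cohort$eta - center) +
      sqrt(1 - r_tt^2) * zeta * scale_g
  }
  out
}

#' Simulate repeated assessment sessions
#'
#' @param cohort An `ef_cohort`.
#' @param battery Battery to administer each session, or `NULL` to return
#'   only the per-session latent abilities (the zero-trial-noise limit).
#' @param k_sessions Number of sessions.
#' @param r_tt Latent stability; defaults to the cohort model's.
#' @param calib Calibration list.
#' @param seed Integer seed.
#' @return List with `abilities` (per-session matrices) and `trials`
#'   (per-session trial logs, `NULL` when `battery` is `NULL`).
#' @export
simulate_sessions <- function(cohort, battery = default_battery(),
                              k_sessions = 2, r_tt = NULL,
                              calib = default_calibration(), seed = 1L) {
  abilities <- session_abilities(cohort, k_sessions, r_tt,
                                 seed = child_seed(seed, "abilities"))
  trials <- NULL
  if (!is.null(battery)) {
    trials <- lapply(seq_len(k_sessions), function(s) {
      administer_battery(cohort, battery, calib,
                         seed = child_seed(seed, paste0("session", s)),
                         session = s, eta = abilities[[s]])
    })
  }
  list(abilities = abilities, trials = trials)
}

#' Comparator-battery scores with known concurrent validity
#'
#' Emulates a second, non-adaptive task suite sharing the latent traits:
#' the comparator score for task j is `lambda_cv * eta_j +
#' sqrt(1 - lambda_cv^2) * noise` with noise drawn from the same latent
#' covariance, so the population concurrent correlation per task is
#' `lambda_cv` by construction.
#'
#' @param cohort An `ef_cohort`.
#' @param lambda_cv Attenuation; defaults to the cohort model's.
#' @param seed Integer seed.
#' @return Matrix of comparator scores, columns `comparator_<task>`.
#' @export
comparator_battery <- function(cohort, lambda_cv = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "ef_cohort"))
  if (is.null(lambda_cv)) lambda_cv <- cohort$model$lambda_cv
  set.seed(seed)
  n <- nrow(cohort$eta)
  noise <- MASS::mvrnorm(n, rep(0, ncol(cohort$eta)), cohort$model$Sigma0)
  if (n == 1) noise <- matrix(noise, nrow = 1)
  group <- cohort$participants$group
  scale_g <- numeric(n)
  for (g in unique(group)) scale_g[group == g] <- cohort$model$s_g[[g]]
  center <- numeric(n)
  for (g in unique(group)) center[group == g] <- cohort$model$mu_g[[g]]
  comp <- lambda_cv * cohort$eta +
    sqrt(1 - lambda_cv^2) * (center + noise * scale_g)
  colnames(comp) <- paste0("comparator_", colnames(cohort$eta))
  comp
}
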