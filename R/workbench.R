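TRIAL_COLUMNS <- c("participant_id", "session", "task", "condition",
                   "trial", "stimulus", "answer", "response", "rt_ms",
                   "window_ms", "feedback")

#' Assemble a validation-study run configuration
#'
#' @param seed Run seed; fanned out deterministically per stage.
#' @param n_validation Size of the cross-sectional (network/CFA) arm.
#' @param n_retest Size of the two-session test-retest arm.
#' @param n_concurrent Subset of the validation arm also completing the
#'   comparator battery.
#' @param group_split Proportion of the validation arm in the younger
#'   group.
#' @param model Cohort model.
#' @param battery Battery specification.
#' @param calib Calibration list.
#' @param cleaning Cleaning configuration.
#' @param analyses Character vector of analysis toggles, any of
#'   `"icc"`, `"network"`, `"communities"`, `"bootstrap"`, `"cfa"`,
#'   `"invariance"`, `"concurrent"`.
#' @param n_boot Bootstrap resamples.
#' @param spinglass_reps Spinglass replications.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_validation = 600, n_retest = 250,
                       n_concurrent = 132, group_split = 0.5,
                       model = default_cohort_model(),
                       battery = default_battery(),
                       calib = default_calibration(),
                       cleaning = cleaning_config(),
                       analyses = c("icc", "network", "communities",
                                    "bootstrap", "cfa", "invariance",
                                    "concurrent"),
                       n_boot = 2500, spinglass_reps = 1000) {
  structure(list(seed = as.integer(seed), n_validation = n_validation,
                 n_retest = n_retest, n_concurrent = n_concurrent,
                 group_split = group_split, model = model,
                 battery = battery, calib = calib, cleaning = cleaning,
                 analyses = analyses, n_boot = n_boot,
                 spinglass_reps = spinglass_reps),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `seed`, `n_validation`, `n_retest`, `n_concurrent`,
#' `group_split`, `analyses`, `n_boot`, `spinglass_reps`, plus battery
#' overrides `battery: {task: {n_trials:, proportions:}}` applied to the
#' single-block tasks.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  battery <- default_battery()
  for (id in names(y$battery)) {
    ov <- y$battery[[id]]
    spec <- battery[[id]]
    if (is.null(spec)) stop("unknown task in config: ", id)
    if (length(spec$blocks) == 1 && !is.null(ov$n_trials)) {
      spec$blocks[[1]]$n_trials <- ov$n_trials
    }
    if (!is.null(ov$proportions)) {
      spec$blocks[[1]]$proportions <- unlist(ov$proportions)
    }
    battery[[id]] <- spec
  }
  args <- y[intersect(names(y), c("seed", "n_validation", "n_retest",
                                  "n_concurrent", "group_split",
                                  "analyses", "n_boot",
                                  "spinglass_reps"))]
  args$battery <- battery
  do.call(run_config, args)
}

#' Write / read a trial log in the pinned CSV format
#'
#' Columns exactly `participant_id, session, task, condition, trial,
#' stimulus, answer, response, rt_ms, window_ms, feedback`; empty field =
#' missing; UTF-8 with a header row. Round-trips preserve values to full
#' precision.
#'
#' @param trials Trial-log data frame.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(TRIAL_COLUMNS %in% names(trials)))
  utils::write.csv(format_num_df(trials[TRIAL_COLUMNS]), path,
                   row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' @rdname write_trials
#' @return `read_trials` returns the trial-log data frame.
#' @export
read_trials <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(TRIAL_COLUMNS, hdr)
  if (length(missing_cols)) {
    stop("trial log is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(participant_id = "character",
                                        session = "integer",
                                        task = "character",
                                        condition = "character",
                                        trial = "integer",
                                        stimulus = "character",
                                        answer = "character",
                                        response = "character",
                                        rt_ms = "numeric",
                                        window_ms = "numeric",
                                        feedback = "character"),
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(out))
  if (length(missing_cols)) {
    stop("trial log is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out
}

#' Write / read a score table in the pinned CSV format
#'
#' Wide format: `participant_id` column plus one numeric column per task
#' metric; empty field = missing.
#'
#' @param scores Data frame or matrix with participant ids as rownames.
#' @param path CSV path.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(participant_id = rownames(scores),
                   as.data.frame(scores), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
}

#' @rdname write_scores
#' @return `read_scores` returns a data frame with participant rownames.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!"participant_id" %in% names(df)) {
    stop("score table is missing column(s): participant_id")
  }
  rownames(df) <- df$participant_id
  df$participant_id <- NULL
  for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
  df
}

# Locale-independent, full-precision numeric formatting for CSV output.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        formatC(df[[j]], digits = 15, format = "g"))
    }
  }
  df
}

#' Run the validation study end to end at desk scale
#'
#' Simulates the test-retest and cross-sectional arms, administers the
#' battery, cleans and scores the trial logs, prepares scores
#' (orientation transform + basic-RT residualization), screens
#' participants, and runs the toggled analyses: per-task ICCs, the pruned
#' network with fit indices, spinglass communities, bootstrap edge
#' stability, correlated 3-factor and bifactor comparison, the multigroup
#' invariance ladder, and concurrent correlations against the comparator
#' battery.
#'
#' @param config A `run_config`.
#' @return A `report_bundle`: named list of result tables plus a
#'   `manifest` recording seeds, sizes, and schema versions.
#' @export
run_validation_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  bundle <- list()
  manifest <- list(schema = 1L, seed = seed,
                   package_version = as.character(utils::packageVersion("efbattery")),
                   n_validation = config$n_validation,
                   n_retest = config$n_retest,
                   n_concurrent = config$n_concurrent,
                   analyses = config$analyses)
  failures <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }

  # ---- test-retest arm
  if ("icc" %in% config$analyses) {
    bundle$icc <- run_stage("icc", {
      cohort_r <- sample_cohort(config$model, config$n_retest,
                                group_split = 1, calib = config$calib,
                                seed = child_seed(seed, "retest_cohort"))
      ses <- simulate_sessions(cohort_r, config$battery, k_sessions = 2,
                               calib = config$calib,
                               seed = child_seed(seed, "retest_sessions"))
      hand <- stats::setNames(cohort_r$participants$dominant_hand,
                              cohort_r$participants$participant_id)
      st <- lapply(ses$trials, build_score_table,
                   battery = config$battery, cfg = config$cleaning,
                   dominant_hand = hand)
      tasks <- colnames(st[[1]])
      do.call(rbind, lapply(tasks, function(tk) {
        r <- icc(st[[1]][, tk], st[[2]][, tk])
        data.frame(task = tk, icc = r$icc, p = r$p, class = r$class,
                   n = r$n, stringsAsFactors = FALSE)
      }))
    })
  }

  # ---- cross-sectional arm (always simulated and scored)
  scores <- NULL
  cohort_v <- NULL
  {
    cohort_v <- sample_cohort(config$model, config$n_validation,
                              group_split = config$group_split,
                              calib = config$calib,
                              seed = child_seed(seed, "validation_cohort"))
    screen <- screen_participants(cohort_v$participants)
    bundle$screening <- as.data.frame(table(reason = stats::na.omit(
      screen$reason)))
    trials <- administer_battery(
      cohort_v, config$battery, config$calib,
      seed = child_seed(seed, "validation_trials"))
    keep_ids <- screen$participant_id[screen$keep]
    trials <- trials[trials$participant_id %in% keep_ids, , drop = FALSE]
    hand <- stats::setNames(cohort_v$participants$dominant_hand,
                            cohort_v$participants$participant_id)
    scores <- build_score_table(trials, config$battery, config$cleaning,
                                dominant_hand = hand)
    bundle$scores <- scores
  }

  net <- NULL
  if ("network" %in% config$analyses && !is.null(scores)) {
    nets <- run_stage("network", {
      sat <- fit_saturated_ggm(scores)
      list(sat = sat, pruned = prune_and_refit(sat, alpha = 0.05))
    })
    net <- nets$pruned
    if (!is.null(net)) {
      pm <- edge_pvalues(nets$sat)
      up <- which(upper.tri(net$omega))
      rc <- arrayInd(up, dim(net$omega))
      bundle$network_edges <- data.frame(
        from = net$variables[rc[, 1]], to = net$variables[rc[, 2]],
        weight = net$omega[up], p = pm[up], retained = net$adj[up],
        stringsAsFactors = FALSE)
      fi <- fit_indices(net)
      bundle$network_fit <- as.data.frame(unclass(fi))
      bundle$centrality <- centrality(net)
    }
  }

  if ("communities" %in% config$analyses && !is.null(net)) {
    bundle$communities <- run_stage("communities", {
      part <- spinglass_communities(net, n_reps = config$spinglass_reps,
                                    seed = child_seed(seed, "spinglass"))
      data.frame(node = names(part$labels),
                 community = as.integer(part$labels),
                 frequency = part$frequency, n_reps = part$n_reps,
                 stringsAsFactors = FALSE)
    })
  }

  if ("bootstrap" %in% config$analyses && !is.null(scores)) {
    bundle$bootstrap <- run_stage("bootstrap", {
      bootstrap_edges(scores[stats::complete.cases(scores), , drop = FALSE],
                      n_boot = config$n_boot,
                      seed = child_seed(seed, "bootstrap"))
    })
  }

  if ("cfa" %in% config$analyses && !is.null(scores)) {
    cfa_res <- run_stage("cfa", {
      cc <- stats::complete.cases(scores)
      fit_c <- fit_cfa(scores[cc, ], model_type = "correlated",
                       seed = child_seed(seed, "cfa_c"))
      fit_b <- suppressWarnings(
        fit_cfa(scores[cc, ], model_type = "bifactor",
                seed = child_seed(seed, "cfa_b")))
      list(fit_c = fit_c, fit_b = fit_b)
    })
    if (!is.null(cfa_res)) {
      bundle$loadings <- data.frame(
        task = rownames(cfa_res$fit_c$loadings),
        round(cfa_res$fit_c$loadings, 4),
        bifactor = round(cfa_res$fit_b$loadings, 4),
        stringsAsFactors = FALSE)
      fits <- list(correlated_3factor = cfa_res$fit_c,
                   bifactor = cfa_res$fit_b)
      if (!is.null(net)) fits <- c(list(network = net), fits)
      bundle$model_comparison <- compare_models(fits)
      bundle$cfa_warnings <- data.frame(
        model = c("correlated_3factor", "bifactor"),
        warnings = c(paste(cfa_res$fit_c$warnings, collapse = "; "),
                     paste(cfa_res$fit_b$warnings, collapse = "; ")),
        stringsAsFactors = FALSE)
    }
  }

  if ("invariance" %in% config$analyses && !is.null(scores)) {
    bundle$invariance <- run_stage("invariance", {
      grp <- cohort_v$participants$group[
        match(rownames(scores), cohort_v$participants$participant_id)]
      inv <- multigroup_invariance(scores, grp)
      tab <- inv$table
      tab$preferred_lrt <- inv$preferred[["lrt"]] == tab$model
      tab$preferred_aic <- inv$preferred[["aic"]] == tab$model
      tab$preferred_bic <- inv$preferred[["bic"]] == tab$model
      tab
    })
  }

  if ("concurrent" %in% config$analyses && !is.null(scores)) {
    bundle$concurrent <- run_stage("concurrent", {
      ids <- utils::head(rownames(scores), config$n_concurrent)
      idx <- match(ids, cohort_v$participants$participant_id)
      sub <- list(participants = cohort_v$participants[idx, , drop = FALSE],
                  eta = cohort_v$eta[idx, , drop = FALSE],
                  nuisance = cohort_v$nuisance[idx, , drop = FALSE],
                  model = cohort_v$model)
      class(sub) <- "ef_cohort"
      comp <- comparator_battery(sub,
                                 seed = child_seed(seed, "comparator"))
      concurrent_correlations(scores[ids, , drop = FALSE], comp)
    })
  }

  manifest$failures <- failures
  bundle$manifest <- manifest
  structure(bundle, class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Tables go to CSV, the manifest to JSON; output is deterministic for a
#' given bundle (no timestamps), so two runs with the same seed produce
#' byte-identical bundles.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in setdiff(names(bundle), "manifest")) {
    obj <- bundle[[nm]]
    path <- file.path(dir, paste0(nm, ".csv"))
    if (is.data.frame(obj) || is.matrix(obj)) {
      df <- as.data.frame(obj)
      if (nm == "scores") {
        df <- cbind(participant_id = rownames(df), df)
      }
      utils::write.csv(format_num_df(df), path, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
      files <- c(files, path)
    }
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, mpath)
  invisible(files)
}
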