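# Independent reference implementations used as oracles. These re-derive
# the rules from their definitions and stay deliberately naive.

# Brute-force span controller: replay an outcome string against the
# written rules (start 3, range 3-9; advance after 2 consecutive
# successes, or after 3 successes at a length with at most 1 interleaved
# miss under the variant rule; terminate after 3 consecutive failures).
oracle_span_run <- function(outcomes, rule = "two_in_a_row") {
  len <- 3L
  lens <- integer(0); succ <- logical(0)
  run_succ <- 0L; run_fail <- 0L
  s_at <- 0L; f_at <- 0L
  terminated <- FALSE
  for (o in outcomes) {
    if (terminated) break
    lens <- c(lens, len); succ <- c(succ, o)
    if (o) {
      run_fail <- 0L
      run_succ <- run_succ + 1L
      s_at <- s_at + 1L
      if (rule == "two_in_a_row") {
        if (run_succ == 2L) {
          len <- min(len + 1L, 9L)
          run_succ <- 0L; s_at <- 0L; f_at <- 0L
        }
      } else {
        if (s_at == 3L && f_at <= 1L) {
          len <- min(len + 1L, 9L)
          run_succ <- 0L; s_at <- 0L; f_at <- 0L
        } else if (s_at == 3L) {
          s_at <- 0L; f_at <- 0L
        }
      }
    } else {
      run_succ <- 0L
      run_fail <- run_fail + 1L
      f_at <- f_at + 1L
      if (run_fail == 3L) terminated <- TRUE
    }
  }
  list(length = lens, success = succ, terminated = terminated,
       final_length = len)
}

# Object span by exhaustive scan over all consecutive pairs.
oracle_object_span <- function(lens) {
  if (length(lens) == 1) return(lens)
  best <- NA_integer_
  for (i in seq_len(length(lens) - 1)) {
    if (lens[i] == lens[i + 1]) best <- max(best, lens[i], na.rm = TRUE)
  }
  if (is.na(best)) max(lens) else best
}

# Partial correlation of columns i, j controlling all others, via the
# correlation of regression residuals (independent of matrix inversion).
oracle_partial_cor <- function(x, i, j) {
  others <- setdiff(seq_len(ncol(x)), c(i, j))
  if (length(others) == 0) return(stats::cor(x[, i], x[, j]))
  ri <- stats::lm.fit(cbind(1, x[, others, drop = FALSE]), x[, i])$residuals
  rj <- stats::lm.fit(cbind(1, x[, others, drop = FALSE]), x[, j])$residuals
  stats::cor(ri, rj)
}

# Brute-force weighted betweenness: enumerate all simple paths between
# each pair, keep the minimum-distance ones, and credit interior nodes
# fractionally. Distances are 1/|w|. Small graphs only.
oracle_betweenness <- function(w) {
  p <- ncol(w)
  dmat <- ifelse(w != 0, 1 / abs(w), Inf)
  paths_between <- function(a, b) {
    out <- list()
    recurse <- function(path, dist) {
      last <- path[length(path)]
      if (last == b) {
        out[[length(out) + 1]] <<- list(path = path, dist = dist)
        return()
      }
      for (nxt in seq_len(p)) {
        if (nxt %in% path || !is.finite(dmat[last, nxt])) next
        recurse(c(path, nxt), dist + dmat[last, nxt])
      }
    }
    recurse(a, 0)
    out
  }
  btw <- numeric(p)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      ps <- paths_between(a, b)
      if (length(ps) == 0) next
      dists <- vapply(ps, `[[`, numeric(1), "dist")
      mind <- min(dists)
      geo <- ps[abs(dists - mind) < 1e-12]
      inner <- table(unlist(lapply(geo, function(g) {
        setdiff(g$path, c(a, b))
      })))
      for (v in names(inner)) {
        btw[as.integer(v)] <- btw[as.integer(v)] +
          inner[[v]] / length(geo)
      }
    }
  }
  btw
}

# Two-way mean squares through stats::aov, as an independent route to the
# ICC variance components.
oracle_icc_a1 <- function(s1, s2) {
  n <- length(s1)
  d <- data.frame(y = c(s1, s2),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Small complete-data score matrix drawn straight from the planted latent
# structure (single group, unit scale).
eta_scores <- function(n, model = default_cohort_model(), seed = 1L) {
  co <- sample_cohort(model, n, group_split = 1, seed = seed)
  co$eta
}
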