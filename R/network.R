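# ---- multivariate-normal likelihood machinery --------------------------

# Casewise ("full information") log-likelihood of data under N(mu, Sigma),
# grouping rows by missingness pattern so each pattern costs one Cholesky.
fiml_loglik <- function(data, mu, Sigma) {
  x <- as.matrix(data)
  obs <- !is.na(x)
  pat <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  ll <- 0
  for (pp in unique(pat)) {
    rows <- which(pat == pp)
    o <- obs[rows[1], ]
    if (!any(o)) next
    xo <- x[rows, o, drop = FALSE]
    So <- Sigma[o, o, drop = FALSE]
    ch <- chol(So)
    ld <- 2 * sum(log(diag(ch)))
    ci <- chol2inv(ch)
    d <- sweep(xo, 2, mu[o])
    q <- rowSums((d %*% ci) * d)
    ll <- ll - 0.5 * sum(ncol(xo) * log(2 * pi) + ld + q)
  }
  ll
}

# EM algorithm for the MVN mean and covariance under missing-at-random
# data; returns the saturated FIML solution.
em_mvn <- function(data, tol = 1e-8, maxit = 500) {
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  Sigma <- diag(v, p)
  obs <- !is.na(x)
  pat <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p)
    for (rows in groups) {
      o <- obs[rows[1], ]
      m <- !o
      xo <- x[rows, o, drop = FALSE]
      if (!any(m)) {
        T1 <- T1 + colSums(x[rows, , drop = FALSE])
        T2 <- T2 + crossprod(x[rows, , drop = FALSE])
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      ci <- chol2inv(chol(Soo))
      B <- Sigma[m, o, drop = FALSE] %*% ci
      d <- sweep(xo, 2, mu[o])
      xm <- matrix(mu[m], nrow(xo), sum(m), byrow = TRUE) + d %*% t(B)
      C <- Sigma[m, m, drop = FALSE] -
        B %*% Sigma[o, m, drop = FALSE]
      xe <- matrix(0, nrow(xo), p)
      xe[, o] <- xo; xe[, m] <- xm
      T1 <- T1 + colSums(xe)
      T2 <- T2 + crossprod(xe)
      T2[m, m] <- T2[m, m] + nrow(xo) * C
    }
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- fiml_loglik(x, mu, Sigma)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iter = it)
}

# Exact MLE of a Gaussian graphical model with structural zeros in the
# concentration matrix (classical iterative conditional-regression
# algorithm). adj[i, j] = TRUE where the edge is free.
ggm_mle_pattern <- function(S, adj, tol = 1e-10, maxit = 500) {
  p <- ncol(S)
  W <- S
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      nbr <- idx[adj[j, idx]]
      if (length(nbr) > 0) {
        beta <- solve(W[nbr, nbr, drop = FALSE], S[nbr, j])
        w12 <- W[idx, nbr, drop = FALSE] %*% beta
      } else {
        w12 <- rep(0, p - 1)
      }
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) break
  }
  K <- chol2inv(chol(W))
  K[!adj & row(K) != col(K)] <- 0
  list(Sigma = W, K = K, iter = it)
}

# Partial-correlation matrix from a concentration matrix.
k_to_omega <- function(K) {
  om <- -stats::cov2cor(K)
  diag(om) <- 0
  om
}

# ---- saturated and pruned network models -------------------------------

#' Fit the saturated Gaussian graphical model
#'
#' Estimates the partial-correlation network of the score table. Under
#' complete data the solution is the analytic inverse of the ML
#' covariance, `omega_ij = -K_ij / sqrt(K_ii K_jj)`; under missing-at-
#' random data the mean and covariance maximize the casewise
#' multivariate-normal likelihood (EM), which reduces to the analytic
#' solution when nothing is missing. Scalings are the `Delta` of the
#' `Sigma = Delta (I - Omega)^-1 Delta` parametrization.
#'
#' @param data Matrix or data frame of scores (rows = participants).
#' @param missing `"auto"` (FIML when any value is missing), `"fiml"`, or
#'   `"listwise"`.
#' @return A `network_model`: `variables`, `omega`, `delta`, `mu`, `adj`
#'   (free-edge mask), `n`, `loglik`, `loglik_sat`, `loglik_baseline`,
#'   `df`, `n_params`, plus the sufficient statistics used.
#' @export
fit_saturated_ggm <- function(data, missing = c("auto", "fiml", "listwise")) {
  missing <- match.arg(missing)
  x <- as.matrix(data)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- ncol(x)
  if (p < 2) stop("need at least 2 variables")
  if (missing == "listwise") {
    x <- x[stats::complete.cases(x), , drop = FALSE]
  }
  has_na <- anyNA(x)
  n <- nrow(x)
  if (n <= p) stop("need n > p")
  if (missing == "fiml" || (has_na && missing == "auto")) {
    em <- em_mvn(x)
    mu <- em$mu; Sigma <- em$Sigma; ll <- em$loglik
  } else {
    mu <- colMeans(x)
    Sigma <- crossprod(sweep(x, 2, mu)) / n
    ll <- fiml_loglik(x, mu, Sigma)
  }
  sv <- svd(Sigma, nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-12) {
    cc <- abs(stats::cov2cor(Sigma)); diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("singular covariance; variables '", colnames(x)[worst[1]],
         "' and '", colnames(x)[worst[2]], "' are collinear")
  }
  K <- chol2inv(chol(Sigma))
  omega <- k_to_omega(K)
  delta <- 1 / sqrt(diag(K))
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  dimnames(omega) <- dimnames(adj) <- list(colnames(x), colnames(x))
  ll_base <- baseline_loglik(x)
  structure(list(variables = colnames(x), omega = omega, delta = delta,
                 mu = mu, adj = adj, n = n, loglik = ll, loglik_sat = ll,
                 loglik_baseline = ll_base,
                 n_params = 2 * p + p * (p - 1) / 2, df = 0L,
                 Sigma = Sigma, data = x, missing = missing,
                 pruned = FALSE),
            class = "network_model")
}

# Independence-model log-likelihood (diagonal covariance), the baseline
# for incremental fit indices; per-variable ML on observed cases.
baseline_loglik <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  v <- colMeans(sweep(x, 2, mu)^2, na.rm = TRUE)
  ll <- 0
  for (j in seq_len(ncol(x))) {
    xo <- x[!is.na(x[, j]), j]
    ll <- ll - 0.5 * sum(log(2 * pi * v[j]) + (xo - mu[j])^2 / v[j])
  }
  ll
}

#' Two-sided edge p-values of a fitted network
#'
#' Fisher-z approximation for a partial correlation controlling the other
#' p - 2 variables: `z = atanh(omega) * sqrt(n - (p - 2) - 3)`.
#'
#' @param model A `network_model`.
#' @return Symmetric matrix of two-sided p-values (diagonal `NA`).
#' @export
edge_pvalues <- function(model) {
  p <- length(model$variables)
  se_inv <- sqrt(model$n - (p - 2) - 3)
  z <- atanh(pmin(pmax(model$omega, -0.9999), 0.9999)) * se_inv
  pm <- 2 * stats::pnorm(-abs(z))
  diag(pm) <- NA
  pm
}

#' Prune non-significant edges and refit under the constraint
#'
#' Edges whose two-sided p-value exceeds `alpha` are fixed to exactly
#' zero and the model is refit by maximum likelihood under the structural
#' zeros (one-shot prune, matching the estimate-prune-refit narrative;
#' pass the result back in for an iterative variant). With complete data
#' the constrained MLE comes from the exact iterative conditional
#' algorithm; with missing data the casewise likelihood is optimized
#' directly.
#'
#' @param model A saturated `network_model`.
#' @param alpha Significance level (default 0.05).
#' @param pattern Optional logical adjacency: fit this fixed edge pattern
#'   instead of pruning by p-value (e.g. a known or pre-registered
#'   structure).
#' @return The pruned, refitted `network_model`; `$pruned_edges` counts
#'   the removals.
#' @export
prune_and_refit <- function(model, alpha = 0.05, pattern = NULL) {
  stopifnot(inherits(model, "network_model"))
  if (is.null(pattern)) {
    pm <- edge_pvalues(model)
    adj <- model$adj & !is.na(pm) & pm <= alpha
    adj <- adj & t(adj)
  } else {
    adj <- pattern | t(pattern)
    diag(adj) <- FALSE
  }
  fit_pruned_ggm(model, adj, alpha = alpha)
}

# Refit a network under a fixed free-edge mask.
fit_pruned_ggm <- function(model, adj, alpha = NA) {
  x <- model$data
  p <- ncol(x)
  n <- model$n
  if (!anyNA(x)) {
    mu <- colMeans(x)
    S <- crossprod(sweep(x, 2, mu)) / n
    fit <- ggm_mle_pattern(S, adj)
    Sigma <- fit$Sigma
    K <- fit$K
    ll <- fiml_loglik(x, mu, Sigma)
  } else {
    res <- fiml_pruned_optim(x, adj, model)
    mu <- res$mu; Sigma <- res$Sigma; ll <- res$loglik
    K <- chol2inv(chol(Sigma))
    K[!adj & row(K) != col(K)] <- 0
  }
  omega <- k_to_omega(K)
  dimnames(omega) <- dimnames(adj) <- list(model$variables, model$variables)
  e <- sum(adj[upper.tri(adj)])
  k_par <- 2 * p + e
  out <- model
  out$omega <- omega
  out$delta <- 1 / sqrt(diag(K))
  out$mu <- mu
  out$adj <- adj
  out$Sigma <- Sigma
  out$loglik <- ll
  out$n_params <- k_par
  out$df <- as.integer(p * (p - 1) / 2 - e)
  out$pruned <- TRUE
  out$alpha <- alpha
  out$pruned_edges <- as.integer(p * (p - 1) / 2 - e)
  out
}

# Direct casewise-likelihood optimization of a pruned network under
# missing data (Delta (I - Omega)^-1 Delta parametrization).
fiml_pruned_optim <- function(x, adj, model) {
  p <- ncol(x)
  epos <- which(adj & upper.tri(adj))
  om0 <- model$omega[epos]
  par0 <- c(om0, log(model$delta), model$mu)
  obj <- function(par) {
    Om <- matrix(0, p, p)
    Om[epos] <- par[seq_along(epos)]
    Om <- Om + t(Om)
    d <- exp(par[length(epos) + seq_len(p)])
    mu <- par[length(epos) + p + seq_len(p)]
    IeO <- diag(p) - Om
    if (min(eigen(IeO, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
      return(1e12)
    }
    Sigma <- diag(d) %*% solve(IeO) %*% diag(d)
    -2 * fiml_loglik(x, mu, Sigma)
  }
  o <- stats::optim(par0, obj, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-12))
  Om <- matrix(0, p, p); Om[epos] <- o$par[seq_along(epos)]; Om <- Om + t(Om)
  d <- exp(o$par[length(epos) + seq_len(p)])
  mu <- o$par[length(epos) + p + seq_len(p)]
  Sigma <- diag(d) %*% solve(diag(p) - Om) %*% diag(d)
  list(mu = mu, Sigma = Sigma, loglik = -o$value / 2)
}

# ---- fit indices -------------------------------------------------------

#' Model fit indices
#'
#' Chi-square is the likelihood ratio against the saturated model,
#' `2 (LL_sat - LL_model)`; CFI compares against the independence
#' baseline; RMSEA uses the `sqrt(max(chi2 - df, 0) / (df (n - 1)))` form
#' with a 90% CI from inverting the noncentral chi-square distribution;
#' AIC and BIC are `-2 LL + 2 k` and `-2 LL + k log n`.
#'
#' @param model A fitted `network_model` or `factor_model`.
#' @return A `fit_indices` list: `chi2`, `df`, `p`, `cfi`, `rmsea`,
#'   `rmsea_lo`, `rmsea_hi`, `aic`, `bic`, `n`, `n_params`.
#' @export
fit_indices <- function(model) {
  compute_fit_indices(
    loglik = model$loglik, loglik_sat = model$loglik_sat,
    loglik_baseline = model$loglik_baseline, df = model$df,
    df_baseline = model$df_baseline %||%
      (length(model$variables) * (length(model$variables) - 1) / 2),
    n = model$n, k = model$n_params)
}

compute_fit_indices <- function(loglik, loglik_sat, loglik_baseline, df,
                                df_baseline, n, k) {
  chi2 <- max(2 * (loglik_sat - loglik), 0)
  chi2_b <- max(2 * (loglik_sat - loglik_baseline), 0)
  p_val <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_baseline, chi2 - df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  if (df > 0) {
    rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
    ci <- rmsea_ci(chi2, df, n)
  } else {
    rmsea <- 0
    ci <- c(0, 0)
  }
  structure(list(chi2 = chi2, df = df, p = p_val, cfi = cfi,
                 rmsea = rmsea, rmsea_lo = ci[1], rmsea_hi = ci[2],
                 aic = -2 * loglik + 2 * k,
                 bic = -2 * loglik + k * log(n),
                 n = n, n_params = k),
            class = "fit_indices")
}

# 90% RMSEA CI: bracket the noncentrality parameter by bisection-backed
# root finding on the noncentral chi-square distribution function.
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  a <- (1 - level) / 2
  upper_ncp <- max(10 * chi2, 100)
  find_ncp <- function(target) {
    f <- function(ncp) stats::pchisq(chi2, df, ncp = ncp) - target
    if (f(0) < target - 1) return(0)
    if (f(0) <= 0) return(0)
    if (f(upper_ncp) > 0) return(upper_ncp)
    stats::uniroot(f, c(0, upper_ncp), tol = 1e-6)$root
  }
  lo_ncp <- if (stats::pchisq(chi2, df) < 1 - a) 0 else find_ncp(1 - a)
  hi_ncp <- if (stats::pchisq(chi2, df) < a) 0 else find_ncp(a)
  sqrt(pmax(c(lo_ncp, hi_ncp), 0) / (df * (n - 1)))
}

# ---- community detection ----------------------------------------------

#' Spinglass community detection on the pruned network
#'
#' Runs the spin-glass community search (the negative-weight extension,
#' which accommodates negative partial correlations) `n_reps` times with
#' distinct seeds, canonicalizes the partition labels, and returns the
#' modal partition with its selection frequency. Disconnected components
#' are partitioned separately; isolated nodes form their own communities.
#'
#' @param model A pruned `network_model`, or a bare (partial-correlation)
#'   weight matrix.
#' @param n_reps Number of replications (default 1000).
#' @param gamma Spin-glass resolution parameter.
#' @param spins Maximum number of spins (communities).
#' @param seed Integer seed.
#' @return A `partition` list: `labels` (named integer vector),
#'   `frequency` of the modal partition, `n_reps`, and the frequency
#'   `table` of all partitions seen.
#' @export
spinglass_communities <- function(model, n_reps = 1000, gamma = 1,
                                  spins = 10, seed = 1L) {
  if (is.matrix(model)) {
    vars <- rownames(model) %||% paste0("V", seq_len(ncol(model)))
    model <- list(omega = model, adj = model != 0, variables = vars)
  }
  om <- model$omega * ifelse(model$adj, 1, 0)
  om <- (om + t(om)) / 2  # remove floating-point asymmetry
  vars <- model$variables
  g <- igraph::graph_from_adjacency_matrix(om, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  reps <- character(n_reps)
  labs_list <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(child_seed(seed, paste0("spinglass", r)))
    labels <- integer(length(vars))
    offset <- 0L
    for (ci in seq_len(comp$no)) {
      nodes <- which(comp$membership == ci)
      if (length(nodes) == 1) {
        labels[nodes] <- offset + 1L
        offset <- offset + 1L
        next
      }
      sub <- igraph::induced_subgraph(g, nodes)
      cl <- igraph::cluster_spinglass(sub, weights = igraph::E(sub)$weight,
                                      spins = spins, gamma = gamma,
                                      implementation = "neg")
      mem <- igraph::membership(cl)
      labels[nodes] <- offset + as.integer(mem)
      offset <- offset + max(mem)
    }
    labels <- canonical_partition(labels)
    labs_list[[r]] <- labels
    reps[r] <- paste(labels, collapse = "-")
  }
  tab <- sort(table(reps), decreasing = TRUE)
  modal <- labs_list[[match(names(tab)[1], reps)]]
  names(modal) <- vars
  structure(list(labels = modal, frequency = as.numeric(tab[1]) / n_reps,
                 n_reps = n_reps, table = tab),
            class = "partition")
}

# ---- bootstrap, centrality, concurrent validity ------------------------

#' Bootstrap stability of pruned edge weights
#'
#' Case-resampling bootstrap of the full saturated-prune-refit pipeline.
#' Pruned-away edges contribute zeros, so the inclusion frequency reads
#' directly as edge stability.
#'
#' @param data Score table (rows = participants).
#' @param n_boot Number of resamples (default 2500).
#' @param alpha Pruning level.
#' @param seed Integer seed.
#' @return Data frame per upper-triangle edge: `from`, `to`, `estimate`
#'   (original pruned fit), `ci_lo`, `ci_hi` (95% percentile), and
#'   `inclusion` (fraction of resamples retaining the edge).
#' @export
bootstrap_edges <- function(data, n_boot = 2500, alpha = 0.05, seed = 1L) {
  x <- as.matrix(data)
  orig <- prune_and_refit(fit_saturated_ggm(x), alpha = alpha)
  p <- ncol(x)
  up <- which(upper.tri(orig$omega))
  boot <- matrix(0, n_boot, length(up))
  set.seed(child_seed(seed, "bootstrap"))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    fit <- tryCatch(
      prune_and_refit(fit_saturated_ggm(x[idx, , drop = FALSE]),
                      alpha = alpha),
      error = function(e) NULL)
    if (!is.null(fit)) boot[b, ] <- fit$omega[up]
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  rc <- arrayInd(up, dim(orig$omega))
  data.frame(from = orig$variables[rc[, 1]], to = orig$variables[rc[, 2]],
             estimate = orig$omega[up], ci_lo = ci[1, ], ci_hi = ci[2, ],
             inclusion = colMeans(boot != 0),
             stringsAsFactors = FALSE)
}

#' Node centrality of a pruned network
#'
#' Strength is the sum of absolute edge weights, expected influence the
#' signed sum; closeness and betweenness are computed on distances
#' `1 / |omega_ij|`.
#'
#' @param model A `network_model`.
#' @return Data frame per node: `strength`, `expected_influence`,
#'   `closeness`, `betweenness`.
#' @export
centrality <- function(model) {
  om <- model$omega * ifelse(model$adj, 1, 0)
  om <- (om + t(om)) / 2
  strength <- rowSums(abs(om))
  ei <- rowSums(om)
  g <- igraph::graph_from_adjacency_matrix(abs(om), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  w <- 1 / igraph::E(g)$weight
  clo <- suppressWarnings(igraph::closeness(g, weights = w))
  btw <- igraph::betweenness(g, weights = w)
  data.frame(node = model$variables, strength = strength,
             expected_influence = ei, closeness = as.numeric(clo),
             betweenness = as.numeric(btw), stringsAsFactors = FALSE)
}

#' Concurrent-validity correlations between two score tables
#'
#' Pairwise-complete Pearson correlations between mapped task pairs, with
#' two-sided p-values and the conventional 0.10 / 0.30 / 0.50 effect-size
#' labels (small / moderate / large).
#'
#' @param table_a,table_b Score tables with participants in matching rows.
#' @param pairing Optional data frame with columns `a`, `b` naming the
#'   column pairs; by default columns are matched by name after stripping
#'   a `comparator_` prefix from `table_b`.
#' @return Data frame: `task_a`, `task_b`, `r`, `n`, `p`, `label`.
#' @export
concurrent_correlations <- function(table_a, table_b, pairing = NULL) {
  a <- as.matrix(table_a); b <- as.matrix(table_b)
  if (is.null(pairing)) {
    bt <- sub("^comparator_", "", colnames(b))
    shared <- intersect(colnames(a), bt)
    pairing <- data.frame(a = shared, b = colnames(b)[match(shared, bt)],
                          stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(pairing)), function(i) {
    xa <- a[, pairing$a[i]]; xb <- b[, pairing$b[i]]
    ok <- !is.na(xa) & !is.na(xb)
    if (sum(ok) < 3) stop("need at least 3 complete pairs for ",
                          pairing$a[i])
    ct <- stats::cor.test(xa[ok], xb[ok])
    data.frame(task_a = pairing$a[i], task_b = pairing$b[i],
               r = unname(ct$estimate), n = sum(ok), p = ct$p.value,
               label = effect_label(unname(ct$estimate)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

effect_label <- function(r) {
  ar <- abs(r)
  if (ar >= 0.5) "large" else if (ar >= 0.3) "moderate"
  else if (ar >= 0.1) "small" else "negligible"
}

# ---- multigroup invariance ---------------------------------------------

#' Multigroup network invariance ladder
#'
#' Fits four nested models over the groups on a shared pruned sparsity
#' pattern: unconstrained (all parameters per group), equal edge weights,
#' equal edges + equal means, and equal edges + means + scalings. Adjacent
#' models are compared by chi-square likelihood-ratio tests with df equal
#' to the difference in free parameters, and all models by AIC/BIC; the
#' preferred model is reported separately per criterion.
#'
#' @param data Score table.
#' @param groups Group label per row (2+ groups, each with n > p).
#' @param alpha Pruning level for the shared pattern (estimated on the
#'   pooled within-group covariance).
#' @param pattern Optional logical adjacency to use instead of pruning.
#' @return An `invariance_ladder`: `table` (one row per model with fit
#'   indices and the LRT against the previous model), `preferred`
#'   (per-criterion verdicts), `pattern`, and the fitted parameter lists.
#' @export
multigroup_invariance <- function(data, groups, alpha = 0.05,
                                  pattern = NULL) {
  x <- as.matrix(data)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  groups <- groups[stats::complete.cases(as.matrix(data))]
  gl <- sort(unique(groups))
  G <- length(gl)
  p <- ncol(x)
  stats_g <- lapply(gl, function(g) {
    xg <- x[groups == g, , drop = FALSE]
    if (nrow(xg) <= p) stop("group '", g, "' has n <= p")
    list(n = nrow(xg), xbar = colMeans(xg),
         S = crossprod(sweep(xg, 2, colMeans(xg))) / nrow(xg))
  })
  names(stats_g) <- gl
  n_tot <- sum(vapply(stats_g, `[[`, numeric(1), "n"))
  if (is.null(pattern)) {
    Sp <- Reduce(`+`, lapply(stats_g, function(s) s$n * s$S)) / n_tot
    Kp <- chol2inv(chol(Sp))
    omp <- k_to_omega(Kp)
    zp <- atanh(omp) * sqrt(n_tot - (p - 2) - 3)
    pattern <- 2 * stats::pnorm(-abs(zp)) <= alpha
    diag(pattern) <- FALSE
    pattern <- pattern & t(pattern)
  }
  e <- sum(pattern[upper.tri(pattern)])
  epos <- which(pattern & upper.tri(pattern))
  # saturated multigroup log-likelihood (per-group saturated)
  ll_sat <- sum(vapply(stats_g, function(s) {
    mvn_n2ll(s$S, s$xbar, s$n, s$S, s$xbar)
  }, numeric(1))) / -2
  fits <- list(
    unconstrained = fit_mg_unconstrained(stats_g, pattern),
    equal_edges = fit_mg_constrained(stats_g, epos, p, eq_means = FALSE,
                                     eq_scalings = FALSE),
    equal_edges_means = fit_mg_constrained(stats_g, epos, p,
                                           eq_means = TRUE,
                                           eq_scalings = FALSE),
    equal_all = fit_mg_equal_all(stats_g, pattern))
  k_par <- c(G * (e + 2 * p), e + G * 2 * p, e + G * p + p, e + 2 * p)
  moments <- G * (p + p * (p + 1) / 2)
  rows <- list()
  prev <- NULL
  for (i in seq_along(fits)) {
    ll <- fits[[i]]$loglik
    chi2 <- 2 * (ll_sat - ll)
    df <- moments - k_par[i]
    rows[[i]] <- data.frame(
      model = names(fits)[i], chi2 = chi2, df = df,
      p = stats::pchisq(chi2, df, lower.tail = FALSE),
      delta_chi2 = if (is.null(prev)) NA_real_ else chi2 - prev$chi2,
      delta_df = if (is.null(prev)) NA_integer_ else df - prev$df,
      lrt_p = if (is.null(prev)) NA_real_ else
        stats::pchisq(chi2 - prev$chi2, df - prev$df, lower.tail = FALSE),
      aic = -2 * ll + 2 * k_par[i],
      bic = -2 * ll + k_par[i] * log(n_tot),
      stringsAsFactors = FALSE)
    prev <- rows[[i]]
  }
  tab <- do.call(rbind, rows)
  lrt_pref <- tab$model[1]
  for (i in 2:nrow(tab)) {
    if (!is.na(tab$lrt_p[i]) && tab$lrt_p[i] >= 0.05) {
      lrt_pref <- tab$model[i]
    } else {
      break
    }
  }
  preferred <- c(lrt = lrt_pref,
                 aic = tab$model[which.min(tab$aic)],
                 bic = tab$model[which.min(tab$bic)])
  structure(list(table = tab, preferred = preferred, pattern = pattern,
                 fits = fits, groups = gl, n = n_tot),
            class = "invariance_ladder")
}

# -2 log-likelihood of one group's sufficient statistics.
mvn_n2ll <- function(S, xbar, n, Sigma, mu) {
  p <- ncol(S)
  ch <- chol(Sigma)
  ld <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  d <- xbar - mu
  n * (p * log(2 * pi) + ld + sum(Sinv * S) + drop(t(d) %*% Sinv %*% d))
}

fit_mg_unconstrained <- function(stats_g, pattern) {
  fits <- lapply(stats_g, function(s) {
    f <- ggm_mle_pattern(s$S, pattern)
    list(Sigma = f$Sigma, mu = s$xbar,
         n2ll = mvn_n2ll(s$S, s$xbar, s$n, f$Sigma, s$xbar))
  })
  list(loglik = -sum(vapply(fits, `[[`, numeric(1), "n2ll")) / 2,
       groups = fits)
}

fit_mg_equal_all <- function(stats_g, pattern) {
  n_tot <- sum(vapply(stats_g, `[[`, numeric(1), "n"))
  xbar <- Reduce(`+`, lapply(stats_g, function(s) s$n * s$xbar)) / n_tot
  Sp <- Reduce(`+`, lapply(stats_g, function(s) {
    s$n * (s$S + tcrossprod(s$xbar - xbar))
  })) / n_tot
  f <- ggm_mle_pattern(Sp, pattern)
  n2ll <- sum(vapply(stats_g, function(s) {
    mvn_n2ll(s$S, s$xbar, s$n, f$Sigma, xbar)
  }, numeric(1)))
  list(loglik = -n2ll / 2, Sigma = f$Sigma, mu = xbar)
}

# Constrained multigroup fit: shared edge weights, optionally shared
# means; scalings always per group here (the fully constrained model has
# its own exact solution). BFGS with analytic gradients on the
# Delta (I - Omega)^-1 Delta parametrization.
fit_mg_constrained <- function(stats_g, epos, p, eq_means, eq_scalings) {
  G <- length(stats_g)
  e <- length(epos)
  # starting values from the pooled fit
  n_tot <- sum(vapply(stats_g, `[[`, numeric(1), "n"))
  Sp <- Reduce(`+`, lapply(stats_g, function(s) s$n * s$S)) / n_tot
  pattern <- matrix(FALSE, p, p); pattern[epos] <- TRUE
  pattern <- pattern | t(pattern)
  f0 <- ggm_mle_pattern(Sp, pattern)
  om0 <- k_to_omega(f0$K)[epos]
  d0 <- log(1 / sqrt(diag(f0$K)))
  par0 <- c(om0, rep(d0, G))
  if (eq_means) {
    par0 <- c(par0, Reduce(`+`, lapply(stats_g, function(s) {
      s$n * s$xbar
    })) / n_tot)
  }
  unpack <- function(par) {
    om <- par[seq_len(e)]
    ds <- lapply(seq_len(G), function(g) exp(par[e + (g - 1) * p + seq_len(p)]))
    mu <- if (eq_means) par[e + G * p + seq_len(p)] else NULL
    list(om = om, ds = ds, mu = mu)
  }
  sigma_of <- function(om, d) {
    Om <- matrix(0, p, p); Om[epos] <- om; Om <- Om + t(Om)
    IeO <- diag(p) - Om
    ev <- eigen(IeO, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) return(NULL)
    Si <- solve(IeO)
    list(Sigma = diag(d) %*% Si %*% diag(d), Si = Si)
  }
  obj <- function(par) {
    u <- unpack(par)
    tot <- 0
    for (g in seq_len(G)) {
      s <- stats_g[[g]]
      ms <- sigma_of(u$om, u$ds[[g]])
      if (is.null(ms)) return(1e12)
      mu_g <- if (eq_means) u$mu else s$xbar
      tot <- tot + mvn_n2ll(s$S, s$xbar, s$n, ms$Sigma, mu_g)
    }
    tot
  }
  grd <- function(par) {
    u <- unpack(par)
    g_om <- numeric(e)
    g_d <- vector("list", G)
    g_mu <- numeric(p)
    for (g in seq_len(G)) {
      s <- stats_g[[g]]
      d <- u$ds[[g]]
      ms <- sigma_of(u$om, d)
      if (is.null(ms)) {
        return(rep(0, length(par)))
      }
      ch <- chol(ms$Sigma)
      Sinv <- chol2inv(ch)
      mu_g <- if (eq_means) u$mu else s$xbar
      dd <- s$xbar - mu_g
      Sstar <- s$S + tcrossprod(dd)
      Gm <- s$n * (Sinv - Sinv %*% Sstar %*% Sinv)
      D <- diag(d)
      A <- ms$Si %*% D %*% Gm %*% D %*% ms$Si
      g_om <- g_om + 2 * A[epos]
      B <- ms$Si %*% D %*% Gm
      g_d[[g]] <- 2 * diag(B) * d
      if (eq_means) g_mu <- g_mu - 2 * s$n * drop(Sinv %*% dd)
    }
    out <- c(g_om, unlist(g_d))
    if (eq_means) out <- c(out, g_mu)
    out
  }
  o <- stats::optim(par0, obj, grd, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  u <- unpack(o$par)
  list(loglik = -o$value / 2, omega_shared = u$om, deltas = u$ds,
       mu = u$mu, convergence = o$convergence)
}
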