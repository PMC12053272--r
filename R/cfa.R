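#' Default factor pattern of the three planted communities
#'
#' Set reconfiguration (forward/backward span, task switching),
#' attentional control (both continuous performance tasks), and
#' interference resolution (flanker, Stroop, visual search, cueing,
#' tap-and-trace).
#'
#' @return Named list mapping factor names to indicator variables.
#' @export
default_ef_pattern <- function() {
  list(set_reconfiguration = c("span_fwd", "span_bwd", "taskswitch"),
       attentional_control = c("cpt_impulsive", "cpt_sustained"),
       interference_resolution = c("flanker", "stroop", "boxed", "compass",
                                   "tap_trace"))
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' `model_type = "correlated"` fits the correlated-factors model (each
#' variable loads on exactly one factor; factor correlations free);
#' `"bifactor"` adds a general factor on every variable with the specific
#' factors mutually orthogonal and orthogonal to the general factor.
#' Identification is by unit factor variance. The ML discrepancy is
#' minimized by BFGS with analytic gradients; on non-convergence up to
#' `n_restarts` jittered restarts are attempted and the best iterate is
#' returned with its status (never an exception). Residual variances are
#' unbounded by default so improper (Heywood) solutions remain observable
#' and raise a warning naming the offending variable; `bound_theta`
#' constrains them positive instead.
#'
#' @param data Score table (rows = participants); means are saturated, so
#'   the covariance structure carries the model.
#' @param pattern Named list factor -> indicator names covering all
#'   columns; see [default_ef_pattern()].
#' @param model_type `"correlated"` or `"bifactor"`.
#' @param n_restarts Random restarts on non-convergence.
#' @param bound_theta Log-parametrize residual variances (no Heywood
#'   cases possible).
#' @param seed Seed for restart jitter.
#' @return A `factor_model`: standardized `loadings` (variables x
#'   factors), `phi` (factor correlations), `theta` (residual variances,
#'   standardized), `loadings_raw`, `theta_raw`, `converged`, `warnings`,
#'   `loglik`, `df`, `n_params`, plus saturated/baseline log-likelihoods
#'   for [fit_indices()].
#' @export
fit_cfa <- function(data, pattern = default_ef_pattern(),
                    model_type = c("correlated", "bifactor"),
                    n_restarts = 10, bound_theta = FALSE, seed = 1L) {
  model_type <- match.arg(model_type)
  x <- as.matrix(data)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  vars <- colnames(x)
  miss <- setdiff(vars, unlist(pattern))
  if (length(miss)) stop("pattern does not cover: ",
                         paste(miss, collapse = ", "))
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  S <- crossprod(sweep(x, 2, mu)) / n
  fac_names <- names(pattern)
  fac_of <- integer(p); names(fac_of) <- vars
  for (f in seq_along(pattern)) fac_of[pattern[[f]]] <- f
  nf <- length(pattern)

  if (model_type == "correlated") {
    load_idx <- cbind(seq_len(p), fac_of[vars])
    nphi <- nf * (nf - 1) / 2
    phi_idx <- which(upper.tri(diag(nf)))
    n_load <- p
  } else {
    # column 1 = general factor, then the specific factors
    load_idx <- rbind(cbind(seq_len(p), 1L),
                      cbind(seq_len(p), 1L + fac_of[vars]))
    nphi <- 0
    phi_idx <- integer(0)
    n_load <- 2 * p
    nf <- nf + 1
  }
  k_par <- n_load + nphi + p
  npar <- k_par

  unpack <- function(par) {
    L <- matrix(0, p, nf)
    L[load_idx] <- par[seq_len(n_load)]
    Phi <- diag(nf)
    if (nphi > 0) {
      Phi[phi_idx] <- par[n_load + seq_len(nphi)]
      Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    }
    th <- par[n_load + nphi + seq_len(p)]
    if (bound_theta) th <- exp(th)
    list(L = L, Phi = Phi, theta = th)
  }
  obj <- function(par) {
    u <- unpack(par)
    Sg <- u$L %*% u$Phi %*% t(u$L) + diag(u$theta, p)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S)
  }
  grd <- function(par) {
    u <- unpack(par)
    Sg <- u$L %*% u$Phi %*% t(u$L) + diag(u$theta, p)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, npar))
    Sinv <- chol2inv(ch)
    G <- Sinv - Sinv %*% S %*% Sinv      # d F / d Sigma
    LP <- u$L %*% u$Phi
    gL <- 2 * (G %*% LP)
    g_load <- gL[load_idx]
    g_phi <- if (nphi > 0) {
      M <- t(u$L) %*% G %*% u$L
      2 * M[phi_idx]
    } else {
      numeric(0)
    }
    g_th <- diag(G)
    if (bound_theta) g_th <- g_th * u$theta
    c(g_load, g_phi, g_th)
  }

  start0 <- c(rep(0.5, n_load), rep(0.3, nphi),
              if (bound_theta) rep(log(0.5), p) else rep(0.5, p))
  set.seed(seed)
  best <- NULL
  for (r in 0:n_restarts) {
    st <- if (r == 0) start0 else start0 + stats::rnorm(npar, 0, 0.15)
    o <- stats::optim(st, obj, grd, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
    if (best$convergence == 0 && r >= 0 && best$value < 1e9) break
  }
  u <- unpack(best$par)
  Sg <- u$L %*% u$Phi %*% t(u$L) + diag(u$theta, p)
  warnings <- character(0)
  if (best$convergence != 0 || best$value >= 1e9) {
    warnings <- c(warnings, "non-convergence: last iterate returned")
  }
  if (any(u$theta < 0)) {
    bad <- vars[u$theta < 0]
    msg <- paste0("Heywood case: negative residual variance for ",
                  paste(bad, collapse = ", "))
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  }
  # sign convention: flip factors so the mean loading is positive
  for (f in seq_len(nf)) {
    nz <- u$L[, f] != 0
    if (any(nz) && sum(u$L[nz, f]) < 0) {
      u$L[, f] <- -u$L[, f]
      if (nphi > 0) {
        u$Phi[f, -f] <- -u$Phi[f, -f]
        u$Phi[-f, f] <- -u$Phi[-f, f]
      }
    }
  }
  sd_hat <- sqrt(diag(Sg))
  L_std <- u$L / sd_hat
  theta_std <- u$theta / diag(Sg)
  colnames(L_std) <- colnames(u$L) <-
    if (model_type == "bifactor") c("general", fac_names) else fac_names
  rownames(L_std) <- rownames(u$L) <- vars
  dimnames(u$Phi) <- list(colnames(L_std), colnames(L_std))
  ll <- -n / 2 * (p * log(2 * pi) + as.numeric(determinant(Sg)$modulus) +
                    sum(chol2inv(chol(Sg)) * S))
  ll_sat <- fiml_loglik(x, mu, S)
  ll_base <- baseline_loglik(x)
  moments <- p * (p + 1) / 2
  structure(list(variables = vars, model_type = model_type,
                 loadings = L_std, phi = u$Phi, theta = theta_std,
                 loadings_raw = u$L, theta_raw = u$theta,
                 implied = Sg, converged = best$convergence == 0,
                 warnings = warnings,
                 loglik = ll, loglik_sat = ll_sat,
                 loglik_baseline = ll_base,
                 n = n, n_params = k_par + p,  # + saturated means
                 df = as.integer(moments - k_par),
                 df_baseline = p * (p - 1) / 2),
            class = "factor_model")
}

#' Compare fitted structural models on one dataset
#'
#' @param fits Named list of fitted models (`network_model` or
#'   `factor_model`) fit to the same data.
#' @return Data frame with one row per model: `chi2`, `df`, `p`, `cfi`,
#'   `rmsea` (with CI bounds), `aic`, `bic`, and `best_*` flags marking
#'   the winner per criterion (lower chi2/rmsea/aic/bic, higher cfi).
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    warning("models were fit on different numbers of rows")
  }
  rows <- lapply(names(fits), function(nm) {
    fi <- fit_indices(fits[[nm]])
    data.frame(model = nm, chi2 = fi$chi2, df = fi$df, p = fi$p,
               cfi = fi$cfi, rmsea = fi$rmsea, rmsea_lo = fi$rmsea_lo,
               rmsea_hi = fi$rmsea_hi, aic = fi$aic, bic = fi$bic,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$best_cfi <- seq_len(nrow(tab)) == which.max(tab$cfi)
  tab$best_rmsea <- seq_len(nrow(tab)) == which.min(tab$rmsea)
  tab$best_aic <- seq_len(nrow(tab)) == which.min(tab$aic)
  tab$best_bic <- seq_len(nrow(tab)) == which.min(tab$bic)
  tab
}
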