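test_that("saturated GGM equals the regression-residual partial correlations", {
  set.seed(1)
  K <- diag(3)
  K[1, 2] <- K[2, 1] <- -0.4
  K[2, 3] <- K[3, 2] <- -0.25
  x <- MASS::mvrnorm(200, rep(0, 3), solve(K))
  colnames(x) <- c("a", "b", "c")
  fit <- fit_saturated_ggm(x)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(fit$omega[i, j], oracle_partial_cor(x, i, j),
                   tolerance = 1e-8)
    }
  }
  # independent columns: all partial correlations near zero
  set.seed(2)
  z <- matrix(stats::rnorm(5000 * 4), ncol = 4)
  fit0 <- fit_saturated_ggm(z)
  expect_lt(max(abs(fit0$omega)), 0.05)
  expect_error(fit_saturated_ggm(cbind(a = 1:20, b = (1:20) * 2,
                                       c = stats::rnorm(20))),
               "collinear")
})

test_that("complete-data FIML equals the analytic inverse-covariance solution", {
  set.seed(3)
  x <- eta_scores(150, seed = 3)
  a <- fit_saturated_ggm(x)                       # analytic path
  f <- fit_saturated_ggm(x, missing = "fiml")     # EM path, forced
  expect_lt(max(abs(a$omega - f$omega)), 1e-6)
  expect_equal(a$loglik, f$loglik, tolerance = 1e-6)
})

test_that("FIML recovers structure under missing-at-random deletion", {
  set.seed(4)
  x <- eta_scores(2000, seed = 4)
  truth <- fit_saturated_ggm(x)
  xm <- x
  xm[stats::runif(length(xm)) < 0.12] <- NA
  fit <- fit_saturated_ggm(xm)
  expect_lt(max(abs(fit$omega - truth$omega)), 0.06)
})

test_that("pruning fixes edges to zero, refit reproduces free moments", {
  x <- eta_scores(600, seed = 5)
  sat <- fit_saturated_ggm(x)
  pr <- prune_and_refit(sat, alpha = 0.05)
  expect_true(all(pr$omega[!pr$adj & upper.tri(pr$adj)] == 0))
  # implied covariance equals the sample covariance on free entries
  S <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
  free <- pr$adj | diag(ncol(x)) > 0
  expect_lt(max(abs((pr$Sigma - S)[free])), 1e-7)
  # alpha = 1 prunes nothing; tiny alpha empties the network
  all_in <- prune_and_refit(sat, alpha = 1)
  expect_true(all(all_in$adj[upper.tri(all_in$adj)]))
  expect_equal(all_in$omega, sat$omega, tolerance = 1e-6)
  none <- prune_and_refit(sat, alpha = 1e-300)
  expect_equal(sum(none$adj), 0L)
  expect_equal(none$df, 45L)
})

test_that("partial correlations are invariant to linear rescaling", {
  x <- eta_scores(300, seed = 6)
  y <- sweep(sweep(x, 2, c(2, 5, 0.1, 1, 3, 7, 0.5, 1, 2, 4), `*`),
             2, seq_len(10), `+`)
  expect_equal(fit_saturated_ggm(x)$omega, fit_saturated_ggm(y)$omega,
               tolerance = 1e-8)
})

test_that("fit indices behave at the identity and obey penalty algebra", {
  x <- eta_scores(200, seed = 7)
  sat <- fit_saturated_ggm(x)
  fi <- fit_indices(sat)
  expect_equal(fi$chi2, 0, tolerance = 1e-8)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  pr <- prune_and_refit(sat, alpha = 0.05)
  fj <- fit_indices(pr)
  expect_gte(fj$df, 0)
  expect_true(fj$rmsea_lo <= fj$rmsea + 1e-12)
  expect_true(fj$rmsea <= fj$rmsea_hi + 1e-12)
  expect_true(fj$cfi >= 0 && fj$cfi <= 1)
  # nested models: AIC difference = chi2 difference - 2 * d(params)
  dk <- fi$n_params - fj$n_params
  expect_equal(fi$aic - fj$aic, (fi$chi2 - fj$chi2) + 2 * dk,
               tolerance = 1e-8)
  expect_equal(fi$bic - fj$bic,
               (fi$chi2 - fj$chi2) + log(pr$n) * dk, tolerance = 1e-8)
})

test_that("spinglass separates disjoint cliques exactly and is reproducible", {
  om <- matrix(0, 6, 6, dimnames = list(paste0("v", 1:6), paste0("v", 1:6)))
  om[1:3, 1:3] <- 0.4; om[4:6, 4:6] <- 0.4; diag(om) <- 0
  part <- spinglass_communities(om, n_reps = 20, seed = 3)
  expect_equal(part$frequency, 1)
  expect_equal(unname(part$labels), c(1, 1, 1, 2, 2, 2))
  # a single edge joins both nodes into one community
  om2 <- matrix(0, 2, 2); om2[1, 2] <- om2[2, 1] <- 0.3
  part2 <- spinglass_communities(om2, n_reps = 5, seed = 1)
  expect_equal(unname(part2$labels), c(1, 1))
  # fully disconnected: every node its own community at frequency 1
  om3 <- matrix(0, 4, 4)
  part3 <- spinglass_communities(om3, n_reps = 5, seed = 1)
  expect_equal(unname(part3$labels), 1:4)
  expect_equal(part3$frequency, 1)
  # reproducibility
  x <- eta_scores(400, seed = 8)
  net <- prune_and_refit(fit_saturated_ggm(x))
  p1 <- spinglass_communities(net, n_reps = 10, seed = 5)
  p2 <- spinglass_communities(net, n_reps = 10, seed = 5)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$frequency, p2$frequency)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (r in 1:20) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2), c(2, 2, 1)), 1)
})

test_that("bootstrap replays deterministically and brackets strong edges", {
  x <- eta_scores(500, seed = 10)
  b1 <- bootstrap_edges(x, n_boot = 2, seed = 4)
  b2 <- bootstrap_edges(x, n_boot = 2, seed = 4)
  expect_identical(b1, b2)
  b3 <- bootstrap_edges(x, n_boot = 150, seed = 5)
  # the two CPTs share a strong planted edge: CI excludes zero
  strong <- b3[b3$from == "cpt_impulsive" & b3$to == "cpt_sustained", ]
  expect_gt(strong$ci_lo, 0)
  expect_gt(strong$inclusion, 0.95)
  # a never-planted, clearly absent edge keeps low inclusion
  absent <- b3[b3$from == "span_fwd" & b3$to == "cpt_sustained", ]
  expect_lt(absent$inclusion, 0.5)
})

test_that("centrality matches closed forms and the brute-force betweenness", {
  # star graph: hub strength (n-1) * w, leaves w
  om <- matrix(0, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  om[1, 2:5] <- om[2:5, 1] <- 0.2
  net <- list(omega = om, adj = om != 0, variables = rownames(om))
  ce <- centrality(net)
  expect_equal(ce$strength[1], 4 * 0.2)
  expect_equal(ce$strength[2], 0.2)
  # all-negative edges: expected influence is minus the strength
  omn <- -om
  cn <- centrality(list(omega = omn, adj = omn != 0,
                        variables = rownames(om)))
  expect_equal(cn$expected_influence, -cn$strength)
  # brute-force betweenness on random small graphs
  set.seed(11)
  for (r in 1:5) {
    p <- 5
    w <- matrix(0, p, p)
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        if (stats::runif(1) < 0.6) {
          w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 0.6)
        }
      }
    }
    rownames(w) <- colnames(w) <- paste0("n", 1:p)
    got <- centrality(list(omega = w, adj = w != 0,
                           variables = rownames(w)))
    expect_equal(got$betweenness, oracle_betweenness(w), tolerance = 1e-9)
  }
})

test_that("a duplicated group yields zero likelihood-ratio differences", {
  x <- eta_scores(300, seed = 12)
  xx <- rbind(x, x)
  grp <- rep(c("g1", "g2"), each = nrow(x))
  inv <- multigroup_invariance(xx, grp)
  expect_lt(max(abs(inv$table$delta_chi2), na.rm = TRUE), 1e-2)
  expect_equal(inv$table$model,
               c("unconstrained", "equal_edges", "equal_edges_means",
                 "equal_all"))
  expect_true(all(diff(inv$table$df) > 0))
})

test_that("concurrent correlations recover construction and label effects", {
  x <- eta_scores(2000, seed = 13)
  co <- sample_cohort(default_cohort_model(), 2000, group_split = 1,
                      seed = 13)
  comp <- comparator_battery(co, lambda_cv = 0.5, seed = 14)
  tab <- concurrent_correlations(co$eta, comp)
  expect_equal(nrow(tab), 10L)
  expect_lt(max(abs(tab$r - 0.5)), 0.06)
  expect_true(all(tab$label %in% c("moderate", "large")))
  # identical columns give r = 1
  one <- concurrent_correlations(co$eta[, 1, drop = FALSE],
                                 structure(co$eta[, 1, drop = FALSE],
                                           dimnames = list(NULL,
                                                           "comparator_span_fwd")))
  expect_equal(one$r, 1)
  # minimum-n edge case computes without error
  tiny_a <- matrix(c(1, 2, 4), dimnames = list(NULL, "t"))
  tiny_b <- matrix(c(2, 1, 5), dimnames = list(NULL, "comparator_t"))
  expect_silent(concurrent_correlations(tiny_a, tiny_b))
})
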