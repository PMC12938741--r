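pen_for <- function(cohort, fu = 0.05, fv = 0.02, gamma = 0.1) {
  lm <- lambda_max(cohort)
  penalty_config(fu * lm$lambda_max_u, fv * lm$lambda_max_v, gamma, gamma)
}

test_that("initialization is seeded, distinct, and unperturbed for K = 1", {
  sim <- simulate_cohort(M = 80, N = 8, P = 20, K = 2, seed = 3)
  pen <- pen_for(sim$cohort)
  i1 <- initialize_clusters(sim$cohort, 4, "elastic", pen, seed = 5)
  i2 <- initialize_clusters(sim$cohort, 4, "elastic", pen, seed = 5)
  expect_identical(i1$pairs, i2$pairs)
  for (a in 1:3) for (b in (a + 1):4)
    expect_gt(sum((i1$pairs[[a]]$u - i1$pairs[[b]]$u)^2), 0)
  for (p in i1$pairs) { expect_unit_norm(p$u); expect_unit_norm(p$v) }

  k1 <- initialize_clusters(sim$cohort, 1, "elastic", pen, seed = 5)
  expect_identical(k1$pairs[[1]], k1$global)
})

test_that("membership goes to the cheapest cluster with documented tie-break", {
  co <- random_cohort(10, 4, 3, seed = 7)
  pen <- penalty_config(0.5, 0.2)
  ini <- initialize_clusters(co, 2, "ipls", pen, seed = 1)
  lab <- assign_memberships(co, ini$pairs, pen, "ipls")
  costs <- sapply(ini$pairs, function(p)
    (as.numeric(co$X %*% p$u) - as.numeric(co$Y %*% p$v))^2 +
      0.5 * sum(abs(p$u)) + 0.2 * sum(abs(p$v)))
  expect_equal(lab, apply(costs, 1, which.min))
  # exact tie (identical pairs) resolves to the lowest index
  lab_tie <- assign_memberships(co, list(ini$pairs[[1]], ini$pairs[[1]]),
                                pen, "ipls")
  expect_true(all(lab_tie == 1L))
})

test_that("equal penalty blocks make assignment depend on residuals only", {
  co <- random_cohort(40, 6, 4, seed = 17)
  set.seed(17)
  u1 <- rnorm(6); u1 <- u1 / sqrt(sum(u1^2))
  v1 <- rnorm(4); v1 <- v1 / sqrt(sum(v1^2))
  # second pair = coordinate permutation: identical L1/L2 penalty blocks
  u2 <- u1[c(2:6, 1)]; v2 <- v1[c(4, 1:3)]
  mk <- function(u, v) structure(list(u = u, v = v), class = "canonical_pair")
  for (lu in c(0.1, 5, 50)) {
    pen <- penalty_config(lu, lu / 2, 0.3, 0.3)
    lab <- assign_memberships(co, list(mk(u1, v1), mk(u2, v2)), pen, "elastic")
    res <- cbind((co$X %*% u1 - co$Y %*% v1)^2, (co$X %*% u2 - co$Y %*% v2)^2)
    expect_equal(lab, max.col(-res, ties.method = "first"))
  }
})

test_that("cluster updates equal subset fits and re-seed empty clusters", {
  sim <- simulate_cohort(M = 120, N = 10, P = 30, K = 2, noise_sd = 0.1,
                         seed = 23)
  pen <- pen_for(sim$cohort, fu = 0.02, fv = 0.01)
  truth <- sim$truth$labels
  ini <- initialize_clusters(sim$cohort, 2, "elastic", pen, seed = 2)
  up <- update_cluster_vectors(sim$cohort, truth, pen, "elastic", ini$pairs,
                               ini$global)
  for (k in 1:2) {
    rows <- which(truth == k)
    ref <- fit_canonical_pair(sim$cohort$X[rows, ], sim$cohort$Y[rows, ],
                              pen, ini$pairs[[k]]$u, ini$pairs[[k]]$v,
                              "elastic")
    expect_equal(up[[k]]$u, ref$u, tolerance = 1e-12)
  }
  # an empty cluster is replaced by a perturbed global pair, not zeros
  lab_empty <- rep(1L, 120)
  expect_message(
    up2 <- withr::with_seed(9,
      update_cluster_vectors(sim$cohort, lab_empty, pen, "elastic",
                             ini$pairs, ini$global)),
    "re-seeding")
  expect_gt(sum(abs(up2[[2]]$u)), 0)
  expect_unit_norm(up2[[2]]$u)
})

test_that("warm and cold starts agree at a converged membership", {
  sim <- simulate_cohort(M = 100, N = 8, P = 20, K = 2, noise_sd = 0.1,
                         seed = 29)
  pen <- pen_for(sim$cohort)
  fit <- scca_cluster(sim$cohort, 2, "elastic", pen, seed = 1,
                      assign_rule = "product")
  warm <- update_cluster_vectors(sim$cohort, fit$cluster, pen, "elastic",
                                 fit$pairs, fit$global_pair)
  for (k in 1:2) {
    rows <- which(fit$cluster == k)
    ini <- sccaclust:::svd_init(sim$cohort$X[rows, ], sim$cohort$Y[rows, ])
    cold <- fit_canonical_pair(sim$cohort$X[rows, ], sim$cohort$Y[rows, ],
                               pen, ini$u, ini$v, "elastic")
    # the alternation is non-convex: warm and cold starts may settle on
    # different stationary pairs, but at the converged membership their
    # penalized costs agree closely
    expect_equal(warm[[k]]$cost, cold$cost, tolerance = 0.02)
  }
})

test_that("the fitted model is reproducible and trajectory monotone", {
  sim <- simulate_cohort(M = 150, N = 10, P = 40, K = 3, support_n = 3,
                         seed = 31)
  pen <- pen_for(sim$cohort)
  f1 <- scca_cluster(sim$cohort, 3, "elastic", pen, seed = 4)
  f2 <- scca_cluster(sim$cohort, 3, "elastic", pen, seed = 4)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$pairs, f2$pairs)
  expect_true(all(diff(f1$total_cost_trajectory) <= 1e-9))
  # per-cluster cost equals the variant cost on the member rows
  for (k in which(f1$counts > 0)) {
    rows <- which(f1$cluster == k)
    expect_equal(f1$per_cluster_cost[k],
                 scca_cost(sim$cohort$X[rows, , drop = FALSE],
                           sim$cohort$Y[rows, , drop = FALSE],
                           f1$pairs[[k]]$u, f1$pairs[[k]]$v, pen, "elastic"),
                 tolerance = 1e-9)
  }
  expect_equal(sum(f1$membership), length(f1$cluster))
  expect_true(all(rowSums(f1$membership) == 1L))
})

test_that("subject order permutation permutes memberships identically", {
  sim <- simulate_cohort(M = 90, N = 8, P = 20, K = 2, seed = 37)
  pen <- pen_for(sim$cohort)
  fit <- scca_cluster(sim$cohort, 2, "elastic", pen, seed = 2,
                      assign_rule = "product")
  perm <- sample(90)
  co_p <- cohort_pair(sim$cohort$X[perm, ], sim$cohort$Y[perm, ],
                      sim$cohort$subject_ids[perm], standardized = TRUE)
  fit_p <- scca_cluster(co_p, 2, "elastic", pen, seed = 2,
                        assign_rule = "product")
  # align labels (cluster indices may swap) then compare membership pattern
  al <- align_labels(fit$cluster[perm], fit_p$cluster, 2)
  expect_equal(al[fit_p$cluster], fit$cluster[perm])
  expect_equal(sort(fit_p$per_cluster_cost), sort(fit$per_cluster_cost),
               tolerance = 1e-6)
})

test_that("planted memberships are a fixed point at vanishing noise", {
  sim <- simulate_cohort(M = 200, N = 12, P = 40, K = 3, support_p = 5,
                         support_n = 4, noise_sd = 1e-4, seed = 43)
  lm <- lambda_max(sim$cohort)
  pen <- penalty_config(0.05 * lm$lambda_max_u, 0.02 * lm$lambda_max_v,
                        0.1, 0.1, tol = 1e-10, max_cd_iter = 200000L)
  truth <- sim$truth$labels
  ini <- initialize_clusters(sim$cohort, 3, "elastic", pen, seed = 1)
  pairs <- update_cluster_vectors(sim$cohort, truth, pen, "elastic",
                                  ini$pairs, ini$global)
  lab <- assign_memberships(sim$cohort, pairs, pen, "elastic", "product")
  # subjects whose latent factor is essentially zero carry no cluster
  # information in either view and may land anywhere; everyone else stays
  informative <- abs(sim$truth$latent) > 0.25
  expect_equal(lab[informative], truth[informative])
  expect_gte(mean(lab == truth), 0.95)
})

test_that("K-scan reports costs and stability without choosing K", {
  sim <- simulate_cohort(M = 80, N = 8, P = 20, K = 2, seed = 47)
  pen <- pen_for(sim$cohort)
  tab <- suppressMessages(scan_k(sim$cohort, ks = 2:3, variant = "elastic",
                                 penalties = pen, seed = 1, n_rep = 2))
  expect_equal(tab$K, 2:3)
  expect_true(all(is.finite(tab$total_cost)))
  expect_named(tab, c("K", "total_cost", "cost_per_subject",
                      "init_stability_ari", "converged"))
})

test_that("model methods expose coefficients, predictions and residuals", {
  sim <- simulate_cohort(M = 100, N = 8, P = 20, K = 2, seed = 53)
  pen <- pen_for(sim$cohort)
  fit <- scca_cluster(sim$cohort, 2, "elastic", pen, seed = 1,
                      assign_rule = "product")
  cf <- coef(fit)
  expect_equal(dim(cf$u), c(20, 2))
  expect_equal(predict(fit, sim$cohort), fit$cluster)
  r <- residuals(fit)
  f <- fitted(fit)
  expect_equal(unname(r), f$alpha - f$beta)
  s <- summary(fit)
  expect_s3_class(s, "summary.scca_cluster")
  expect_output(print(s), "SCCA clustering")
})
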