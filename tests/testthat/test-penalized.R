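test_that("penalized cost matches hand sums and the term-by-term oracle", {
  X <- matrix(c(1, -1), 2, 1); Y <- X
  pen <- penalty_config(0.5, 0.5)
  expect_equal(scca_cost(X, Y, 1, 1, pen, "ipls"), 1.0)
  expect_equal(scca_cost(X, Y, 0, 0, pen, "ipls"), 0)

  pen_e <- penalty_config(1, 0, gamma_u = 1, gamma_v = 0)
  expect_equal(scca_cost(X, Y, 1, 0, pen_e, "elastic"), 4)

  set.seed(11)
  for (r in 1:5) {
    X <- matrix(rnorm(15), 5, 3); Y <- matrix(rnorm(10), 5, 2)
    u <- rnorm(3); v <- rnorm(2)
    lu <- runif(1); lv <- runif(1); gu <- runif(1); gv <- runif(1)
    expect_equal(scca_cost(X, Y, u, v, penalty_config(lu, lv), "ipls"),
                 cost_oracle(X, Y, u, v, lu, lv), tolerance = 1e-12)
    expect_equal(scca_cost(X, Y, u, v, penalty_config(lu, lv, gu, gv),
                           "elastic"),
                 cost_oracle(X, Y, u, v, lu, lv, gu, gv), tolerance = 1e-12)
    # elastic with zero ridge reduces to the L1-only cost
    expect_identical(scca_cost(X, Y, u, v, penalty_config(lu, lv, 0, 0),
                               "elastic"),
                     scca_cost(X, Y, u, v, penalty_config(lu, lv), "ipls"))
  }
  expect_error(scca_cost(X, Y, rnorm(4), v, penalty_config(1, 1), "ipls"),
               "dimension")
})

test_that("the coordinate solver matches the univariate soft-threshold form", {
  # fixed spec-style instance: single column, closed form gives 0.5
  w <- solve_penalized_direction(matrix(c(1, 0), 2, 1), c(2, 0),
                                 lambda = 2, gamma = 1)
  expect_equal(as.numeric(w), 0.5, tolerance = 1e-10)

  set.seed(21)
  for (r in 1:100) {
    a <- rnorm(sample(2:6, 1)); rr <- rnorm(length(a))
    lambda <- runif(1, 0, 3); gamma <- runif(1, 0, 2)
    closed <- {
      z <- abs(sum(a * rr)) - lambda / 2
      if (z > 0) sign(sum(a * rr)) * z / (sum(a * a) + gamma) else 0
    }
    w <- solve_penalized_direction(matrix(a, ncol = 1), rr, lambda, gamma)
    expect_equal(as.numeric(w), closed, tolerance = 1e-10)
  }
})

test_that("lambda = gamma = 0 recovers ordinary least squares", {
  set.seed(31)
  for (r in 1:100) {
    n <- sample(6:12, 1); p <- sample(2:4, 1)
    A <- matrix(rnorm(n * p), n, p); rr <- rnorm(n)
    ols <- qr.solve(A, rr)
    w <- solve_penalized_direction(A, rr, 0, 0, tol = 1e-12,
                                   max_iter = 20000)
    expect_equal(unname(as.numeric(w)), unname(ols), tolerance = 1e-8)
  }
})

test_that("lambda above the full-shrinkage bound yields exact zeros", {
  set.seed(41)
  A <- matrix(rnorm(40), 10, 4); rr <- rnorm(10)
  bound <- 2 * max(abs(crossprod(A, rr)))
  w <- solve_penalized_direction(A, rr, bound * 1.0001, 0)
  expect_identical(as.numeric(w), rep(0, 4))
  # also from a non-zero warm start
  w2 <- solve_penalized_direction(A, rr, bound * 1.5, 0.2, w0 = rnorm(4))
  expect_identical(as.numeric(w2), rep(0, 4))
})

test_that("the solver agrees with glmnet on random elastic-net instances", {
  skip_if_not_installed("glmnet")
  set.seed(51)
  for (r in 1:10) {
    n <- 40; p <- 8
    A <- matrix(rnorm(n * p), n, p); rr <- rnorm(n)
    # glmnet internally scales a gaussian response to unit 1/n-variance and
    # applies lambda on that scale, so hand it a pre-scaled response
    rr <- rr / sqrt(mean((rr - mean(rr))^2))
    lambda <- runif(1, 0.5, 4); gamma <- runif(1, 0, 2)
    # glmnet minimizes (1/2n)||r-Aw||^2 + lg(ag|w|_1 + (1-ag)/2 |w|_2^2);
    # scaling by 2n maps to ||r-Aw||^2 + lambda|w|_1 + gamma|w|_2^2 with
    # lambda = 2n lg ag, gamma = n lg (1-ag).
    lg <- lambda / (2 * n) + gamma / n
    ag <- (lambda / (2 * n)) / lg
    g <- glmnet::glmnet(A, rr, alpha = ag, lambda = lg * c(16, 8, 4, 2, 1),
                        intercept = FALSE, standardize = FALSE,
                        thresh = 1e-14)
    w <- solve_penalized_direction(A, rr, lambda, gamma, tol = 1e-12)
    expect_equal(as.numeric(w), as.numeric(g$beta[, 5]), tolerance = 1e-3)
  }
})

test_that("alternating canonical fits descend pre-rescaling at every half-step", {
  set.seed(61)
  co <- random_cohort(40, 10, 6, seed = 61)
  pen <- penalty_config(2, 0.5, 0.2, 0.2)
  fit <- fit_canonical_pair(co$X, co$Y, pen, rnorm(10), rnorm(6), "elastic")
  expect_true(all(fit$half_step_costs[, 2] <=
                  fit$half_step_costs[, 1] + 1e-9))
  expect_unit_norm(fit$u)
  expect_unit_norm(fit$v)
  # stored cost equals a recomputation on the stored vectors
  expect_equal(fit$cost, scca_cost(co$X, co$Y, fit$u, fit$v, pen, "elastic"),
               tolerance = 1e-10)
  # converged cost never exceeds the initialization cost
  expect_lte(fit$cost, fit$cost_sequence[1] + 1e-9)
})

test_that("sign canonicalization fixes the (u,v) vs (-u,-v) ambiguity", {
  co <- random_cohort(30, 8, 5, seed = 71)
  pen <- penalty_config(1, 0.3)
  f1 <- fit_canonical_pair(co$X, co$Y, pen, rep(1, 8), rep(1, 5), "ipls")
  f2 <- fit_canonical_pair(co$X, co$Y, pen, -rep(1, 8), -rep(1, 5), "ipls")
  expect_gt(f1$v[which.max(abs(f1$v))], 0)
  expect_gt(f2$v[which.max(abs(f2$v))], 0)
  # flipping both vectors leaves the cost unchanged
  expect_equal(scca_cost(co$X, co$Y, -f1$u, -f1$v, pen, "ipls"), f1$cost,
               tolerance = 1e-12)
})

test_that("a large ridge penalty shrinks the unrescaled solution", {
  co <- random_cohort(40, 10, 6, seed = 81)
  v0 <- rnorm(6); v0 <- v0 / sqrt(sum(v0^2))
  r <- as.numeric(co$Y %*% v0)
  w_ridge0 <- solve_penalized_direction(co$X, r, 1, 0)
  w_ridge9 <- solve_penalized_direction(co$X, r, 1, 50)
  expect_lt(sqrt(sum(w_ridge9^2)), sqrt(sum(w_ridge0^2)))
})

test_that("over-penalized fits fail loudly instead of returning zeros", {
  co <- random_cohort(20, 6, 4, seed = 91)
  big <- 10 * 2 * max(abs(crossprod(co$X, co$Y)))
  pen <- penalty_config(big, big)
  expect_error(fit_canonical_pair(co$X, co$Y, pen, rep(1, 6), rep(1, 4),
                                  "ipls"),
               "penalties too large")
})

test_that("canonical scores are the stored projections", {
  co <- random_cohort(15, 5, 3, seed = 5)
  pen <- penalty_config(0.5, 0.1)
  fit <- fit_canonical_pair(co$X, co$Y, pen, rep(1, 5), rep(1, 3), "ipls")
  sc <- canonical_scores(co, fit)
  expect_equal(unname(sc$alpha), as.numeric(co$X %*% fit$u))
  expect_equal(unname(sc$beta), as.numeric(co$Y %*% fit$v))
  expect_equal(canonical_covariance(co$X, co$Y, fit$u, fit$v),
               sum(sc$alpha * sc$beta))
})
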