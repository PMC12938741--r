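#' Penalty and solver settings for the sparse canonical solvers
#'
#' `lambda_u`/`lambda_v` are the L1 (sparsity) weights on the genetic and
#' imaging canonical vectors; `gamma_u`/`gamma_v` are the ridge weights used
#' by the elastic variant. The IPLS variant is the special case
#' `gamma_u = gamma_v = 0`. Defaults follow the convention of a stronger
#' sparsity constraint on the genetic view than on the imaging view
#' (`lambda_u` ten times `lambda_v`) so that only the most relevant variants
#' are selected while spatial imaging patterns stay complete.
#'
#' @param lambda_u,lambda_v Non-negative L1 penalty weights.
#' @param gamma_u,gamma_v Non-negative L2 penalty weights.
#' @param max_inner_iter Cap on alternations inside [fit_canonical_pair()].
#' @param max_cd_iter Cap on coordinate-descent sweeps per subproblem.
#' @param tol Relative-cost convergence tolerance for the alternation (also
#'   used, scaled, by the coordinate-descent stopping rule).
#' @param rescale If `TRUE` (default) each updated canonical vector is
#'   renormalized to unit Euclidean norm when non-zero.
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(lambda_u = 1, lambda_v = lambda_u / 10,
                           gamma_u = 0, gamma_v = 0,
                           max_inner_iter = 100L, max_cd_iter = 20000L,
                           tol = 1e-6, rescale = TRUE) {
  stopifnot(lambda_u >= 0, lambda_v >= 0, gamma_u >= 0, gamma_v >= 0,
            max_inner_iter >= 1, max_cd_iter >= 1, tol > 0)
  structure(list(lambda_u = lambda_u, lambda_v = lambda_v,
                 gamma_u = gamma_u, gamma_v = gamma_v,
                 max_inner_iter = as.integer(max_inner_iter),
                 max_cd_iter = as.integer(max_cd_iter),
                 tol = tol, rescale = isTRUE(rescale)),
            class = "penalty_config")
}

check_variant <- function(variant, penalties) {
  variant <- match.arg(variant, c("ipls", "elastic"))
  if (variant == "ipls" && (penalties$gamma_u != 0 || penalties$gamma_v != 0))
    stop("IPLS requires gamma_u = gamma_v = 0; use variant = \"elastic\"")
  variant
}

#' Penalized canonical cost
#'
#' `scca_cost()` evaluates the penalized squared-difference objective
#' `||Xu - Yv||^2 + lambda_u ||u||_1 + lambda_v ||v||_1`
#' (plus `gamma_u ||u||_2^2 + gamma_v ||v||_2^2` for the elastic variant)
#' for one canonical pair on one subject set.
#'
#' @param X,Y Views (rows = subjects).
#' @param u,v Canonical weight vectors (length `ncol(X)` / `ncol(Y)`).
#' @param penalties A [penalty_config()].
#' @param variant `"ipls"` (L1 only) or `"elastic"` (L1 + L2).
#' @return Non-negative scalar.
#' @export
scca_cost <- function(X, Y, u, v, penalties, variant = c("ipls", "elastic")) {
  variant <- check_variant(variant, penalties)
  if (length(u) != ncol(X) || length(v) != ncol(Y))
    stop("dimension mismatch between weight vectors and views")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  res <- sum((X %*% u - Y %*% v)^2)
  pen <- penalty_value(u, v, penalties, variant)
  res + pen
}

# Penalty block of the objective (shared by cost and surrogate bookkeeping).
penalty_value <- function(u, v, penalties, variant) {
  pen <- penalties$lambda_u * sum(abs(u)) + penalties$lambda_v * sum(abs(v))
  if (variant == "elastic")
    pen <- pen + penalties$gamma_u * sum(u^2) + penalties$gamma_v * sum(v^2)
  pen
}

#' Diagnostic covariance form of the canonical objective
#'
#' The classical CCA objective `(Xu)' Yv`, i.e. the sum over subjects of the
#' product of the two canonical scores. The clustering machinery minimizes
#' the squared-difference form instead (the two are not equivalent); this
#' product form is provided purely as a diagnostic.
#'
#' @inheritParams scca_cost
#' @return Scalar covariance between the canonical scores.
#' @export
canonical_covariance <- function(X, Y, u, v) {
  drop(crossprod(X %*% u, Y %*% v))
}

#' Solve one penalized regression direction
#'
#' Minimizes `||A w - r||^2 + lambda ||w||_1 + gamma ||w||_2^2` by cyclic
#' coordinate descent with covariance updates. Because the residual carries
#' no 1/2 factor, the univariate update soft-thresholds at `lambda / 2`:
#' `w_j = S(a_j' rho_j, lambda/2) / (a_j' a_j + gamma)`.
#'
#' @param A Design matrix (subjects x features).
#' @param r Response vector (one canonical score per subject).
#' @param lambda,gamma Non-negative penalty weights.
#' @param w0 Optional warm start (defaults to zero).
#' @param max_iter Sweep cap.
#' @param tol Stop when the largest coordinate change in a sweep is below
#'   `tol * (1 + max |w|)`.
#' @return Numeric weight vector with attributes `iterations` and
#'   `converged`; warns on non-convergence with the final gap.
#' @export
solve_penalized_direction <- function(A, r, lambda, gamma = 0, w0 = NULL,
                                      max_iter = 1000L, tol = 1e-8) {
  A <- as.matrix(A)
  stopifnot(nrow(A) >= 1, lambda >= 0, gamma >= 0)
  if (length(r) != nrow(A)) stop("length(r) must equal nrow(A)")
  if (is.null(w0)) w0 <- numeric(ncol(A))
  G <- crossprod(A)
  cvec <- drop(crossprod(A, r))
  fit <- cd_penalized(G, cvec, lambda, gamma, as.numeric(w0),
                      as.integer(max_iter), tol)
  w <- drop(fit$w)
  if (!fit$converged)
    warning(sprintf("coordinate descent did not converge in %d sweeps (gap %.3g)",
                    max_iter, fit$gap))
  attr(w, "iterations") <- fit$iterations
  attr(w, "converged") <- fit$converged
  w
}

# Unit-norm rescale; zero vectors are returned unchanged.
unit_rescale <- function(w) {
  n <- sqrt(sum(w^2))
  if (n > 0) w / n else w
}

# Joint sign canonicalization: flip (u, v) so the largest-magnitude entry of
# v is positive. Removes the (u,v) vs (-u,-v) ambiguity so weights are
# comparable across repetitions.
canonicalize_sign <- function(u, v) {
  if (all(v == 0)) return(list(u = u, v = v))
  j <- which.max(abs(v))
  if (v[j] < 0) list(u = -u, v = -v) else list(u = u, v = v)
}

#' Fit a single sparse canonical pair
#'
#' Alternates a u-step (penalized regression of the imaging score `Yv` on
#' `X`) and a v-step (regression of `Xu` on `Y`), each followed by unit-norm
#' rescaling of the updated vector, until the relative change in the
#' penalized cost falls below `penalties$tol` or `max_inner_iter`
#' alternations. The returned pair is the best (lowest rescaled-cost)
#' iterate encountered, so a warm-started refit never ends above its
#' starting cost. The sign is canonicalized so the largest-magnitude
#' imaging weight is positive.
#'
#' @inheritParams scca_cost
#' @param init_u,init_v Non-zero starting vectors.
#' @return A `canonical_pair` with elements `u`, `v`, `cost`, `n_iter`,
#'   `cost_sequence` (rescaled cost after each alternation) and
#'   `half_step_costs` (pre-rescaling objective after each half-step).
#' @export
fit_canonical_pair <- function(X, Y, penalties, init_u, init_v,
                               variant = c("ipls", "elastic")) {
  variant <- check_variant(variant, penalties)
  stopifnot(length(init_u) == ncol(X), length(init_v) == ncol(Y))
  if (all(init_u == 0) || all(init_v == 0))
    stop("initial canonical vectors must be non-zero")
  u <- if (penalties$rescale) unit_rescale(init_u) else init_u
  v <- if (penalties$rescale) unit_rescale(init_v) else init_v
  gu <- if (variant == "elastic") penalties$gamma_u else 0
  gv <- if (variant == "elastic") penalties$gamma_v else 0
  cd_tol <- min(1e-8, penalties$tol)

  cost <- scca_cost(X, Y, u, v, penalties, variant)
  best <- list(u = u, v = v, cost = cost)
  cost_seq <- cost
  half_costs <- NULL  # rows: (objective before, objective after), pre-rescaling
  n_iter <- 0L
  for (it in seq_len(penalties$max_inner_iter)) {
    n_iter <- it
    # u-step: minimize over u with v fixed (pre-rescaling objective recorded)
    u_raw <- solve_penalized_direction(X, drop(Y %*% v),
                                       penalties$lambda_u, gu, w0 = u,
                                       max_iter = penalties$max_cd_iter,
                                       tol = cd_tol)
    half_costs <- rbind(half_costs,
                        c(cost, scca_cost(X, Y, u_raw, v, penalties, variant)))
    u_new <- if (penalties$rescale) unit_rescale(u_raw) else u_raw
    # v-step against the rescaled u
    before_v <- scca_cost(X, Y, u_new, v, penalties, variant)
    v_raw <- solve_penalized_direction(Y, drop(X %*% u_new),
                                       penalties$lambda_v, gv, w0 = v,
                                       max_iter = penalties$max_cd_iter,
                                       tol = cd_tol)
    half_costs <- rbind(half_costs,
                        c(before_v,
                          scca_cost(X, Y, u_new, v_raw, penalties, variant)))
    v_new <- if (penalties$rescale) unit_rescale(v_raw) else v_raw
    if (all(u_new == 0) && all(v_new == 0))
      stop("penalties too large: both canonical vectors shrank to zero")
    u <- u_new; v <- v_new
    new_cost <- scca_cost(X, Y, u, v, penalties, variant)
    cost_seq <- c(cost_seq, new_cost)
    if (new_cost < best$cost) best <- list(u = u, v = v, cost = new_cost)
    if (abs(new_cost - cost) <= penalties$tol * (1 + abs(cost))) break
    cost <- new_cost
  }
  if (all(best$u == 0) || all(best$v == 0))
    stop("penalties too large: a canonical vector shrank to zero")
  sgn <- canonicalize_sign(best$u, best$v)
  structure(list(u = sgn$u, v = sgn$v, cost = best$cost, n_iter = n_iter,
                 cost_sequence = cost_seq, half_step_costs = half_costs,
                 variant = variant),
            class = "canonical_pair")
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat(sprintf("Sparse canonical pair (%s): cost %.6g after %d alternations\n",
              x$variant, x$cost, x$n_iter))
  cat(sprintf("  non-zero weights: %d/%d SNPs, %d/%d ROIs\n",
              sum(x$u != 0), length(x$u), sum(x$v != 0), length(x$v)))
  invisible(x)
}

#' Canonical scores for one pair
#'
#' @param cohort A [cohort_pair()].
#' @param pair A `canonical_pair`.
#' @return List with `alpha = X u` and `beta = Y v`.
#' @export
canonical_scores <- function(cohort, pair) {
  list(alpha = drop(cohort$X %*% pair$u), beta = drop(cohort$Y %*% pair$v))
}
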