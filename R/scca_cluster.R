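# Alternating SCCA clustering: simultaneous estimation of a one-hot
# membership matrix R (M x K) and per-cluster sparse canonical pairs
# (u_k, v_k), minimizing the per-subject penalized surrogate
#   sum_i [ ||X_i u_{k(i)} - Y_i v_{k(i)}||^2 + pen(k(i)) ].

# Deterministic starting vectors for the global fit: leading singular
# vectors of X'Y (one canonical direction), with an all-ones fallback.
svd_init <- function(X, Y) {
  s <- svd(crossprod(X, Y), nu = 1L, nv = 1L)
  u <- drop(s$u); v <- drop(s$v)
  if (all(u == 0)) u <- rep(1 / sqrt(ncol(X)), ncol(X))
  if (all(v == 0)) v <- rep(1 / sqrt(ncol(Y)), ncol(Y))
  canonicalize_sign(u, v)
}

perturb_pair <- function(pair, perturb_scale) {
  jitter1 <- function(w) {
    rms <- sqrt(mean(w^2))
    unit_rescale(w + stats::rnorm(length(w), sd = perturb_scale * rms))
  }
  u <- jitter1(pair$u); v <- jitter1(pair$v)
  sgn <- canonicalize_sign(u, v)
  pair$u <- sgn$u; pair$v <- sgn$v
  pair
}

#' Perturbation-based initialization of the cluster canonical pairs
#'
#' Fits one global canonical pair on the whole cohort, then derives K
#' distinct starting pairs by adding seeded Gaussian noise (standard
#' deviation `perturb_scale` times the per-entry RMS of the global vector)
#' independently to each copy and renormalizing. `K = 1` returns the
#' unperturbed global pair.
#'
#' @param cohort A standardized [cohort_pair()].
#' @param K Number of clusters.
#' @param variant `"ipls"` or `"elastic"`.
#' @param penalties A [penalty_config()].
#' @param seed Integer seed driving the perturbations.
#' @param perturb_scale Relative perturbation magnitude (> 0).
#' @return List with `global` (the unperturbed fit) and `pairs` (K pairs).
#' @export
initialize_clusters <- function(cohort, K, variant, penalties, seed,
                                perturb_scale = 0.1) {
  stopifnot(K >= 1, perturb_scale > 0)
  init <- svd_init(cohort$X, cohort$Y)
  global <- fit_canonical_pair(cohort$X, cohort$Y, penalties,
                               init$u, init$v, variant)
  pairs <- if (K == 1L) list(global) else {
    withr_seed(seed, replicate(K, perturb_pair(global, perturb_scale),
                               simplify = FALSE))
  }
  list(global = global, pairs = pairs)
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Per-subject penalized cost matrix: entry (i, k) is
# ||X_i u_k - Y_i v_k||^2 + pen(k).
subject_cost_matrix <- function(cohort, pairs, penalties, variant) {
  K <- length(pairs)
  A <- vapply(pairs, function(p) drop(cohort$X %*% p$u), numeric(nrow(cohort$X)))
  B <- vapply(pairs, function(p) drop(cohort$Y %*% p$v), numeric(nrow(cohort$Y)))
  res <- (matrix(A, ncol = K) - matrix(B, ncol = K))^2
  pen <- vapply(pairs, function(p) penalty_value(p$u, p$v, penalties, variant),
                numeric(1))
  sweep(res, 2L, pen, "+")
}

#' Assign subjects to clusters
#'
#' Two membership rules are provided. `rule = "residual"` sends each
#' subject to the cluster minimizing the per-subject penalized cost
#' `||X_i u_k - Y_i v_k||^2 + lambda_u ||u_k||_1 + lambda_v ||v_k||_1`
#' (plus ridge terms for the elastic variant); this rule is an exact
#' coordinate-descent step on the surrogate total, so the fit's cost
#' trajectory is non-increasing. `rule = "product"` sends each subject to
#' the cluster maximizing the product of its canonical scores
#' `(X_i u_k)(Y_i v_k)`, the classical covariance-form membership
#' criterion; it separates clusters whose canonical scores are near zero
#' under the wrong model (where the squared difference is blind) and is
#' the rule to use when the goal is subtype separation. Ties break toward
#' the lowest cluster index.
#'
#' @inheritParams initialize_clusters
#' @param pairs List of K `canonical_pair`s.
#' @param rule `"residual"` (penalized squared difference) or `"product"`
#'   (canonical-score product).
#' @return Integer vector of cluster labels in `1:K` (a one-hot membership
#'   matrix is available via [membership_matrix()]).
#' @export
assign_memberships <- function(cohort, pairs, penalties,
                               variant = c("ipls", "elastic"),
                               rule = c("residual", "product")) {
  variant <- check_variant(variant, penalties)
  rule <- match.arg(rule)
  if (rule == "product") {
    K <- length(pairs)
    A <- vapply(pairs, function(p) drop(cohort$X %*% p$u),
                numeric(nrow(cohort$X)))
    B <- vapply(pairs, function(p) drop(cohort$Y %*% p$v),
                numeric(nrow(cohort$Y)))
    return(max.col(matrix(A, ncol = K) * matrix(B, ncol = K),
                   ties.method = "first"))
  }
  costs <- subject_cost_matrix(cohort, pairs, penalties, variant)
  max.col(-costs, ties.method = "first")
}

#' One-hot membership matrix from labels
#'
#' @param labels Integer labels in `1:K`.
#' @param K Number of clusters.
#' @return M x K binary matrix with one 1 per row.
#' @export
membership_matrix <- function(labels, K) {
  R <- matrix(0L, nrow = length(labels), ncol = K)
  R[cbind(seq_along(labels), labels)] <- 1L
  R
}

# Surrogate contribution of one cluster: within-cluster residual plus the
# penalty block counted once per member.
cluster_surrogate <- function(cohort, rows, pair, penalties, variant) {
  if (length(rows) == 0L) return(0)
  res <- sum((cohort$X[rows, , drop = FALSE] %*% pair$u -
              cohort$Y[rows, , drop = FALSE] %*% pair$v)^2)
  res + length(rows) * penalty_value(pair$u, pair$v, penalties, variant)
}

#' Refit the canonical pair of every cluster
#'
#' For each non-empty cluster, [fit_canonical_pair()] is run on the member
#' rows, warm-started at the previous pair; the refit is kept only if it
#' lowers that cluster's contribution to the per-subject surrogate total,
#' so the outer loop is a descent method. Empty clusters are re-seeded from
#' a fresh perturbation of the global pair (with a message), keeping K fixed.
#'
#' @inheritParams assign_memberships
#' @param labels Integer membership labels in `1:K`.
#' @param warm_pairs Previous K pairs (warm starts).
#' @param global_pair Global fit used to re-seed empty clusters.
#' @param perturb_scale Perturbation magnitude for re-seeding.
#' @param safeguard Keep the warm-start pair whenever the refit would raise
#'   the cluster's surrogate contribution (required for the monotone
#'   trajectory under the residual assignment rule).
#' @return List of K updated `canonical_pair`s.
#' @export
update_cluster_vectors <- function(cohort, labels, penalties, variant,
                                   warm_pairs, global_pair = NULL,
                                   perturb_scale = 0.1, safeguard = TRUE) {
  variant <- check_variant(variant, penalties)
  K <- length(warm_pairs)
  out <- warm_pairs
  for (k in seq_len(K)) {
    rows <- which(labels == k)
    if (length(rows) == 0L) {
      if (is.null(global_pair))
        stop("empty cluster ", k, " and no global pair to re-seed from")
      message("re-seeding empty cluster ", k, " from a perturbed global pair")
      out[[k]] <- perturb_pair(global_pair, perturb_scale)
      next
    }
    Xk <- cohort$X[rows, , drop = FALSE]
    Yk <- cohort$Y[rows, , drop = FALSE]
    cand <- tryCatch(
      fit_canonical_pair(Xk, Yk, penalties, warm_pairs[[k]]$u,
                         warm_pairs[[k]]$v, variant),
      error = function(e) NULL)
    if (is.null(cand)) {
      # a poorly aligned warm start can be fully shrunk away; restart the
      # subset fit from its own deterministic SVD initialization
      ini <- svd_init(Xk, Yk)
      cand <- tryCatch(fit_canonical_pair(Xk, Yk, penalties, ini$u, ini$v,
                                          variant),
                       error = function(e) NULL)
    }
    if (!is.null(cand)) {
      if (!safeguard) { out[[k]] <- cand; next }
      old_c <- cluster_surrogate(cohort, rows, warm_pairs[[k]], penalties, variant)
      new_c <- cluster_surrogate(cohort, rows, cand, penalties, variant)
      if (new_c <= old_c + 1e-12) out[[k]] <- cand
    }
  }
  out
}

#' Sparse canonical correlation clustering
#'
#' Simultaneously estimates K cluster-specific sparse canonical pairs and a
#' one-hot cluster membership, by alternating (i) per-subject assignment to
#' the cluster with the lowest penalized canonical discrepancy and (ii)
#' per-cluster refitting of the sparse canonical pair on the member rows.
#' Initial pairs come from seeded perturbations of a single global fit.
#' The recorded total cost is the per-subject penalized surrogate, which
#' both half-updates decrease, so the trajectory is non-increasing.
#'
#' @param cohort A standardized [cohort_pair()] (see [standardize()]).
#' @param K Number of clusters (required; must be < number of subjects).
#' @param variant `"ipls"` (L1 penalties only) or `"elastic"` (L1 + L2).
#' @param penalties A [penalty_config()].
#' @param seed Integer seed; all randomness (initial perturbations,
#'   empty-cluster re-seeding) flows from it.
#' @param max_outer_iter Cap on assignment/update rounds.
#' @param tol Relative change in the surrogate total below which the fit is
#'   declared converged (membership becoming stationary also stops it).
#' @param perturb_scale Initialization perturbation magnitude.
#' @param assign_rule Membership rule, `"residual"` (default; penalized
#'   squared difference, guaranteed-descent trajectory) or `"product"`
#'   (canonical-score product; see [assign_memberships()] for when each is
#'   appropriate).
#' @param init_pairs Optional list of K starting `canonical_pair`s
#'   (overrides the perturbation initialization).
#' @return An object of class `scca_cluster` with elements `cluster`
#'   (integer labels), `pairs`, `membership` (M x K one-hot matrix),
#'   `per_cluster_cost` (penalized cost of each cluster on its rows, raw
#'   and per subject), `total_cost_trajectory`, `converged`, `n_iter`,
#'   `seed`, `variant`, `penalties`, `counts` and `global_pair`.
#' @examples
#' sim <- simulate_cohort(M = 120, N = 10, P = 30, K = 2, seed = 1)
#' fit <- scca_cluster(sim$cohort, K = 2, variant = "elastic",
#'                     penalties = penalty_config(2, 0.5, 0.1, 0.1), seed = 1)
#' table(fit$cluster, sim$truth$labels)
#' @export
scca_cluster <- function(cohort, K, variant = c("elastic", "ipls"),
                         penalties = penalty_config(), seed = 1L,
                         max_outer_iter = 100L, tol = 1e-6,
                         perturb_scale = 0.1,
                         assign_rule = c("residual", "product"),
                         init_pairs = NULL) {
  stopifnot(inherits(cohort, "cohort_pair"))
  variant <- check_variant(variant, penalties)
  assign_rule <- match.arg(assign_rule)
  M <- nrow(cohort$X)
  if (K < 1 || M <= K) stop("need 1 <= K < number of subjects")
  if (!cohort$standardized)
    warning("cohort is not standardized; run standardize() first")

  init <- initialize_clusters(cohort, K, variant, penalties, seed,
                              perturb_scale)
  pairs <- if (is.null(init_pairs)) init$pairs else init_pairs
  if (length(pairs) != K) stop("init_pairs must have length K")

  if (K == 1L && is.null(init_pairs)) {
    # single-cluster model is exactly the global canonical-pair fit
    labels <- rep(1L, M)
    traj <- total_surrogate(cohort, labels, pairs, penalties, variant)
    return(finish_scca_cluster(cohort, labels, pairs, traj, TRUE, 0L, K,
                               variant, assign_rule, penalties, seed,
                               init$global))
  }

  labels <- assign_memberships(cohort, pairs, penalties, variant, assign_rule)
  traj <- total_surrogate(cohort, labels, pairs, penalties, variant)
  converged <- FALSE
  degen_run <- 0L
  n_iter <- 0L
  withr_seed(seed + 1L, {
    for (it in seq_len(max_outer_iter)) {
      n_iter <- it
      pairs <- update_cluster_vectors(cohort, labels, penalties, variant,
                                      pairs, init$global, perturb_scale,
                                      safeguard = (assign_rule == "residual"))
      reseeded <- FALSE
      if (assign_rule == "product") {
        pairs <- reseed_duplicates(cohort, pairs, labels, penalties, variant)
        reseeded <- isTRUE(attr(pairs, "reseeded"))
      }
      new_labels <- assign_memberships(cohort, pairs, penalties, variant,
                                       assign_rule)
      cost <- total_surrogate(cohort, new_labels, pairs, penalties, variant)
      traj <- c(traj, cost)
      if (sum(tabulate(new_labels, K) > 0L) <= 1L && K > 1L) {
        degen_run <- degen_run + 1L
        if (degen_run >= 3L)
          warning("degenerate clustering: all subjects in one cluster for 3 iterations")
      } else degen_run <- 0L
      stable <- all(new_labels == labels) && !reseeded
      prev <- traj[length(traj) - 1L]
      small <- if (assign_rule == "residual")
        abs(prev - cost) <= tol * (1 + abs(prev)) else FALSE
      labels <- new_labels
      if (stable || small) { converged <- TRUE; break }
    }
  })

  finish_scca_cluster(cohort, labels, pairs, traj, converged, n_iter, K,
                      variant, assign_rule, penalties, seed, init$global)
}

finish_scca_cluster <- function(cohort, labels, pairs, traj, converged,
                                n_iter, K, variant, assign_rule, penalties,
                                seed, global_pair) {
  counts <- tabulate(labels, K)
  pcc <- vapply(seq_len(K), function(k) {
    rows <- which(labels == k)
    if (length(rows) == 0L) return(NA_real_)
    scca_cost(cohort$X[rows, , drop = FALSE], cohort$Y[rows, , drop = FALSE],
              pairs[[k]]$u, pairs[[k]]$v, penalties, variant)
  }, numeric(1))

  structure(list(cluster = labels, pairs = pairs,
                 membership = membership_matrix(labels, K),
                 per_cluster_cost = pcc,
                 per_cluster_cost_per_subject = pcc / pmax(counts, 1L),
                 total_cost_trajectory = traj,
                 converged = converged, n_iter = n_iter,
                 counts = counts, K = K, variant = variant,
                 assign_rule = assign_rule,
                 penalties = penalties, seed = seed,
                 subject_ids = cohort$subject_ids,
                 snp_ids = cohort$snp_ids, roi_ids = cohort$roi_ids,
                 global_pair = global_pair,
                 scores = lapply(pairs, function(p) canonical_scores(cohort, p))),
            class = "scca_cluster")
}

# Degenerate-cluster remedy for the product assignment rule: when two
# clusters converge onto (nearly) the same canonical direction, the weaker
# one (less within-cluster score-product mass) is refit on the subjects the
# current model serves worst (lowest best product), analogous to k-means++
# reseeding of duplicate centroids. Returns the possibly modified pairs.
reseed_duplicates <- function(cohort, pairs, labels, penalties, variant,
                              sim_threshold = 0.9) {
  K <- length(pairs)
  if (K < 2L) return(pairs)
  A <- vapply(pairs, function(p) drop(cohort$X %*% p$u), numeric(nrow(cohort$X)))
  B <- vapply(pairs, function(p) drop(cohort$Y %*% p$v), numeric(nrow(cohort$Y)))
  prod <- matrix(A, ncol = K) * matrix(B, ncol = K)
  best <- apply(prod, 1L, max)
  simU <- abs(crossprod(vapply(pairs, `[[`, numeric(length(pairs[[1]]$u)), "u")))
  mass <- vapply(seq_len(K), function(k) sum(prod[labels == k, k]), numeric(1))
  n_worst <- max(10L, nrow(cohort$X) %/% K)
  changed <- FALSE
  for (j in seq_len(K - 1L)) for (k in seq(j + 1L, K)) {
    if (simU[j, k] > sim_threshold) {
      weak <- if (mass[j] < mass[k]) j else k
      rows <- order(best)[seq_len(min(n_worst, nrow(cohort$X)))]
      Xw <- cohort$X[rows, , drop = FALSE]
      Yw <- cohort$Y[rows, , drop = FALSE]
      ini <- svd_init(Xw, Yw)
      cand <- tryCatch(fit_canonical_pair(Xw, Yw, penalties, ini$u, ini$v,
                                          variant),
                       error = function(e) NULL)
      if (!is.null(cand)) { pairs[[weak]] <- cand; changed <- TRUE }
    }
  }
  attr(pairs, "reseeded") <- changed
  pairs
}

# Surrogate total over all subjects (penalties counted per subject).
total_surrogate <- function(cohort, labels, pairs, penalties, variant) {
  costs <- subject_cost_matrix(cohort, pairs, penalties, variant)
  sum(costs[cbind(seq_along(labels), labels)])
}

#' @export
print.scca_cluster <- function(x, ...) {
  cat(sprintf("SCCA clustering (%s), K = %d, %d subjects\n",
              x$variant, x$K, length(x$cluster)))
  cat("  cluster sizes:", paste(x$counts, collapse = ", "), "\n")
  cat(sprintf("  converged: %s after %d outer iterations\n",
              x$converged, x$n_iter))
  cat("  per-cluster cost:",
      paste(sprintf("%.4g", x$per_cluster_cost), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.scca_cluster <- function(object, ...) {
  nz <- t(vapply(object$pairs, function(p)
    c(snps = sum(p$u != 0), rois = sum(p$v != 0)), numeric(2)))
  out <- list(K = object$K, variant = object$variant,
              counts = object$counts, converged = object$converged,
              n_iter = object$n_iter,
              per_cluster_cost = object$per_cluster_cost,
              per_cluster_cost_per_subject = object$per_cluster_cost_per_subject,
              nonzero = nz,
              final_cost = object$total_cost_trajectory[length(object$total_cost_trajectory)])
  class(out) <- "summary.scca_cluster"
  out
}

#' @export
print.summary.scca_cluster <- function(x, ...) {
  cat(sprintf("SCCA clustering (%s), K = %d\n", x$variant, x$K))
  tab <- data.frame(size = x$counts,
                    cost = x$per_cluster_cost,
                    cost_per_subject = x$per_cluster_cost_per_subject,
                    nonzero_snps = x$nonzero[, "snps"],
                    nonzero_rois = x$nonzero[, "rois"])
  rownames(tab) <- paste0("S", seq_len(x$K))
  print(tab)
  cat(sprintf("Converged: %s (%d iterations); surrogate total %.6g\n",
              x$converged, x$n_iter, x$final_cost))
  invisible(x)
}

#' @export
coef.scca_cluster <- function(object, ...) {
  u <- vapply(object$pairs, `[[`, numeric(length(object$snp_ids)), "u")
  v <- vapply(object$pairs, `[[`, numeric(length(object$roi_ids)), "v")
  dimnames(u) <- list(object$snp_ids, paste0("S", seq_len(object$K)))
  dimnames(v) <- list(object$roi_ids, paste0("S", seq_len(object$K)))
  list(u = u, v = v)
}

#' Predict subtype membership for new subjects
#'
#' Applies the fitted per-cluster canonical pairs to a new (standardized)
#' cohort and assigns each row by the same penalized rule used during
#' fitting.
#'
#' @param object A fitted `scca_cluster` model.
#' @param newdata A [cohort_pair()] with the same feature columns.
#' @param ... Unused.
#' @return Integer cluster labels.
#' @export
predict.scca_cluster <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort_pair"))
  if (ncol(newdata$X) != length(object$snp_ids) ||
      ncol(newdata$Y) != length(object$roi_ids))
    stop("newdata feature dimensions do not match the fitted model")
  assign_memberships(newdata, object$pairs, object$penalties, object$variant,
                     object$assign_rule)
}

#' @export
fitted.scca_cluster <- function(object, ...) {
  k <- object$cluster
  data.frame(subject_id = object$subject_ids, cluster = k,
             alpha = vapply(seq_along(k), function(i)
               object$scores[[k[i]]]$alpha[i], numeric(1)),
             beta = vapply(seq_along(k), function(i)
               object$scores[[k[i]]]$beta[i], numeric(1)))
}

#' @export
residuals.scca_cluster <- function(object, ...) {
  f <- fitted(object)
  stats::setNames(f$alpha - f$beta, f$subject_id)
}

#' Plot the convergence trajectory
#'
#' @param x A fitted `scca_cluster` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scca_cluster <- function(x, ...) {
  graphics::plot(seq_along(x$total_cost_trajectory) - 1L,
                 x$total_cost_trajectory, type = "b",
                 xlab = "outer iteration", ylab = "penalized surrogate total",
                 main = sprintf("SCCA clustering convergence (%s, K = %d)",
                                x$variant, x$K), ...)
  invisible(x)
}

#' Exploratory scan over candidate cluster counts
#'
#' Fits the model for each K in `ks` and reports the converged surrogate
#' total, per-subject cost, and a small initialization-stability summary
#' (mean ARI across `n_rep` re-seeded fits). Makes no automatic choice of K.
#'
#' @inheritParams scca_cluster
#' @param ks Integer vector of candidate cluster counts.
#' @param n_rep Re-seeded fits per K for the stability summary.
#' @return Data frame with one row per K.
#' @export
scan_k <- function(cohort, ks = 2:6, variant = c("elastic", "ipls"),
                   penalties = penalty_config(), seed = 1L, n_rep = 3L) {
  variant <- match.arg(variant)
  rows <- lapply(ks, function(K) {
    fits <- lapply(seq_len(n_rep), function(r)
      scca_cluster(cohort, K, variant, penalties, seed = seed + r - 1L))
    ari <- if (n_rep >= 2L) {
      pairsARI <- utils::combn(n_rep, 2L, function(ij)
        mclust::adjustedRandIndex(fits[[ij[1]]]$cluster, fits[[ij[2]]]$cluster))
      mean(pairsARI)
    } else NA_real_
    tr <- fits[[1]]$total_cost_trajectory
    data.frame(K = K, total_cost = tr[length(tr)],
               cost_per_subject = tr[length(tr)] / length(fits[[1]]$cluster),
               init_stability_ari = ari, converged = fits[[1]]$converged)
  })
  do.call(rbind, rows)
}
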