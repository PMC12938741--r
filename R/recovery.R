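#' @useDynLib sccaclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Score a fitted model against planted synthetic truth
#'
#' Computes the adjusted Rand index between the recovered and planted
#' memberships and, after aligning cluster labels, the support-recovery F1
#' (non-zero pattern of the canonical vectors vs the planted loadings) for
#' each view.
#'
#' @param fit A fitted [scca_cluster()] model.
#' @param truth A `synthetic_truth` from [simulate_cohort()].
#' @param cohort The standardized cohort the model was fitted on (needed to
#'   map planted supports onto retained columns).
#' @return List with `ari`, `f1_u`, `f1_v` (per-cluster means) and the
#'   per-cluster F1 vectors.
#' @export
score_recovery <- function(fit, truth, cohort) {
  ari <- mclust::adjustedRandIndex(fit$cluster, truth$labels)
  K <- fit$K
  perm <- align_labels(truth$labels, fit$cluster, K)
  # fitted cluster k corresponds to planted cluster perm[k]
  keep_x <- match(cohort$snp_ids, paste0("snp", seq_along(truth$a[[1L]])))
  keep_y <- match(cohort$roi_ids, paste0("roi", seq_along(truth$b[[1L]])))
  f1 <- function(est, tru) {
    tp <- sum(est & tru)
    if (tp == 0) return(0)
    prec <- tp / sum(est); rec <- tp / sum(tru)
    2 * prec * rec / (prec + rec)
  }
  f1_u <- vapply(seq_len(K), function(k) {
    f1(fit$pairs[[k]]$u != 0, truth$a[[perm[k]]][keep_x] != 0)
  }, numeric(1))
  f1_v <- vapply(seq_len(K), function(k) {
    f1(fit$pairs[[k]]$v != 0, truth$b[[perm[k]]][keep_y] != 0)
  }, numeric(1))
  list(ari = ari, f1_u = mean(f1_u), f1_v = mean(f1_v),
       f1_u_per_cluster = f1_u, f1_v_per_cluster = f1_v)
}

#' Data-driven full-shrinkage bound for the L1 penalty
#'
#' The smallest `lambda` that forces the penalized direction to exactly
#' zero is `2 max_j |a_j' r|`; this returns that bound for the u-step of a
#' cohort at a given starting `v` (the global SVD start by default), a
#' convenient scale for penalty grids.
#'
#' @param cohort A standardized [cohort_pair()].
#' @return List with `lambda_max_u` and `lambda_max_v`.
#' @export
lambda_max <- function(cohort) {
  init <- svd_init(cohort$X, cohort$Y)
  list(lambda_max_u = 2 * max(abs(crossprod(cohort$X, cohort$Y %*% init$v))),
       lambda_max_v = 2 * max(abs(crossprod(cohort$Y, cohort$X %*% init$u))))
}

#' Oracle grid selection of penalties on a planted cohort
#'
#' Fits the clustering over a small grid of `(lambda_u, lambda_v)` values
#' (fractions of the data-derived full-shrinkage bounds) and returns the
#' pair maximizing ARI plus mean support F1 against the planted truth.
#' This is a scoring device for simulation studies, not a data-driven
#' tuning rule.
#'
#' @inheritParams score_recovery
#' @param fractions_u,fractions_v Grid fractions of the shrinkage bounds.
#' @param variant,assign_rule,seed Passed to [scca_cluster()].
#' @param gamma Ridge weight applied to both views for the elastic variant.
#' @return List with `penalties` (the selected [penalty_config()]), `grid`
#'   (all scores) and `best` (the winning row).
#' @export
select_penalties_oracle <- function(cohort, truth,
                                    fractions_u = c(0.05, 0.1, 0.2),
                                    fractions_v = c(0.02, 0.05),
                                    variant = "elastic", gamma = 0.1,
                                    assign_rule = "product", seed = 1L) {
  lm <- lambda_max(cohort)
  K <- length(truth$a)
  rows <- list()
  for (fu in fractions_u) for (fv in fractions_v) {
    pen <- penalty_config(fu * lm$lambda_max_u, fv * lm$lambda_max_v,
                          gamma_u = if (variant == "elastic") gamma else 0,
                          gamma_v = if (variant == "elastic") gamma else 0)
    sc <- tryCatch({
      fit <- scca_cluster(cohort, K, variant, pen, seed = seed,
                          assign_rule = assign_rule)
      score_recovery(fit, truth, cohort)
    }, error = function(e) list(ari = NA_real_, f1_u = NA_real_,
                                f1_v = NA_real_))
    rows[[length(rows) + 1L]] <-
      data.frame(frac_u = fu, frac_v = fv,
                 lambda_u = pen$lambda_u, lambda_v = pen$lambda_v,
                 ari = sc$ari, f1_u = sc$f1_u, f1_v = sc$f1_v,
                 score = sc$ari + (sc$f1_u + sc$f1_v) / 2)
  }
  grid <- do.call(rbind, rows)
  best <- grid[which.max(grid$score), ]
  list(penalties = penalty_config(best$lambda_u, best$lambda_v,
                                  gamma_u = if (variant == "elastic") gamma else 0,
                                  gamma_v = if (variant == "elastic") gamma else 0),
       grid = grid, best = best)
}
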