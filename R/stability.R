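# Reproducibility machinery: ICC on binarized SNP selections, dispersion of
# canonical weights, initialization/bootstrap stability with co-assignment,
# and longitudinal consistency of subtype labels.

#' Binarize a canonical weight vector
#'
#' Non-zero entries (the soft-thresholding solver produces exact zeros) are
#' coded 1, zeros 0, marking which features a run selected.
#'
#' @param u Numeric weight vector.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_weights <- function(u) as.integer(u != 0)

#' Intraclass correlation: two-way mixed, consistency, average measures
#'
#' ICC(3,k) from the two-way targets x raters ANOVA without replication:
#' `(MS_targets - MS_error) / MS_targets`. Targets are features (e.g. SNP
#' positions), raters are repetition runs. Consistency-type: invariant to
#' adding a constant to any rater column.
#'
#' @param ratings Numeric matrix, targets in rows, raters in columns; at
#'   least 2 of each, no missing cells.
#' @return Scalar ICC (at most 1); `NaN` with a warning when the
#'   between-target mean square is zero.
#' @export
icc_consistency_avg <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 targets and 2 raters")
  if (anyNA(ratings)) stop("ratings matrix must have no missing cells")
  grand <- mean(ratings)
  ss_rows <- k * sum((rowMeans(ratings) - grand)^2)
  ss_cols <- n * sum((colMeans(ratings) - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  if (ms_rows == 0) {
    warning("zero between-target variance; ICC undefined")
    return(NaN)
  }
  (ms_rows - ms_err) / ms_rows
}

#' Align cluster labels between two runs
#'
#' Finds the permutation of `1:K` that, applied to `candidate`, maximizes
#' agreement with `reference` (the assignment problem on the K x K
#' contingency table, solved by exhaustive search; exact for K <= 7).
#'
#' @param reference,candidate Integer label vectors over the same subjects.
#' @param K Number of clusters.
#' @return Integer permutation `p` such that `p[candidate]` best matches
#'   `reference`.
#' @export
align_labels <- function(reference, candidate, K) {
  stopifnot(length(reference) == length(candidate))
  if (K > 7L) stop("exhaustive label matching supported for K <= 7")
  tab <- matrix(0L, K, K)
  for (i in seq_along(reference))
    tab[candidate[i], reference[i]] <- tab[candidate[i], reference[i]] + 1L
  perms <- permutations_of(K)
  overlap <- vapply(perms, function(p)
    sum(tab[cbind(seq_len(K), p)]), numeric(1))
  perms[[which.max(overlap)]]
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(K - 1L))
    for (pos in 0:(K - 1L))
      out[[length(out) + 1L]] <- append(p, K, after = pos)
  out
}

#' Repeated-fit stability analysis
#'
#' Refits the clustering `n_rep` times, either with different seeds on the
#' fixed data (`mode = "init"`) or on bootstrap resamples of the subjects
#' (`mode = "bootstrap"`), aligns every run's labels to the first run, and
#' summarizes: per-cluster ICC of the binarized SNP weights across runs,
#' per-feature standard deviation of the canonical weights, the M x M
#' co-assignment frequency matrix, and each subject's predominant-label
#' frequency. For bootstrap runs, a subject pair contributes only to
#' repetitions where both were drawn; pairs never co-drawn are `NA`.
#'
#' @inheritParams scca_cluster
#' @param n_rep Number of repetitions (>= 2).
#' @param mode `"init"` or `"bootstrap"`.
#' @param seed Root seed; per-repetition seeds are derived from it.
#' @param assign_rule Membership rule passed to [scca_cluster()].
#' @param boot_rows Optional list of `n_rep` row-index vectors overriding the
#'   bootstrap draws (e.g. to replay resamples from a manifest).
#' @return A `stability_report` list with elements `labels` (M x n_rep,
#'   aligned; `NA` where a subject was not drawn), `co_assignment`,
#'   `predominant_freq`, `icc_u` (per cluster), `weight_sd_u`,
#'   `weight_sd_v`, `mode`, `n_rep`, `failures`.
#' @export
repeat_fit_stability <- function(cohort, K, variant = c("elastic", "ipls"),
                                 penalties = penalty_config(), n_rep = 100L,
                                 mode = c("init", "bootstrap"), seed = 1L,
                                 max_outer_iter = 100L, perturb_scale = 0.1,
                                 assign_rule = c("residual", "product"),
                                 boot_rows = NULL) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  assign_rule <- match.arg(assign_rule)
  stopifnot(n_rep >= 2L)
  M <- nrow(cohort$X)
  rep_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, n_rep))

  labels <- matrix(NA_integer_, M, n_rep)
  U <- array(NA_real_, dim = c(length(cohort$snp_ids), K, n_rep))
  V <- array(NA_real_, dim = c(length(cohort$roi_ids), K, n_rep))
  failures <- 0L
  for (r in seq_len(n_rep)) {
    rows <- if (mode == "bootstrap") {
      if (!is.null(boot_rows)) boot_rows[[r]]
      else withr_seed(rep_seeds[r] %% 1000003L + 7L,
                      sample.int(M, M, replace = TRUE))
    } else seq_len(M)
    dat <- if (mode == "bootstrap") subset_resample(cohort, rows) else cohort
    fit <- tryCatch(
      scca_cluster(dat, K, variant, penalties,
                   seed = rep_seeds[r],
                   max_outer_iter = max_outer_iter,
                   perturb_scale = perturb_scale, assign_rule = assign_rule),
      error = function(e) { warning("repetition ", r, " failed: ",
                                    conditionMessage(e)); NULL })
    if (is.null(fit)) { failures <- failures + 1L; next }
    # map row labels back to original subjects (duplicates agree by
    # construction: assignment is a deterministic function of the row data)
    lab <- rep(NA_integer_, M)
    lab[rows] <- fit$cluster
    labels[, r] <- lab
    cf <- coef(fit)
    U[, , r] <- cf$u
    V[, , r] <- cf$v
  }
  if (failures > 0.2 * n_rep)
    stop("more than 20% of stability repetitions failed")
  ok <- which(colSums(!is.na(labels)) > 0L)

  # align every run to the first successful one: permute cluster labels,
  # reorder the weight columns to match, and resolve the joint (u, v) sign
  # freedom against the reference run so weight dispersions are meaningful
  ref <- labels[, ok[1L]]
  for (r in ok[-1L]) {
    both <- which(!is.na(ref) & !is.na(labels[, r]))
    perm <- align_labels(ref[both], labels[both, r], K)
    labels[, r] <- perm[labels[, r]]
    inv <- order(perm)  # column k of run r corresponds to cluster perm[k]
    U[, , r] <- U[, inv, r]
    V[, , r] <- V[, inv, r]
    for (k in seq_len(K)) {
      agree <- sum(U[, k, r] * U[, k, ok[1L]], na.rm = TRUE) +
        sum(V[, k, r] * V[, k, ok[1L]], na.rm = TRUE)
      if (!is.na(agree) && agree < 0) {
        U[, k, r] <- -U[, k, r]
        V[, k, r] <- -V[, k, r]
      }
    }
  }

  co <- co_assignment_matrix(labels[, ok, drop = FALSE])
  pred <- apply(labels[, ok, drop = FALSE], 1L, function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0L) return(NA_real_)
    max(tabulate(z, K)) / length(z)
  })
  icc_u <- vapply(seq_len(K), function(k) {
    B <- apply(U[, k, ok, drop = FALSE], c(1L, 3L), function(w) as.integer(w != 0))
    tryCatch(icc_consistency_avg(B), warning = function(w) NaN)
  }, numeric(1))
  sd0 <- function(A) apply(A[, , ok, drop = FALSE], c(1L, 2L), stats::sd)
  structure(list(labels = labels, co_assignment = co,
                 predominant_freq = pred, icc_u = icc_u,
                 weight_sd_u = sd0(U), weight_sd_v = sd0(V),
                 mode = mode, n_rep = n_rep, failures = failures,
                 subject_ids = cohort$subject_ids, seed = seed),
            class = "stability_report")
}

# Bootstrap resample keeping row provenance; subject IDs must stay unique
# for cohort_pair, so duplicates get a draw suffix (labels are mapped back
# by row position, not ID).
subset_resample <- function(cohort, rows) {
  out <- subset_cohort(cohort, rows)
  out$subject_ids <- make.unique(out$subject_ids)
  rownames(out$X) <- rownames(out$Y) <- out$subject_ids
  out
}

# Same-cluster frequency over repetitions; entry (i, j) uses only
# repetitions where both i and j have a label.
co_assignment_matrix <- function(labels) {
  M <- nrow(labels)
  present <- !is.na(labels)
  n_both <- tcrossprod(present * 1)
  K <- max(labels, na.rm = TRUE)
  same <- matrix(0, M, M)
  for (k in seq_len(K)) {
    ind <- (labels == k) & present
    same <- same + tcrossprod(ind * 1)
  }
  co <- same / n_both
  co[n_both == 0] <- NA_real_
  diag(co) <- ifelse(diag(n_both) > 0, 1, NA_real_)
  co
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report (%s, %d repetitions, %d failures)\n",
              x$mode, x$n_rep, x$failures))
  cat("  per-cluster ICC of binarized SNP selections:",
      paste(sprintf("%.3f", x$icc_u), collapse = ", "), "\n")
  cat(sprintf("  mean predominant-label frequency: %.3f\n",
              mean(x$predominant_freq, na.rm = TRUE)))
  cat(sprintf("  mean off-diagonal co-assignment: %.3f\n",
              mean(x$co_assignment[upper.tri(x$co_assignment)], na.rm = TRUE)))
  invisible(x)
}

#' Longitudinal consistency of subtype labels
#'
#' Proportion of subjects with at least two visits whose label is identical
#' at every visit. Single-visit subjects are excluded and counted.
#'
#' @param visit_labels Integer label per scan row (same order as the cohort
#'   rows the longitudinal index points into).
#' @param index A `longitudinal_index` (see [load_longitudinal()]).
#' @return Scalar in `[0, 1]` with attributes `n_multi_visit` and
#'   `n_single_visit`; `NaN` with a warning when no subject has two visits.
#' @export
longitudinal_consistency <- function(visit_labels, index) {
  labs <- visit_labels[index$row_index]
  per_subj <- split(labs, index$subject_id)
  multi <- per_subj[lengths(per_subj) >= 2L]
  n_single <- sum(lengths(per_subj) == 1L)
  if (length(multi) == 0L) {
    warning("no multi-visit subjects; consistency undefined")
    out <- NaN
  } else {
    out <- mean(vapply(multi, function(z) all(z == z[1L]), logical(1)))
  }
  attr(out, "n_multi_visit") <- length(multi)
  attr(out, "n_single_visit") <- n_single
  out
}

#' Longitudinal subtype-consistency pipeline
#'
#' Assigns every scan of an expanded (multi-visit) cohort to a subtype with
#' a fitted model and returns the proportion of multi-visit subjects keeping
#' the same subtype across all visits.
#'
#' @param model A fitted [scca_cluster()] model.
#' @param cohort_long Expanded cohort with one row per scan, standardized
#'   over the pooled set of all scans.
#' @param index The matching `longitudinal_index`.
#' @return As [longitudinal_consistency()].
#' @export
longitudinal_pipeline <- function(model, cohort_long, index) {
  labs <- predict(model, cohort_long)
  longitudinal_consistency(labs, index)
}
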