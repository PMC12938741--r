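# Seeded synthetic two-view cohorts with planted cluster-specific sparse
# canonical structure. Stands in for restricted imaging-genetics inputs so
# the whole pipeline is testable offline.

sparse_loading <- function(len, support_idx) {
  w <- numeric(len)
  repeat {
    vals <- stats::rnorm(length(support_idx))
    if (any(vals != 0)) break
  }
  w[support_idx] <- vals
  unit_rescale(w)
}

draw_supports <- function(K, support, total) {
  if (K * support <= total) {
    idx <- sample.int(total, K * support)
    split(idx, rep(seq_len(K), each = support))
  } else {
    warning("disjoint supports infeasible (K * support > features); ",
            "sampling overlapping supports")
    lapply(seq_len(K), function(k) sample.int(total, support))
  }
}

#' Simulate a two-view cohort with planted sparse canonical structure
#'
#' Each cluster k has unit-norm sparse loading vectors `a_k` (genetic,
#' `support_p` non-zeros) and `b_k` (imaging, `support_n` non-zeros), with
#' supports disjoint across clusters when feasible. A subject i in cluster k
#' draws a latent factor `t_i ~ N(0, 1)` and
#' `X_i = t_i a_k' + noise`, `Y_i = t_i b_k' + noise`
#' (independent Gaussian noise with sd `noise_sd`), so within each cluster
#' the canonical scores `X a_k` and `Y b_k` share the latent factor with
#' population correlation `1 / (1 + noise_sd^2)`. The returned cohort is
#' z-scored via [standardize()] (note: with `noise_sd = 0` the off-support
#' columns are constant and are dropped there).
#'
#' An optional dosage mode instead generates the genetic view as
#' `Binomial(2, p_j)` risk-allele dosages with cluster-specific allele
#' frequency shifts on the support, mimicking additive SNP coding.
#'
#' @param M,N,P Subjects, imaging features (ROIs), genetic features (SNPs).
#' @param K Number of planted clusters.
#' @param support_p,support_n Non-zeros per genetic / imaging loading.
#' @param noise_sd Noise standard deviation (default 0.2).
#' @param cluster_props Cluster proportions (must sum to 1; equal by
#'   default). Sizes are deterministic (largest-remainder rounding).
#' @param seed Integer seed.
#' @param dosage_mode Generate genetic view as binomial dosages.
#' @param dosage_shift Allele-frequency shift on support SNPs (dosage mode).
#' @return List with `cohort` (standardized [cohort_pair()]) and `truth`
#'   (a `synthetic_truth`: `labels`, loading lists `a`, `b`, `latent`,
#'   `noise_sd`, `seed`, plus the pre-standardization matrices `raw_X`,
#'   `raw_Y` for validation).
#' @export
simulate_cohort <- function(M = 400L, N = 20L, P = 100L, K = 4L,
                            support_p = 5L, support_n = 4L, noise_sd = 0.2,
                            cluster_props = rep(1 / K, K), seed = 1L,
                            dosage_mode = FALSE, dosage_shift = 0.15) {
  stopifnot(support_p <= P, support_n <= N, noise_sd >= 0,
            length(cluster_props) == K)
  if (abs(sum(cluster_props) - 1) > 1e-8)
    stop("cluster_props must sum to 1")
  sizes <- floor(M * cluster_props)
  rem <- M - sum(sizes)
  if (rem > 0) {
    frac <- M * cluster_props - floor(M * cluster_props)
    add <- order(-frac)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1L
  }
  if (any(sizes < 2L)) stop("every cluster needs at least 2 subjects")
  labels <- rep(seq_len(K), times = sizes)

  withr_seed(seed, {
    sup_a <- draw_supports(K, support_p, P)
    sup_b <- draw_supports(K, support_n, N)
    a <- lapply(sup_a, sparse_loading, len = P)
    b <- lapply(sup_b, sparse_loading, len = N)
    latent <- stats::rnorm(M)
    Y <- t(vapply(seq_len(M), function(i) latent[i] * b[[labels[i]]],
                  numeric(N))) + matrix(stats::rnorm(M * N, sd = noise_sd), M, N)
    if (dosage_mode) {
      p0 <- stats::runif(P, 0.1, 0.5)
      X <- matrix(0, M, P)
      for (i in seq_len(M)) {
        p <- p0
        sup <- sup_a[[labels[i]]]
        p[sup] <- pmin(pmax(p[sup] + dosage_shift * sign(a[[labels[i]]][sup]),
                            0.02), 0.98)
        X[i, ] <- stats::rbinom(P, 2L, p)
      }
    } else {
      X <- t(vapply(seq_len(M), function(i) latent[i] * a[[labels[i]]],
                    numeric(P))) +
        matrix(stats::rnorm(M * P, sd = noise_sd), M, P)
    }
  })
  colnames(X) <- paste0("snp", seq_len(P))
  colnames(Y) <- paste0("roi", seq_len(N))
  ids <- sprintf("subj%04d", seq_len(M))
  raw <- cohort_pair(X, Y, ids, standardized = FALSE)
  cohort <- standardize(raw)
  truth <- structure(list(labels = labels, a = a, b = b,
                          support_a = sup_a, support_b = sup_b,
                          latent = latent, noise_sd = noise_sd, seed = seed,
                          raw_X = X, raw_Y = Y),
                     class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' Simulate repeat visits for every subject
#'
#' Re-noises each subject's noiseless base signal (`t_i a_k'`, `t_i b_k'`)
#' independently per visit with sd `visit_noise_sd`; cluster labels are
#' constant across visits by construction. The expanded cohort is z-scored
#' over the pooled set of all scans.
#'
#' @param truth A `synthetic_truth` from [simulate_cohort()].
#' @param n_visits Visits per subject (>= 2).
#' @param visit_noise_sd Per-visit noise sd (0 makes all visits identical).
#' @param seed Integer seed.
#' @return List with `cohort` (standardized, one row per scan) and `index`
#'   (a `longitudinal_index`).
#' @export
simulate_longitudinal <- function(truth, n_visits = 2L, visit_noise_sd = 0.2,
                                  seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_visits >= 2L)
  M <- length(truth$labels)
  P <- length(truth$a[[1L]]); N <- length(truth$b[[1L]])
  base_X <- t(vapply(seq_len(M), function(i)
    truth$latent[i] * truth$a[[truth$labels[i]]], numeric(P)))
  base_Y <- t(vapply(seq_len(M), function(i)
    truth$latent[i] * truth$b[[truth$labels[i]]], numeric(N)))
  rows <- M * n_visits
  withr_seed(seed, {
    X <- base_X[rep(seq_len(M), each = n_visits), , drop = FALSE] +
      matrix(stats::rnorm(rows * P, sd = visit_noise_sd), rows, P)
    Y <- base_Y[rep(seq_len(M), each = n_visits), , drop = FALSE] +
      matrix(stats::rnorm(rows * N, sd = visit_noise_sd), rows, N)
  })
  colnames(X) <- paste0("snp", seq_len(P))
  colnames(Y) <- paste0("roi", seq_len(N))
  subj <- sprintf("subj%04d", rep(seq_len(M), each = n_visits))
  ids <- paste0(subj, "_v", rep(seq_len(n_visits), times = M))
  cohort <- standardize(cohort_pair(X, Y, ids, standardized = FALSE))
  # standardize() can drop columns but never rows, so row indices are stable
  index <- longitudinal_index(subj, rep(seq_len(n_visits), times = M),
                              seq_len(rows), cohort)
  list(cohort = cohort, index = index)
}
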