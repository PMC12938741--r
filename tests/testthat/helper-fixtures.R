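# Shared fixtures: all built in code at test time.

# Tiny aligned CSV pair on disk; returns the two paths.
write_tiny_views <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                             ids_img = c("A", "B", "C"),
                             ids_gen = ids_img, seed = 42) {
  set.seed(seed)
  img <- data.frame(subject_id = ids_img,
                    roi1 = round(rnorm(length(ids_img)), 6),
                    roi2 = round(rnorm(length(ids_img)), 6))
  gen <- data.frame(subject_id = ids_gen,
                    snp1 = sample(0:2, length(ids_gen), replace = TRUE),
                    snp2 = sample(0:2, length(ids_gen), replace = TRUE),
                    snp3 = round(runif(length(ids_gen), 0, 2), 6))
  ip <- file.path(dir, "imaging.csv"); gp <- file.path(dir, "genetic.csv")
  write.csv(img, ip, row.names = FALSE, quote = FALSE)
  write.csv(gen, gp, row.names = FALSE, quote = FALSE)
  list(imaging = ip, genetic = gp, dir = dir)
}

# Small in-memory cohort with arbitrary (non-planted) structure.
random_cohort <- function(M = 30, P = 8, N = 5, seed = 1, standardized = TRUE) {
  set.seed(seed)
  co <- cohort_pair(matrix(rnorm(M * P), M, P,
                           dimnames = list(NULL, paste0("snp", 1:P))),
                    matrix(rnorm(M * N), M, N,
                           dimnames = list(NULL, paste0("roi", 1:N))),
                    sprintf("s%03d", 1:M))
  if (standardized) standardize(co) else co
}

# Independent term-by-term cost oracle, written separately from the solver.
cost_oracle <- function(X, Y, u, v, lu, lv, gu = 0, gv = 0) {
  resid <- as.numeric(X %*% u) - as.numeric(Y %*% v)
  sum(resid * resid) + lu * sum(abs(u)) + lv * sum(abs(v)) +
    gu * sum(u * u) + gv * sum(v * v)
}

# Brute-force two-way ANOVA ICC(3,k) oracle via stats::aov.
icc_aov_oracle <- function(ratings) {
  df <- data.frame(rating = as.vector(ratings),
                   target = factor(rep(seq_len(nrow(ratings)),
                                       times = ncol(ratings))),
                   rater = factor(rep(seq_len(ncol(ratings)),
                                      each = nrow(ratings))))
  tab <- summary(stats::aov(rating ~ target + rater, data = df))[[1]]
  ms <- tab[["Mean Sq"]]
  (ms[1] - ms[3]) / ms[1]
}

expect_unit_norm <- function(w, tol = 1e-10) {
  expect_equal(sqrt(sum(w^2)), 1, tolerance = tol)
}
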