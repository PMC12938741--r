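# Subtype characterization: within-subtype mean z-score maps (0-1
# normalized across subtypes), SNP dosage profiles and rankings,
# cross-modality cross-tabulation, pathway/cell-type proportions.

#' Within-subtype column means of one view
#'
#' @param cohort A [cohort_pair()].
#' @param labels Integer subtype labels in `1:K`.
#' @param view `"imaging"` or `"genetic"`.
#' @param K Number of subtypes (default `max(labels)`).
#' @return K x F matrix of within-subtype mean z-scores.
#' @export
subtype_means <- function(cohort, labels, view = c("imaging", "genetic"),
                          K = max(labels)) {
  view <- match.arg(view)
  m <- if (view == "imaging") cohort$Y else cohort$X
  out <- matrix(NA_real_, K, ncol(m), dimnames = list(paste0("S", 1:K),
                                                      colnames(m)))
  for (k in seq_len(K)) {
    rows <- which(labels == k)
    if (length(rows) == 0L) stop("subtype ", k, " is empty")
    out[k, ] <- colMeans(m[rows, , drop = FALSE])
  }
  out
}

#' Global min-max normalization to [0, 1]
#'
#' One rescaling `(x - min) / (max - min)` over all entries, so values stay
#' comparable across subtypes; both endpoints are attained.
#'
#' @param m Non-constant numeric matrix.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_01 <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) stop("constant matrix: min-max normalization undefined")
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Rank SNPs within each subtype by mean dosage magnitude
#'
#' Orders SNPs by descending absolute within-subtype mean z-scored dosage
#' (ties broken by SNP ID), keeping the signed value in the output.
#'
#' @param snp_means K x P matrix from [subtype_means()] (genetic view).
#' @param top_n How many SNPs to keep per subtype.
#' @return Data frame with columns `subtype`, `rank`, `snp_id`,
#'   `mean_dosage`.
#' @export
rank_snps <- function(snp_means, top_n = 60L) {
  stopifnot(top_n <= ncol(snp_means))
  ids <- colnames(snp_means)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(snp_means)))
  out <- lapply(seq_len(nrow(snp_means)), function(k) {
    v <- snp_means[k, ]
    ord <- order(-abs(v), ids)[seq_len(top_n)]
    data.frame(subtype = k, rank = seq_len(top_n), snp_id = ids[ord],
               mean_dosage = unname(v[ord]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-tabulate two subtype labelings
#'
#' Entry `(a, b)` is the proportion of subjects with label `a` in the first
#' labeling among subjects with label `b` in the second, so each column sums
#' to 1 (the layout used to report tau-subtype composition within each
#' amyloid subtype).
#'
#' @param labels_a,labels_b Integer label vectors over the same subjects.
#' @param Ka,Kb Numbers of classes (default the observed maxima).
#' @return Ka x Kb proportion matrix; empty `b`-classes give `NaN` columns
#'   with a warning.
#' @export
cross_tabulate <- function(labels_a, labels_b,
                           Ka = max(labels_a), Kb = max(labels_b)) {
  stopifnot(length(labels_a) == length(labels_b))
  counts <- matrix(0, Ka, Kb,
                   dimnames = list(paste0("A", 1:Ka), paste0("B", 1:Kb)))
  for (i in seq_along(labels_a))
    counts[labels_a[i], labels_b[i]] <- counts[labels_a[i], labels_b[i]] + 1
  nb <- colSums(counts)
  if (any(nb == 0)) warning("empty class in second labeling: ",
                            paste(which(nb == 0), collapse = ", "))
  sweep(counts, 2L, nb, "/")
}

#' Pathway or cell-type composition of the subtype dosage profiles
#'
#' For each subtype, annotated SNPs are grouped by category and weighted by
#' the absolute within-subtype mean z-scored dosage; category masses are
#' normalized to sum to 1. Set `weighted = FALSE` to count SNPs instead
#' (every selected SNP weight 1). Unannotated SNPs are excluded and counted.
#'
#' @param snp_means K x P matrix from [subtype_means()] (genetic view).
#' @param annotation An `annotation_map` (see [load_annotation()]).
#' @param axis `"pathway"` or `"cell_type"`.
#' @param weighted Weight categories by absolute mean dosage (default) or
#'   by SNP counts.
#' @return K x C matrix of proportions (rows sum to 1) with attribute
#'   `n_unannotated`.
#' @export
category_proportions <- function(snp_means, annotation,
                                 axis = c("pathway", "cell_type"),
                                 weighted = TRUE) {
  axis <- match.arg(axis)
  ids <- colnames(snp_means)
  hit <- match(ids, annotation$snp_id)
  annotated <- which(!is.na(hit))
  if (length(annotated) == 0L) stop("no annotated SNPs")
  cats <- annotation[[axis]][hit[annotated]]
  lev <- sort(unique(annotation[[axis]]))
  out <- matrix(0, nrow(snp_means), length(lev),
                dimnames = list(rownames(snp_means), lev))
  for (k in seq_len(nrow(snp_means))) {
    w <- if (weighted) abs(snp_means[k, annotated]) else
      as.numeric(snp_means[k, annotated] != 0)
    mass <- tapply(w, factor(cats, levels = lev), sum, default = 0)
    tot <- sum(mass)
    if (tot == 0) { out[k, ] <- NaN; next }
    out[k, ] <- mass / tot
  }
  attr(out, "n_unannotated") <- length(ids) - length(annotated)
  out
}

#' Full subtype profile of a fitted model
#'
#' Bundles the imaging mean z-score maps (raw and 0-1 normalized across
#' subtypes), the SNP dosage profiles, the top-ranked SNPs per subtype, and
#' the subtype sizes. If an unstandardized cohort is supplied, raw-scale
#' (e.g. SUVR) mean profiles are included as well.
#'
#' @param cohort The standardized [cohort_pair()] the model was fitted on.
#' @param model A fitted [scca_cluster()] model (or an integer label vector).
#' @param top_n SNPs to rank per subtype.
#' @param raw_cohort Optional unstandardized cohort for raw-scale profiles.
#' @return A `subtype_profile` list.
#' @export
subtype_profile <- function(cohort, model, top_n = min(60L, length(cohort$snp_ids)),
                            raw_cohort = NULL) {
  labels <- if (inherits(model, "scca_cluster")) model$cluster else model
  K <- if (inherits(model, "scca_cluster")) model$K else max(labels)
  im <- subtype_means(cohort, labels, "imaging", K)
  sm <- subtype_means(cohort, labels, "genetic", K)
  out <- list(imaging_means = im,
              imaging_means_01 = minmax_01(im),
              snp_means = sm,
              snp_rank = rank_snps(sm, top_n),
              counts = tabulate(labels, K))
  if (!is.null(raw_cohort)) {
    out$imaging_means_raw <- subtype_means(raw_cohort, labels, "imaging", K)
    out$snp_means_raw <- subtype_means(raw_cohort, labels, "genetic", K)
  }
  structure(out, class = "subtype_profile")
}

#' @export
print.subtype_profile <- function(x, ...) {
  cat("Subtype profile:", nrow(x$imaging_means), "subtypes, sizes",
      paste(x$counts, collapse = ", "), "\n")
  cat("Normalized imaging mean z-scores (0-1 across subtypes):\n")
  print(round(x$imaging_means_01, 3))
  invisible(x)
}

#' Heatmap of normalized subtype imaging profiles
#'
#' @param x A `subtype_profile`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.subtype_profile <- function(x, ...) {
  m <- x$imaging_means_01
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  xlab = "ROI", ylab = "subtype", axes = FALSE,
                  main = "Mean imaging z-scores (0-1 normalized)", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m))
  invisible(x)
}
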