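#' Construct an aligned two-view cohort
#'
#' A `cohort_pair` holds a genetic view `X` (subjects x SNPs, risk-allele
#' dosages) and an imaging view `Y` (subjects x ROIs, e.g. regional PET SUVRs)
#' over the same subjects in the same row order.
#'
#' @param X Numeric matrix, M x P (genetic view).
#' @param Y Numeric matrix, M x N (imaging view).
#' @param subject_ids Character vector of length M, unique.
#' @param snp_ids,roi_ids Column identifiers; default to the matrix colnames.
#' @param standardized Logical flag; `TRUE` once each column is z-scored.
#' @return An object of class `cohort_pair`.
#' @export
cohort_pair <- function(X, Y, subject_ids,
                        snp_ids = colnames(X), roi_ids = colnames(Y),
                        standardized = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  subject_ids <- as.character(subject_ids)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows (subjects)")
  if (length(subject_ids) != nrow(X))
    stop("subject_ids length must equal the number of rows")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ID: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyNA(X) || anyNA(Y))
    stop("missing values in cohort matrices; impute or drop before construction")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(X)))
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(ncol(Y)))
  rownames(X) <- rownames(Y) <- subject_ids
  colnames(X) <- snp_ids; colnames(Y) <- roi_ids
  structure(list(X = X, Y = Y, subject_ids = subject_ids,
                 snp_ids = as.character(snp_ids),
                 roi_ids = as.character(roi_ids),
                 standardized = isTRUE(standardized)),
            class = "cohort_pair")
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat("Two-view cohort:", nrow(x$X), "subjects,",
      ncol(x$X), "SNPs,", ncol(x$Y), "ROIs\n")
  cat("  standardized:", x$standardized, "\n")
  invisible(x)
}

#' @export
dim.cohort_pair <- function(x) c(nrow(x$X), ncol(x$X), ncol(x$Y))

# Row subset preserving metadata; used by the cluster engine and bootstrap.
subset_cohort <- function(cohort, rows) {
  out <- cohort
  out$X <- cohort$X[rows, , drop = FALSE]
  out$Y <- cohort$Y[rows, , drop = FALSE]
  out$subject_ids <- cohort$subject_ids[rows]
  out
}

read_view_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("matrix file needs an ID column plus features: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate subject ID in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell in %s at row %d (subject %s), column '%s'",
                 basename(path), bad[1, 1], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  rownames(num) <- ids
  num
}

#' Read a PLINK additive-dosage export (.raw)
#'
#' Reads the whitespace-delimited `.raw` format written by
#' `plink --recode A`: six leading columns (FID, IID, PAT, MAT, SEX,
#' PHENOTYPE) followed by one `SNP_<allele>` dosage column per variant.
#' Subjects are keyed on IID and the counted-allele suffix is stripped from
#' the SNP identifiers.
#'
#' @param path Path to the `.raw` file.
#' @return Numeric dosage matrix with subject IDs as rownames.
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(df)[1:6]))
    stop("not a PLINK .raw export (missing ", paste(setdiff(need, names(df)),
         collapse = ", "), ")")
  ids <- as.character(df$IID)
  if (anyDuplicated(ids))
    stop("duplicate subject ID in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dos <- as.matrix(df[, -(1:6), drop = FALSE])
  storage.mode(dos) <- "double"
  colnames(dos) <- sub("_[ACGTDI0-9]+$", "", colnames(dos))
  rownames(dos) <- ids
  dos
}

#' Load and align the imaging and genetic views of a cohort
#'
#' Both files are delimited text with a header row of feature IDs and a first
#' column of subject IDs (the genetic view may instead be a PLINK `.raw`
#' export). Rows are restricted to the subjects present in both files, in the
#' imaging file's order.
#'
#' @param imaging_path,genetic_path Paths to the two matrices.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param missing One of `"reject"` (drop subjects with any missing value,
#'   with a message) or `"impute"` (column-mean imputation).
#' @return An unstandardized [cohort_pair()].
#' @export
load_cohort <- function(imaging_path, genetic_path, sep = NULL,
                        missing = c("reject", "impute")) {
  missing <- match.arg(missing)
  Y <- read_view_matrix(imaging_path, sep)
  X <- if (grepl("\\.raw$", genetic_path)) read_plink_raw(genetic_path)
       else read_view_matrix(genetic_path, sep)
  ids <- rownames(Y)[rownames(Y) %in% rownames(X)]
  if (length(ids) == 0L)
    stop("no shared subject IDs between imaging and genetic files")
  X <- X[ids, , drop = FALSE]
  Y <- Y[ids, , drop = FALSE]
  na_rows <- which(rowSums(is.na(X)) + rowSums(is.na(Y)) > 0L)
  if (length(na_rows) > 0L) {
    if (missing == "reject") {
      message("dropping ", length(na_rows), " subject(s) with missing values: ",
              paste(ids[na_rows], collapse = ", "))
      keep <- setdiff(seq_along(ids), na_rows)
      if (length(keep) == 0L) stop("all subjects have missing values")
      X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
      ids <- ids[keep]
    } else {
      X <- impute_colmean(X); Y <- impute_colmean(Y)
    }
  }
  cohort_pair(X, Y, ids, standardized = FALSE)
}

impute_colmean <- function(m) {
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- mean(m[!nas, j])
  }
  m
}

#' Z-score the columns of both views
#'
#' Each retained column is replaced by `(x - mean(x)) / sd(x)` using the
#' sample (M-1) standard deviation, computed over the whole cohort.
#' Zero-variance columns carry no between-subject signal and would be
#' degenerate predictors for the penalized solvers, so they are dropped with
#' a message.
#'
#' @param cohort An unstandardized [cohort_pair()].
#' @return A standardized `cohort_pair` (possibly with fewer columns).
#' @export
standardize <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_pair"))
  if (cohort$standardized) stop("cohort is already standardized")
  if (nrow(cohort$X) < 2L)
    stop("standardization needs at least 2 subjects (sd undefined)")
  zs <- function(m, label) {
    mu <- colMeans(m)
    sd <- apply(m, 2L, stats::sd)
    drop <- which(sd == 0)
    if (length(drop) > 0L) {
      message("dropping ", length(drop), " zero-variance ", label,
              " column(s): ", paste(colnames(m)[drop], collapse = ", "))
      m <- m[, -drop, drop = FALSE]; mu <- mu[-drop]; sd <- sd[-drop]
    }
    if (ncol(m) == 0L) stop("all ", label, " columns have zero variance")
    sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
  }
  X <- zs(cohort$X, "genetic")
  Y <- zs(cohort$Y, "imaging")
  cohort_pair(X, Y, cohort$subject_ids, standardized = TRUE)
}

#' Write a cohort's views back to CSV
#'
#' @param cohort A [cohort_pair()].
#' @param imaging_path,genetic_path Output paths.
#' @export
write_cohort <- function(cohort, imaging_path, genetic_path) {
  wr <- function(m, path) {
    df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  wr(cohort$Y, imaging_path)
  wr(cohort$X, genetic_path)
  invisible(c(imaging_path, genetic_path))
}

#' Read a longitudinal visit index
#'
#' CSV with columns `subject_id`, `visit_order` (integer, 0-based or 1-based),
#' and `row_index` (1-based row into the cohort matrices). Visits are sorted
#' by `visit_order` within subject.
#'
#' @param path CSV path.
#' @param cohort The [cohort_pair()] the row indices refer to.
#' @return A `longitudinal_index` data frame; single-visit subjects are kept
#'   but flagged in the `multi_visit` column.
#' @export
load_longitudinal <- function(path, cohort) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit_order", "row_index")
  if (!all(need %in% names(df)))
    stop("longitudinal table must have columns: ", paste(need, collapse = ", "))
  longitudinal_index(df$subject_id, df$visit_order, df$row_index, cohort)
}

#' @rdname load_longitudinal
#' @param subject_id,visit_order,row_index Vectors defining the index.
#' @export
longitudinal_index <- function(subject_id, visit_order, row_index, cohort) {
  df <- data.frame(subject_id = as.character(subject_id),
                   visit_order = as.integer(visit_order),
                   row_index = as.integer(row_index),
                   stringsAsFactors = FALSE)
  M <- nrow(cohort$X)
  if (any(df$row_index < 1L | df$row_index > M))
    stop("row_index out of bounds (cohort has ", M, " rows)")
  if (anyDuplicated(df[, c("subject_id", "visit_order")]))
    stop("duplicate (subject_id, visit_order) pair in longitudinal index")
  df <- df[order(df$subject_id, df$visit_order), , drop = FALSE]
  rownames(df) <- NULL
  nv <- table(df$subject_id)
  df$multi_visit <- nv[df$subject_id] >= 2L
  if (any(!df$multi_visit))
    message(sum(tapply(df$multi_visit, df$subject_id, all) == FALSE),
            " single-visit subject(s) are uninformative for consistency")
  class(df) <- c("longitudinal_index", "data.frame")
  df
}

#' Read a SNP annotation table
#'
#' CSV with columns `snp_id`, `gene`, `pathway`, `cell_type`; each annotated
#' SNP maps to exactly one pathway and one cell-type category.
#'
#' @param path CSV path.
#' @return An `annotation_map` data frame.
#' @export
load_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "gene", "pathway", "cell_type")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stop("SNP annotated more than once: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  class(df) <- c("annotation_map", "data.frame")
  df
}
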