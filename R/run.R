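# Config-driven runners tying the modules into reproducible runs.
# Each runner validates its config, executes, writes its outputs plus a
# manifest (config, seed, input hashes, package version) so a run can be
# reproduced exactly; inst/exec/sccaclust is a thin shell wrapper.

#' Build and validate a run configuration
#'
#' @param imaging_path,genetic_path Input view matrices (genetic may be a
#'   PLINK `.raw`).
#' @param out_dir Output directory (created if missing).
#' @param variant `"elastic"` or `"ipls"`.
#' @param k Number of clusters.
#' @param lambda_u,lambda_v,gamma_u,gamma_v Penalty weights.
#' @param seed Root seed for all randomness in the run.
#' @param n_rep Repetitions for stability runs.
#' @param mode Stability mode, `"init"` or `"bootstrap"`.
#' @param longitudinal_path Optional visit-index CSV.
#' @param annotation_path Optional SNP annotation CSV.
#' @param ... Additional fields (e.g. simulation sizes `M`, `N`, `P`,
#'   `noise_sd`, `n_visits`, `top_n`, `perturb_scale`).
#' @return A validated `scca_config` list.
#' @export
scca_config <- function(imaging_path = NULL, genetic_path = NULL,
                        out_dir = ".", variant = "elastic", k = 2L,
                        lambda_u = 1, lambda_v = lambda_u / 10,
                        gamma_u = 0, gamma_v = 0, seed = 1L, n_rep = 10L,
                        mode = "init", longitudinal_path = NULL,
                        annotation_path = NULL, ...) {
  variant <- match.arg(variant, c("elastic", "ipls"))
  mode <- match.arg(mode, c("init", "bootstrap"))
  stopifnot(k >= 1, n_rep >= 2, seed == floor(seed))
  cfg <- c(list(imaging_path = imaging_path, genetic_path = genetic_path,
                out_dir = out_dir, variant = variant, k = as.integer(k),
                lambda_u = lambda_u, lambda_v = lambda_v,
                gamma_u = gamma_u, gamma_v = gamma_v,
                seed = as.integer(seed), n_rep = as.integer(n_rep),
                mode = mode, longitudinal_path = longitudinal_path,
                annotation_path = annotation_path),
           list(...))
  if (cfg$variant == "ipls" && (cfg$gamma_u != 0 || cfg$gamma_v != 0))
    stop("ipls variant requires gamma_u = gamma_v = 0")
  structure(cfg, class = "scca_config")
}

config_penalties <- function(cfg) {
  penalty_config(cfg$lambda_u, cfg$lambda_v, cfg$gamma_u, cfg$gamma_v)
}

cfg_get <- function(cfg, name, default) {
  if (!is.null(cfg[[name]])) cfg[[name]] else default
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  inputs <- c(cfg$imaging_path, cfg$genetic_path, cfg$longitudinal_path,
              cfg$annotation_path)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  hashes <- if (length(inputs) > 0L)
    as.list(tools::md5sum(unlist(inputs))) else list()
  cfg_list <- Filter(Negate(is.null), unclass(cfg))
  manifest <- c(list(package = "sccaclust",
                     version = as.character(utils::packageVersion("sccaclust")),
                     config = cfg_list, input_md5 = hashes),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(z) formatC(z, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

load_standardized <- function(cfg) {
  if (is.null(cfg$imaging_path) || is.null(cfg$genetic_path))
    stop("config must set imaging_path and genetic_path")
  standardize(load_cohort(cfg$imaging_path, cfg$genetic_path))
}

#' Run the full subtyping pipeline from a configuration
#'
#' Loads and standardizes the two views, fits the SCCA clustering model,
#' and writes: `membership.csv` (subject, subtype), `canonical_u.csv` /
#' `canonical_v.csv` (feature, per-subtype weight), `trajectory.csv`,
#' subtype profile CSVs, and `manifest.json`.
#'
#' @param cfg An [scca_config()].
#' @return The fitted model, invisibly.
#' @export
run_fit <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_standardized(cfg)
  fit <- scca_cluster(cohort, cfg$k, cfg$variant, config_penalties(cfg),
                      seed = cfg$seed,
                      perturb_scale = cfg_get(cfg, "perturb_scale", 0.1),
                      assign_rule = cfg_get(cfg, "assign_rule", "residual"))
  write_num_csv(data.frame(subject_id = cohort$subject_ids,
                           subtype = fit$cluster),
                file.path(cfg$out_dir, "membership.csv"))
  cf <- coef(fit)
  write_num_csv(data.frame(feature_id = rownames(cf$u), cf$u,
                           check.names = FALSE),
                file.path(cfg$out_dir, "canonical_u.csv"))
  write_num_csv(data.frame(feature_id = rownames(cf$v), cf$v,
                           check.names = FALSE),
                file.path(cfg$out_dir, "canonical_v.csv"))
  write_num_csv(data.frame(iteration = seq_along(fit$total_cost_trajectory) - 1L,
                           total_cost = fit$total_cost_trajectory),
                file.path(cfg$out_dir, "trajectory.csv"))
  prof <- NULL
  if (all(fit$counts > 0L)) {
    prof <- subtype_profile(cohort, fit,
                            top_n = cfg_get(cfg, "top_n",
                                            min(60L, length(cohort$snp_ids))))
    write_profile_csvs(prof, cfg$out_dir)
  } else {
    message("skipping subtype profiles: empty subtype ",
            paste(which(fit$counts == 0L), collapse = ", "))
  }
  if (!is.null(prof) && !is.null(cfg$annotation_path)) {
    ann <- load_annotation(cfg$annotation_path)
    for (ax in c("pathway", "cell_type")) {
      pr <- category_proportions(prof$snp_means, ann, ax)
      write_num_csv(data.frame(subtype = rownames(pr), pr, check.names = FALSE),
                    file.path(cfg$out_dir, paste0("proportions_", ax, ".csv")))
    }
  }
  write_manifest(cfg, cfg$out_dir,
                 list(converged = fit$converged, n_iter = fit$n_iter,
                      per_cluster_cost = fit$per_cluster_cost,
                      counts = fit$counts))
  invisible(fit)
}

write_profile_csvs <- function(prof, out_dir) {
  tidy <- function(m, value) {
    data.frame(subtype = rep(rownames(m), times = ncol(m)),
               feature_id = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }
  write_num_csv(tidy(prof$imaging_means), file.path(out_dir, "imaging_means.csv"))
  write_num_csv(tidy(prof$imaging_means_01),
                file.path(out_dir, "imaging_means_01.csv"))
  write_num_csv(tidy(prof$snp_means), file.path(out_dir, "snp_means.csv"))
  write_num_csv(prof$snp_rank, file.path(out_dir, "snp_rank.csv"))
}

#' Run a stability analysis from a configuration
#'
#' Writes the co-assignment matrix, per-subject predominant-label
#' frequencies, and per-cluster ICC table, plus a manifest.
#'
#' @param cfg An [scca_config()] (`n_rep`, `mode` are used).
#' @return The `stability_report`, invisibly.
#' @export
run_stability <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_standardized(cfg)
  rep_ <- repeat_fit_stability(cohort, cfg$k, cfg$variant,
                               config_penalties(cfg), n_rep = cfg$n_rep,
                               mode = cfg$mode, seed = cfg$seed,
                               assign_rule = cfg_get(cfg, "assign_rule",
                                                     "residual"))
  write_num_csv(as.data.frame(rep_$co_assignment),
                file.path(cfg$out_dir, "co_assignment.csv"))
  write_num_csv(data.frame(subject_id = cohort$subject_ids,
                           predominant_freq = rep_$predominant_freq),
                file.path(cfg$out_dir, "predominant_freq.csv"))
  write_num_csv(data.frame(subtype = paste0("S", seq_along(rep_$icc_u)),
                           icc = rep_$icc_u),
                file.path(cfg$out_dir, "icc.csv"))
  write_manifest(cfg, cfg$out_dir,
                 list(mode = rep_$mode, failures = rep_$failures,
                      icc = rep_$icc_u))
  invisible(rep_)
}

#' Run a longitudinal consistency analysis from a configuration
#'
#' Fits the model on the pooled scans, assigns every scan independently,
#' and reports the proportion of multi-visit subjects with a stable label.
#'
#' @param cfg An [scca_config()] with `longitudinal_path` set.
#' @return The consistency value, invisibly.
#' @export
run_longitudinal <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$longitudinal_path))
    stop("config must set longitudinal_path")
  cohort <- load_standardized(cfg)
  index <- load_longitudinal(cfg$longitudinal_path, cohort)
  fit <- scca_cluster(cohort, cfg$k, cfg$variant, config_penalties(cfg),
                      seed = cfg$seed,
                      assign_rule = cfg_get(cfg, "assign_rule", "residual"))
  cons <- longitudinal_pipeline(fit, cohort, index)
  write_num_csv(data.frame(consistency = as.numeric(cons),
                           n_multi_visit = attr(cons, "n_multi_visit"),
                           n_single_visit = attr(cons, "n_single_visit")),
                file.path(cfg$out_dir, "longitudinal_consistency.csv"))
  write_manifest(cfg, cfg$out_dir, list(consistency = as.numeric(cons)))
  invisible(cons)
}

#' Simulate a cohort from a configuration and write it to disk
#'
#' Writes `imaging.csv` and `genetic.csv` in the format [load_cohort()]
#' reads, a `truth.csv` with the planted labels for scoring, and optionally
#' a longitudinal expansion.
#'
#' @param cfg An [scca_config()]; fields `M`, `N`, `P`, `noise_sd`,
#'   `support_p`, `support_n`, `n_visits` override the generator defaults.
#' @return The simulation list, invisibly.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(M = cfg_get(cfg, "M", 400L),
                         N = cfg_get(cfg, "N", 20L),
                         P = cfg_get(cfg, "P", 100L),
                         K = cfg$k,
                         support_p = cfg_get(cfg, "support_p", 5L),
                         support_n = cfg_get(cfg, "support_n", 4L),
                         noise_sd = cfg_get(cfg, "noise_sd", 0.2),
                         seed = cfg$seed)
  write_cohort(sim$cohort, file.path(cfg$out_dir, "imaging.csv"),
               file.path(cfg$out_dir, "genetic.csv"))
  write_num_csv(data.frame(subject_id = sim$cohort$subject_ids,
                           true_cluster = sim$truth$labels),
                file.path(cfg$out_dir, "truth.csv"))
  n_visits <- cfg_get(cfg, "n_visits", 0L)
  if (n_visits >= 2L) {
    lg <- simulate_longitudinal(sim$truth, n_visits,
                                cfg_get(cfg, "visit_noise_sd", 0.2),
                                seed = cfg$seed + 1L)
    write_cohort(lg$cohort, file.path(cfg$out_dir, "imaging_long.csv"),
                 file.path(cfg$out_dir, "genetic_long.csv"))
    write_num_csv(as.data.frame(lg$index)[, c("subject_id", "visit_order",
                                              "row_index")],
                  file.path(cfg$out_dir, "visits.csv"))
  }
  write_manifest(cfg, cfg$out_dir)
  invisible(sim)
}

#' Recompute subtype profiles from written fit outputs
#'
#' @param cfg An [scca_config()] whose `out_dir` holds a prior
#'   [run_fit()]'s `membership.csv`.
#' @return The `subtype_profile`, invisibly.
#' @export
run_profile <- function(cfg) {
  memb_path <- file.path(cfg$out_dir, "membership.csv")
  if (!file.exists(memb_path)) stop("no membership.csv in ", cfg$out_dir)
  cohort <- load_standardized(cfg)
  memb <- utils::read.csv(memb_path, stringsAsFactors = FALSE)
  labels <- memb$subtype[match(cohort$subject_ids, memb$subject_id)]
  prof <- subtype_profile(cohort, as.integer(labels),
                          top_n = cfg_get(cfg, "top_n",
                                          min(60L, length(cohort$snp_ids))))
  write_profile_csvs(prof, cfg$out_dir)
  invisible(prof)
}
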