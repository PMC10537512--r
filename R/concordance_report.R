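## Cross-tabulation of heterotic groups against marker clusters, per-cluster
## testcross trait means, and the end-to-end pipeline driver.

#' Cross-tabulate heterotic groups against marker clusters
#'
#' Rows are heterotic group labels (including a row for lines the method
#' left unassigned, when any), columns marker clusters.  Testers never
#' appear in rows (they define the groups); cluster labels for samples
#' outside the assignment (the testers) are ignored.
#'
#' @param assignment a `heterotic_assignment` (from [assign_sca()] or
#'   [assign_hsgca()]).
#' @param clusters a [ward_cluster()] result (or any named label vector).
#' @return object of class `group_cluster_crosstab`: list with `counts`
#'   (groups x clusters), `row_pct` (rows summing to 100), `n`.
#' @export
crosstab_groups_clusters <- function(assignment, clusters) {
  labels <- if (is.list(clusters)) clusters$labels else clusters
  common <- intersect(assignment$line, names(labels))
  if (length(common) == 0) stop("no samples shared between assignment and clusters")
  grp <- stats::setNames(assignment$group, assignment$line)[common]
  cl <- labels[common]
  lv <- intersect(c("HGA", "HGB", "unassigned"), unique(grp))
  counts <- table(factor(grp, levels = lv), factor(cl))
  counts <- unclass(counts)
  row_pct <- 100 * counts / pmax(rowSums(counts), 1)
  structure(list(counts = counts, row_pct = row_pct, n = length(common)),
            class = "group_cluster_crosstab")
}

#' @export
print.group_cluster_crosstab <- function(x, ...) {
  cat("heterotic group x marker cluster (", x$n, " lines)\ncounts:\n",
      sep = "")
  print(x$counts)
  cat("row %:\n")
  print(round(x$row_pct, 1))
  invisible(x)
}

#' Per-cluster, per-tester testcross trait means
#'
#' Arithmetic mean of member lines' testcross means, by tester, for one
#' trait.  Clusters with no member line present in the means table are
#' returned as `NA`.
#'
#' @param clusters a [ward_cluster()] result.
#' @param means a [cell_means()] result for the trait of interest.
#' @return data.frame: `cluster`, `n_lines`, one mean column per tester.
#' @export
cluster_trait_means <- function(clusters, means) {
  stopifnot(inherits(means, "cross_means"))
  labels <- if (is.list(clusters)) clusters$labels else clusters
  testers <- colnames(means$cross_means)
  cl_ids <- sort(unique(labels))
  rows <- lapply(cl_ids, function(cl) {
    members <- intersect(names(labels)[labels == cl],
                         rownames(means$cross_means))
    vals <- if (length(members) == 0) rep(NA_real_, length(testers))
            else colMeans(means$cross_means[members, , drop = FALSE])
    c(n_lines = length(members), vals)
  })
  out <- data.frame(cluster = cl_ids, do.call(rbind, rows))
  names(out) <- c("cluster", "n_lines", paste0("mean_", testers))
  out
}

#' Run the full pipeline
#'
#' Orchestrates the complete analysis on a trial table plus genotype matrix
#' (real or simulated): cell means, effects and ANOVA per trait, SCA and
#' HSGCA heterotic assignment, method concordance, marker QC and diversity,
#' IBS distances, Ward clustering, PCA, admixture over a K range with
#' Evanno delta-K, and the group-by-cluster cross-tabulations.  With
#' `outdir` set, every table is written as CSV/JSON (plus the newick tree)
#' along with a run log recording seeds, thresholds and conventions.
#'
#' @param trial a [trial_table].
#' @param geno a [genotype_matrix] covering the lines (and testers).
#' @param traits traits to analyse; default all in `trial`.
#' @param config a [grouping_config()].
#' @param k_clusters flat cluster count for the Ward tree (default 3).
#' @param k_range K values for the admixture scan (default 1:5).
#' @param n_replicates admixture restarts per K (default 10).
#' @param seed integer seed for the admixture restarts.
#' @param outdir optional output directory.
#' @return a list bundle with elements `means`, `effects`, `anova`,
#'   `assignments`, `concordance`, `marker_summary`, `filter_report`,
#'   `ibs`, `ward`, `pca`, `admixture`, `evanno`, `crosstabs`,
#'   `cluster_means`.
#' @export
run_pipeline <- function(trial, geno, traits = trial$traits,
                         config = grouping_config(),
                         k_clusters = 3, k_range = 1:5,
                         n_replicates = 10, seed = 1, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(means = list(), effects = list(), anova = list(),
              assignments = list())
  for (tr in traits) {
    res$means[[tr]] <- stage("cell_means", cell_means(trial, tr))
    res$anova[[tr]] <- stage("anova", anova_line_by_tester(trial, tr))
    res$effects[[tr]] <- stage("effects",
                               estimate_effects(res$means[[tr]],
                                                res$anova[[tr]]))
    cm <- res$means[[tr]]
    check <- if (!is.null(cm$check_means)) mean(cm$check_means) else
      cm$overall_mean
    n_per_mean <- res$anova[[tr]]$design["n_envs"] *
      res$anova[[tr]]$design["n_reps"]
    lsd_v <- stage("lsd", lsd(res$anova[[tr]], config$alpha, n_per_mean))
    res$assignments[[paste0(tr, "_SCA")]] <-
      stage("assign_sca", assign_sca(res$effects[[tr]], cm, check, lsd_v,
                                     config, tr))
    res$assignments[[paste0(tr, "_HSGCA")]] <-
      stage("assign_hsgca", assign_hsgca(res$effects[[tr]], config, tr))
  }
  res$concordance <- stage("compare_methods",
                           compare_methods(res$assignments))

  fl <- stage("filter_markers", filter_markers(geno))
  res$filter_report <- fl$report
  st <- stage("marker_stats", marker_stats(fl$geno))
  res$marker_summary <- stage("summarize_diversity", summarize_diversity(st))
  res$ibs <- stage("ibs_distance", ibs_distance(fl$geno))
  res$ward <- stage("ward_cluster", ward_cluster(res$ibs, k_clusters))
  res$pca <- stage("pca_genotypes",
                   pca_genotypes(fl$geno, min(10, nrow(geno$calls) - 1)))
  adm <- list()
  for (K in k_range)
    adm[[as.character(K)]] <-
      stage("admixture_em", admixture_em(fl$geno, K, n_replicates,
                                         seed = seed + 97L * K))
  res$admixture <- adm
  if (length(k_range) >= 3) {
    lls <- lapply(adm, `[[`, "replicate_logliks")
    res$evanno <- stage("evanno_delta_k", evanno_delta_k(lls))
  }
  res$crosstabs <- lapply(res$assignments, crosstab_groups_clusters,
                          clusters = res$ward)
  res$cluster_means <- lapply(res$means, function(m)
    cluster_trait_means(res$ward, m))

  if (!is.null(outdir)) write_pipeline_outputs(res, trial, outdir,
                                               config, seed)
  invisible(res)
}

write_pipeline_outputs <- function(res, trial, outdir, config, seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  for (tr in names(res$effects)) {
    ef <- res$effects[[tr]]
    tab <- data.frame(line = names(ef$gca_line), gca = ef$gca_line,
                      ef$sca, ef$hsgca, check.names = FALSE)
    names(tab) <- c("line", "gca",
                    paste0("sca_", colnames(ef$sca)),
                    paste0("hsgca_", colnames(ef$hsgca)))
    wcsv(tab, paste0("effects_", tr, ".csv"))
    wcsv(res$anova[[tr]]$table, paste0("anova_", tr, ".csv"))
  }
  for (nm in names(res$assignments))
    wcsv(res$assignments[[nm]], paste0("assignment_", nm, ".csv"))
  jsonlite::write_json(
    list(rho = res$concordance$rho, p = res$concordance$p,
         agreement_pct = res$concordance$agreement_pct),
    file.path(outdir, "concordance.json"), digits = NA, matrix = "rowmajor")
  wcsv(cbind(stat = rownames(res$marker_summary), res$marker_summary),
       "diversity_summary.csv")
  utils::write.csv(as.data.frame(unclass(res$ibs)),
                   file.path(outdir, "ibs_distance.csv"))
  writeLines(write_newick(res$ward), file.path(outdir, "dendrogram.nwk"))
  wcsv(data.frame(sample = names(res$ward$labels),
                  cluster = res$ward$labels), "clusters.csv")
  wcsv(data.frame(sample = rownames(res$pca$scores), res$pca$scores),
       "pca_scores.csv")
  bestK <- res$admixture[[length(res$admixture)]]
  if (!is.null(res$evanno)) {
    wcsv(res$evanno, "evanno.csv")
    bk <- attr(res$evanno, "best_K")
    if (!is.na(bk)) bestK <- res$admixture[[as.character(bk)]]
  }
  wcsv(data.frame(sample = rownames(bestK$Q), bestK$Q,
                  assignment = bestK$assignments), "q_matrix.csv")
  for (nm in names(res$crosstabs)) {
    ct <- res$crosstabs[[nm]]
    wcsv(data.frame(group = rownames(ct$counts), ct$counts,
                    check.names = FALSE),
         paste0("crosstab_", nm, ".csv"))
  }
  log <- list(seed = seed, date = as.character(Sys.Date()),
              design = as.list(trial$design),
              grouping = list(tester_to_group =
                                as.list(config$tester_to_group),
                              alpha = config$alpha,
                              min_sca_magnitude =
                                as.list(config$min_sca_magnitude),
                              tie_break = config$tie_break),
              conventions = list(
                yield = "kg/ha at 15% moisture, yield = W*(100-m)/85*1e4/area",
                margins = "line/tester means from cross means",
                anova = "RCBD sequential SS, EMS F tests, no lattice adjustment",
                repeatability = "entry-mean, moment estimators truncated at 0",
                ward = "ward.D2 convention on IBS distances",
                membership = ">= 0.60 assigns to argmax subgroup"))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
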