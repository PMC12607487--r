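#' Run the full discrimination pipeline
#'
#' Chains the analysis stages on an abundance table with two-class labels:
#' abundance-cutoff filtering, hierarchical clustering of the z-scored
#' filtered table, PCA of the filtered features, Pearson-correlation
#' cluster feature selection, PCA of the selected features, then PLS-DA on
#' the filtered table with training R2, k-fold cross-validated Q2, a label
#' permutation test, and VIP scores. Every stage parameter is recorded in
#' the returned summary, and all randomness is governed by \code{seed},
#' so reruns with the same configuration are identical.
#'
#' @param table an \code{abundance_table} or a path to an abundance CSV.
#' @param classes a \code{sample_classes} or a path to a classes CSV.
#' @param cutoff percent abundance cutoff (default 10).
#' @param cutoff_rule cutoff rule, see \code{\link{cutoff_filter}}.
#' @param corr_threshold absolute-correlation threshold for feature
#'   clustering (default 0.7).
#' @param n_select number of representative features to select
#'   (default 4; capped at the number of correlation clusters).
#' @param n_components PLS/PCA components (default 2).
#' @param folds cross-validation folds (default 5).
#' @param n_permutations permutation-test runs (default 1000).
#' @param linkage HCA linkage method (default \code{"average"}).
#' @param seed integer seed for fold assignment and permutations.
#' @param out_dir optional directory; when given, per-stage CSV artifacts
#'   and a machine-readable \code{summary.json} are written there.
#' @return an object of class \code{pipeline_result}: a list with
#'   \code{summary} (plain list, JSON-serializable), \code{model},
#'   \code{vip}, \code{cv}, \code{permutation}, \code{hca},
#'   \code{pca_filtered}, \code{pca_selected}, \code{correlation_clusters},
#'   and the filtered/selected tables.
#' @export
run_pipeline <- function(table, classes, cutoff = 10,
                         cutoff_rule = "any_sample",
                         corr_threshold = 0.7, n_select = 4,
                         n_components = 2, folds = 5,
                         n_permutations = 1000, linkage = "average",
                         seed = 1, out_dir = NULL) {
  if (is.character(table)) {
    if (!file.exists(table)) stop("input file not found: ", table, call. = FALSE)
    table <- read_abundance_table(table)
  }
  if (is.character(classes)) {
    if (!file.exists(classes)) {
      stop("classes file not found: ", classes, call. = FALSE)
    }
    classes_obj <- read_classes(classes)
  } else classes_obj <- classes
  al <- align(table, classes_obj)
  y <- al$y

  filtered <- cutoff_filter(al$table, threshold = cutoff, rule = cutoff_rule)
  z <- zscore(filtered)
  trees <- hca(z, method = linkage)
  X <- t(filtered$values)

  pca_filtered <- pca(X, n_components = min(n_components,
                                            min(nrow(X) - 1L, ncol(X))))
  corr <- pearson_matrix(filtered)
  clus <- correlation_clusters(corr, threshold = corr_threshold)
  n_sel <- min(n_select, length(clus$clusters))
  selected <- select_representatives(clus, filtered, n_select = n_sel)
  sel_table <- subset_features(filtered, selected)
  pca_selected <- pca(t(sel_table$values),
                      n_components = min(n_components,
                                         min(nrow(X) - 1L, length(selected))))

  model <- plsda_fit(X, y, n_components = n_components)
  fitstats <- r_squared(model)
  cv <- q_squared(X, y, k = folds, n_components = n_components, seed = seed)
  perm <- permutation_test(X, y, n_runs = n_permutations, k = folds,
                           n_components = n_components, seed = seed)
  v <- vip(model)

  vip_df <- data.frame(feature = names(v$scores),
                       vip = unname(v$scores),
                       above_threshold = unname(v$scores >= v$threshold),
                       stringsAsFactors = FALSE)
  summary <- list(
    settings = list(cutoff = cutoff, cutoff_rule = cutoff_rule,
                    corr_threshold = corr_threshold, n_select = n_sel,
                    n_components = n_components, folds = folds,
                    n_permutations = n_permutations, linkage = linkage,
                    seed = seed, class_names = al$class_names),
    feature_counts = list(initial = length(al$table$feature_ids),
                          after_cutoff = length(filtered$feature_ids),
                          selected = length(selected)),
    correlation = list(n_clusters = length(clus$clusters),
                       threshold = corr_threshold),
    selected_features = selected,
    pca = list(
      filtered = list(
        explained_variance_ratio = unname(pca_filtered$explained_variance_ratio),
        cumulative_variance = unname(utils::tail(pca_filtered$cumulative_variance, 1))),
      selected = list(
        explained_variance_ratio = unname(pca_selected$explained_variance_ratio),
        cumulative_variance = unname(utils::tail(pca_selected$cumulative_variance, 1)))),
    plsda = list(r2 = fitstats$r2, sse = fitstats$sse, sst = fitstats$sst,
                 q2 = cv$q2, press = cv$press, tss = cv$tss,
                 observed_q2 = perm$observed_q2,
                 p_value = perm$p_value, n_permutations = perm$n_runs),
    vip = vip_df
  )

  result <- structure(list(summary = summary, model = model, vip = v,
                           cv = cv, permutation = perm, hca = trees,
                           pca_filtered = pca_filtered,
                           pca_selected = pca_selected,
                           correlation_clusters = clus,
                           filtered_table = filtered,
                           selected_table = sel_table,
                           classes = classes_obj),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

# Write per-stage CSV artifacts plus the machine-readable summary.
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(out_dir, name)
  write_abundance_table(result$filtered_table, fp("filtered.csv"))
  write_abundance_table(result$selected_table, fp("selected.csv"))
  utils::write.csv(result$hca$samples$merges, fp("hca_samples_merges.csv"),
                   row.names = FALSE)
  utils::write.csv(result$hca$features$merges, fp("hca_features_merges.csv"),
                   row.names = FALSE)
  sc <- scores_for_plot(result$model, result$classes)
  utils::write.csv(sc, fp("plsda_scores.csv"), row.names = FALSE)
  pcs <- data.frame(sample = rownames(result$pca_filtered$scores),
                    result$pca_filtered$scores,
                    class = sc$class, stringsAsFactors = FALSE)
  utils::write.csv(pcs, fp("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(result$summary$vip, fp("vip.csv"), row.names = FALSE)
  utils::write.csv(data.frame(permuted_q2 = result$permutation$permuted_q2),
                   fp("permuted_q2.csv"), row.names = FALSE)
  jsonlite::write_json(result$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable pipeline report
#'
#' Deterministic plain-text report of a pipeline run: settings and seeds,
#' feature counts at each reduction step, PCA variances, PLS-DA validation
#' statistics, and the VIP features at or above the importance threshold.
#'
#' @param result a \code{pipeline_result} (or its \code{summary} list).
#' @return a character vector of report lines.
#' @export
render_report <- function(result) {
  s <- if (inherits(result, "pipeline_result")) result$summary else result
  st <- s$settings
  lines <- c(
    sprintf("chemodiscrim pipeline report (package version %s)",
            as.character(utils::packageVersion("chemodiscrim"))),
    "",
    "settings:",
    sprintf("  cutoff: %g%% (rule: %s)", st$cutoff, st$cutoff_rule),
    sprintf("  correlation threshold: %g", st$corr_threshold),
    sprintf("  components: %d | folds: %d | permutations: %d",
            st$n_components, st$folds, st$n_permutations),
    sprintf("  linkage: %s | seed: %d", st$linkage, st$seed),
    sprintf("  classes: %s", paste(st$class_names, collapse = " vs ")),
    "",
    sprintf("feature reduction: %d -> %d (cutoff) -> %d (correlation clusters: %d)",
            s$feature_counts$initial, s$feature_counts$after_cutoff,
            s$feature_counts$selected, s$correlation$n_clusters),
    sprintf("selected features: %s", paste(s$selected_features, collapse = ", ")),
    "",
    sprintf("PCA cumulative variance (%d PCs): filtered %.1f%%, selected %.1f%%",
            st$n_components, 100 * s$pca$filtered$cumulative_variance,
            100 * s$pca$selected$cumulative_variance),
    "",
    "PLS-DA validation:",
    sprintf("  R2 = %.4f (SSE = %.4f, SST = %.4f)",
            s$plsda$r2, s$plsda$sse, s$plsda$sst),
    sprintf("  Q2 = %.4f (PRESS = %.4f, TSS = %.4f)",
            s$plsda$q2, s$plsda$press, s$plsda$tss),
    sprintf("  permutation p-value = %.4g (%d runs)",
            s$plsda$p_value, s$plsda$n_permutations),
    "",
    sprintf("VIP (threshold %g):", 1))
  flagged <- s$vip[s$vip$above_threshold, , drop = FALSE]
  if (nrow(flagged) == 0L) {
    lines <- c(lines, "  no features above threshold")
  } else {
    flagged <- flagged[order(-flagged$vip), , drop = FALSE]
    lines <- c(lines, sprintf("  %-28s %.3f", flagged$feature, flagged$vip))
  }
  lines
}
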