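#' Hierarchical clustering of samples and/or features
#'
#' Agglomerative clustering with Euclidean distances, defaulting to average
#' linkage. For heatmap-style exploration of relative-abundance data apply
#' \code{\link{zscore}} first, then cluster both axes. Results are wrapped
#' as linkage trees holding the merge table (node indices, merge height,
#' cluster size) and the dendrogram leaf order, so figures can be rebuilt
#' as data artifacts.
#'
#' Negative node indices in the merge table denote original observations,
#' positive ones earlier merges (the \code{\link[stats]{hclust}}
#' convention). Ties are resolved by the lower input index first.
#'
#' @param x an \code{abundance_table} or a features x samples numeric
#'   matrix (e.g. z-scores).
#' @param metric distance metric; only \code{"euclidean"} is supported.
#' @param method linkage method: \code{"average"} (default),
#'   \code{"complete"}, \code{"single"} or \code{"ward"}
#'   (Ward's criterion on squared Euclidean distances, \code{ward.D2}).
#' @param cluster_axes which axes to cluster: \code{"both"} (default),
#'   \code{"samples"}, or \code{"features"}.
#' @return a list of class \code{hca_result} with elements \code{samples}
#'   and \code{features}, each a \code{linkage_tree} or \code{NULL}.
#' @export
hca <- function(x, metric = "euclidean",
                method = c("average", "complete", "single", "ward"),
                cluster_axes = c("both", "samples", "features")) {
  method <- match.arg(method)
  cluster_axes <- match.arg(cluster_axes)
  metric <- match.arg(metric, "euclidean")
  m <- as_feature_matrix(x)
  if (any(!is.finite(m))) stop("non-finite values in input", call. = FALSE)
  hmethod <- if (method == "ward") "ward.D2" else method
  build <- function(mat) {
    if (nrow(mat) < 2L) stop("need at least two items to cluster", call. = FALSE)
    linkage_tree(stats::hclust(stats::dist(mat, method = metric),
                               method = hmethod),
                 method = method, metric = metric)
  }
  out <- list(
    samples  = if (cluster_axes %in% c("both", "samples")) build(t(m)) else NULL,
    features = if (cluster_axes %in% c("both", "features")) build(m) else NULL
  )
  structure(out, class = "hca_result")
}

# Wrap an hclust object as a linkage_tree with an explicit merge table.
linkage_tree <- function(h, method = h$method, metric = "euclidean") {
  nmerge <- nrow(h$merge)
  size <- integer(nmerge)
  for (i in seq_len(nmerge)) {
    a <- h$merge[i, 1]; b <- h$merge[i, 2]
    size[i] <- (if (a < 0) 1L else size[a]) + (if (b < 0) 1L else size[b])
  }
  merges <- data.frame(node_a = h$merge[, 1], node_b = h$merge[, 2],
                       height = h$height, size = size)
  structure(list(merges = merges, leaf_order = h$order, labels = h$labels,
                 method = method, metric = metric, hclust = h),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("linkage_tree: %d leaves, %s linkage (%s)\n",
              length(x$leaf_order), x$method, x$metric))
  print(utils::head(x$merges))
  invisible(x)
}

#' Principal component analysis by singular value decomposition
#'
#' Columns are centered, and by default scaled to unit standard deviation,
#' before the SVD. Explained-variance ratios are computed against the total
#' variance of the (centered, scaled) matrix, so they sum to one when all
#' components are retained. The sign of each component is fixed so that its
#' largest-magnitude loading entry is positive, making results reproducible
#' across platforms.
#'
#' @param x samples x features numeric matrix, or an
#'   \code{abundance_table} (transposed internally).
#' @param n_components number of components to retain; must not exceed
#'   \code{min(n_samples - 1, n_features)}.
#' @param scale scale columns to unit variance (default \code{TRUE}).
#' @return an object of class \code{pca_result} with \code{scores}
#'   (samples x components), \code{loadings} (features x components,
#'   orthonormal), \code{explained_variance_ratio},
#'   \code{cumulative_variance} (both per retained component), and
#'   \code{all_variance_ratio} (every component of the decomposition).
#' @export
pca <- function(x, n_components = 2, scale = TRUE) {
  X <- as_sample_matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PCA needs at least two samples", call. = FALSE)
  if (n_components < 1L || n_components > min(n - 1L, p)) {
    stop(sprintf("n_components must be in [1, %d]", min(n - 1L, p)),
         call. = FALSE)
  }
  if (scale) {
    Xs <- autoscale_fast(X)$x
  } else {
    Xs <- X - rep(colMeans(X), each = n)
  }
  s <- svd(Xs)
  ev <- s$d^2
  ratio <- ev / sum(ev)
  k <- n_components
  loadings <- s$v[, seq_len(k), drop = FALSE]
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  for (a in seq_len(k)) {
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  cn <- paste0("PC", seq_len(k))
  dimnames(loadings) <- list(colnames(X), cn)
  dimnames(scores) <- list(rownames(X), cn)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = ratio[seq_len(k)],
                 cumulative_variance = cumsum(ratio)[seq_len(k)],
                 all_variance_ratio = ratio,
                 n_components = k, scaled = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components\n", x$n_components))
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "), "\n")
  cat("cumulative:", sprintf("%.3f", utils::tail(x$cumulative_variance, 1)), "\n")
  invisible(x)
}

#' Rank features by between-class separation
#'
#' Features are z-scored and ranked by the absolute difference of their
#' class-mean z-scores, the quantity that drives the visual separation of
#' class blocks in a clustered heatmap. Ties are broken alphabetically by
#' feature name.
#'
#' @param table an \code{abundance_table}.
#' @param classes a \code{sample_classes} object; both classes must be
#'   present.
#' @return a data.frame with columns \code{feature} and \code{score},
#'   sorted by decreasing score.
#' @export
top_discriminative_features <- function(table, classes) {
  al <- align(table, classes)
  y <- al$y
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  z <- zscore(al$table)
  d <- abs(rowMeans(z[, y == 0L, drop = FALSE]) -
           rowMeans(z[, y == 1L, drop = FALSE]))
  ord <- order(-d, names(d))
  data.frame(feature = names(d)[ord], score = unname(d[ord]),
             stringsAsFactors = FALSE)
}
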