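#' Pearson correlation matrix of features
#'
#' Feature-by-feature Pearson correlations across samples, with the sample
#' (n - 1) covariance convention and a diagonal of exactly one.
#'
#' @param table an \code{abundance_table} with at least three samples.
#' @return a symmetric features x features correlation matrix.
#' @export
pearson_matrix <- function(table) {
  m <- as_feature_matrix(table)
  if (ncol(m) < 3L) {
    stop("correlation needs at least three samples", call. = FALSE)
  }
  sds <- apply(m, 1, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- rownames(m)[sds < 1e-12]
    if (is.null(bad)) bad <- which(sds < 1e-12)
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(t(m))
  diag(r) <- 1
  r
}

#' Correlation clusters by connected components
#'
#' Partitions features into the connected components of the graph that
#' joins two features whenever the absolute Pearson correlation between
#' them reaches \code{threshold}. This is the most reproducible reading of
#' "correlation clusters": every feature lands in exactly one cluster, and
#' the partition is invariant to feature order. Clusters are reported in
#' order of their smallest member index.
#'
#' @param correlation a symmetric correlation matrix with unit diagonal
#'   (see \code{\link{pearson_matrix}}).
#' @param threshold absolute-correlation cutoff in (0, 1].
#' @return an object of class \code{correlation_clusters} with the
#'   \code{correlation} matrix, the \code{clusters} (list of feature-name
#'   vectors), a named \code{membership} vector, and the \code{threshold}.
#' @export
correlation_clusters <- function(correlation, threshold = 0.7) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must be in (0, 1]", call. = FALSE)
  }
  correlation <- as.matrix(correlation)
  n <- nrow(correlation)
  if (n != ncol(correlation)) stop("correlation matrix must be square", call. = FALSE)
  if (max(abs(correlation - t(correlation))) > 1e-8) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  nm <- rownames(correlation)
  if (is.null(nm)) nm <- paste0("f", seq_len(n))
  adj <- abs(correlation) >= threshold
  visited <- rep(FALSE, n)
  clusters <- list()
  membership <- integer(n)
  for (i in seq_len(n)) {
    if (visited[i]) next
    # breadth-first sweep from the lowest unvisited index
    comp <- integer(0)
    queue <- i
    visited[i] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comp <- sort(comp)
    clusters[[length(clusters) + 1L]] <- nm[comp]
    membership[comp] <- length(clusters)
  }
  names(membership) <- nm
  structure(list(correlation = correlation, clusters = clusters,
                 membership = membership, threshold = threshold),
            class = "correlation_clusters")
}

#' @export
print.correlation_clusters <- function(x, ...) {
  cat(sprintf("correlation_clusters: %d clusters at |r| >= %g\n",
              length(x$clusters), x$threshold))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  [%d] %s\n", i, paste(x$clusters[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Select one representative feature per correlation cluster
#'
#' Picks, within each cluster, the feature maximizing the chosen criterion
#' (mean relative abundance by default, or VIP score when a fitted model is
#' available), then ranks clusters by their representative's criterion
#' value and returns the top \code{n_select} representatives. All ties are
#' broken alphabetically by feature name.
#'
#' @param clusters a \code{correlation_clusters} object.
#' @param table the \code{abundance_table} the correlations came from
#'   (used by the \code{max_mean_abundance} criterion).
#' @param criterion \code{"max_mean_abundance"} (default) or
#'   \code{"max_vip"}.
#' @param vip a \code{vip_vector} (or named numeric vector of VIP scores);
#'   required for criterion \code{max_vip}.
#' @param n_select number of representatives to return; must not exceed
#'   the number of clusters.
#' @return a character vector of selected feature names, in decreasing
#'   criterion order.
#' @export
select_representatives <- function(clusters, table,
                                   criterion = c("max_mean_abundance",
                                                 "max_vip"),
                                   vip = NULL,
                                   n_select = length(clusters$clusters)) {
  stopifnot(inherits(clusters, "correlation_clusters"))
  criterion <- match.arg(criterion)
  if (n_select > length(clusters$clusters)) {
    stop(sprintf("n_select (%d) exceeds the number of clusters (%d)",
                 n_select, length(clusters$clusters)), call. = FALSE)
  }
  if (criterion == "max_vip") {
    if (is.null(vip)) {
      stop("criterion 'max_vip' requires a VIP vector", call. = FALSE)
    }
    value <- if (inherits(vip, "vip_vector")) vip$scores else vip
  } else {
    m <- as_feature_matrix(table)
    value <- rowMeans(m)
  }
  missing <- setdiff(unlist(clusters$clusters), names(value))
  if (length(missing)) {
    stop("no criterion value for feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  reps <- vapply(clusters$clusters, function(fs) {
    fs[order(-value[fs], fs)][1]
  }, character(1))
  ord <- order(-value[reps], reps)
  unname(reps[ord][seq_len(n_select)])
}
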