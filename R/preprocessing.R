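#' Abundance-cutoff feature filtering
#'
#' Retains the features of a relative-abundance table that qualify as
#' "major components" under a percent-abundance cutoff. The default rule
#' keeps a feature if its abundance reaches the threshold in at least one
#' sample, with an inclusive boundary, i.e. a feature whose maximum is
#' exactly the threshold is retained. The 10% default follows the common
#' convention of calling a metabolite a major component when it reaches
#' 10% relative abundance.
#'
#' @param table an \code{abundance_table}.
#' @param threshold percent relative abundance cutoff, in (0, 100).
#' @param rule how the per-sample abundances are summarized before the
#'   comparison: \code{"any_sample"} (max over samples, default),
#'   \code{"all_samples"} (min), or \code{"mean"}.
#' @param inclusive if \code{TRUE} (default) the comparison is
#'   \code{>= threshold}, otherwise strictly \code{>}.
#' @return the filtered \code{abundance_table}; feature order and samples
#'   untouched.
#' @export
cutoff_filter <- function(table, threshold = 10,
                          rule = c("any_sample", "all_samples", "mean"),
                          inclusive = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 100) {
    stop("'threshold' must be a single value in (0, 100)", call. = FALSE)
  }
  m <- table$values
  stat <- switch(rule,
                 any_sample  = apply(m, 1, max),
                 all_samples = apply(m, 1, min),
                 mean        = rowMeans(m))
  keep <- if (inclusive) stat >= threshold else stat > threshold
  if (!any(keep)) stop("empty table after cutoff", call. = FALSE)
  abundance_table(m[keep, , drop = FALSE])
}

#' Per-feature z-score standardization
#'
#' Centers each feature (row) to mean zero and scales it to unit sample
#' standard deviation (n - 1 denominator). Returns a plain numeric matrix
#' rather than an \code{abundance_table}, since standardized values are
#' signed and no longer relative abundances.
#'
#' @param x an \code{abundance_table} or a features x samples numeric
#'   matrix.
#' @return a features x samples matrix of z-scores.
#' @export
zscore <- function(x) {
  m <- as_feature_matrix(x)
  if (ncol(m) < 2L) stop("z-scoring needs at least two samples", call. = FALSE)
  mu <- rowMeans(m)
  centered <- m - mu
  sds <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  if (any(sds < 1e-12)) {
    bad <- rownames(m)[sds < 1e-12]
    if (is.null(bad)) bad <- which(sds < 1e-12)
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  centered / sds
}

#' Column autoscaling with explicit statistics provenance
#'
#' Centers and scales the columns of a samples x features matrix to mean
#' zero and unit sample standard deviation. When \code{center} and
#' \code{scale} are supplied (e.g. statistics estimated on a training fold
#' during cross-validation) they are applied as-is rather than recomputed,
#' so held-out data is never allowed to leak into the scaling.
#'
#' @param x samples x features numeric matrix.
#' @param center optional centering vector (one entry per column).
#' @param scale optional scaling vector (one entry per column).
#' @return a list with elements \code{x} (scaled matrix), \code{center},
#'   and \code{scale}.
#' @export
autoscale <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (is.null(center) != is.null(scale)) {
    stop("supply both 'center' and 'scale', or neither", call. = FALSE)
  }
  if (is.null(center)) {
    return(autoscale_fast(x))
  }
  if (length(center) != ncol(x) || length(scale) != ncol(x)) {
    stop("'center'/'scale' length must equal ncol(x)", call. = FALSE)
  }
  if (any(scale < 1e-12)) stop("zero entries in 'scale'", call. = FALSE)
  n <- nrow(x)
  scaled <- (x - rep(center, each = n)) / rep(scale, each = n)
  list(x = scaled, center = center, scale = scale)
}
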