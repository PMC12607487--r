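#' Construct an abundance table
#'
#' An abundance table holds GC/MS relative abundances (percent of total
#' identified peak area) as a features x samples matrix with unique feature
#' and sample identifiers. Values must be finite and non-negative, and each
#' sample's column sum may not exceed 100 by more than \code{sum_tol}
#' (sums below 100 are normal: unidentified peaks are excluded from the
#' denominator).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique metabolite names
#'   (defaults to \code{rownames(values)}).
#' @param sample_ids character vector of unique sample names
#'   (defaults to \code{colnames(values)}).
#' @param sum_tol tolerance above 100 allowed for per-sample column sums;
#'   the default 0.5 accommodates tables rounded to two decimals.
#' @return an object of class \code{abundance_table} with elements
#'   \code{values}, \code{feature_ids}, \code{sample_ids}.
#' @export
#' @examples
#' m <- matrix(c(50, 30, 20, 10, 5, 5), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' abundance_table(m)
abundance_table <- function(values, feature_ids = rownames(values),
                            sample_ids = colnames(values), sum_tol = 0.5) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric", call. = FALSE)
  if (is.null(feature_ids)) stop("feature identifiers are required", call. = FALSE)
  if (is.null(sample_ids)) stop("sample identifiers are required", call. = FALSE)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length of feature_ids does not match the number of rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of sample_ids does not match the number of columns", call. = FALSE)
  }
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f)) {
    stop("duplicate feature identifier(s): ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite abundance value(s)", call. = FALSE)
  if (any(values < 0)) stop("negative abundance value(s)", call. = FALSE)
  cs <- colSums(values)
  if (any(cs > 100 + sum_tol)) {
    bad <- sample_ids[which.max(cs)]
    stop(sprintf("sample '%s' has column sum %.4f > 100 (+ tolerance %g)",
                 bad, max(cs), sum_tol), call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids),
            class = "abundance_table")
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("features:", paste(utils::head(x$feature_ids, 5), collapse = ", "),
      if (length(x$feature_ids) > 5) "...", "\n")
  cat("samples: ", paste(utils::head(x$sample_ids, 6), collapse = ", "),
      if (length(x$sample_ids) > 6) "...", "\n")
  invisible(x)
}

#' Subset an abundance table by feature names
#'
#' @param table an \code{abundance_table}.
#' @param features character vector of feature identifiers to keep
#'   (order preserved as given).
#' @return an \code{abundance_table} restricted to \code{features}.
#' @export
subset_features <- function(table, features) {
  stopifnot(inherits(table, "abundance_table"))
  missing <- setdiff(features, table$feature_ids)
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  abundance_table(table$values[features, , drop = FALSE])
}

#' Read an abundance table from CSV
#'
#' Expects a header row and identifiers in the first column. Cells holding
#' \code{"-"}, the empty string, or \code{NA} are interpreted as
#' "compound not detected" and set to 0, matching relative-abundance
#' reporting conventions.
#'
#' @param path path to a CSV file.
#' @param orientation whether features or samples occupy the rows of the
#'   file; the returned table is always features x samples.
#' @return an \code{abundance_table}.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("features_in_rows",
                                                 "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("abundance CSV must have a header row, an identifier column and ",
         "at least one value column", call. = FALSE)
  }
  ids <- trimws(raw[[1]])
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L)
  for (j in seq_len(ncol(raw) - 1L)) {
    v <- trimws(raw[[j + 1L]])
    v[v %in% c("-", "", "NA")] <- "0"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   raw[[j + 1L]][bad[1]], bad[1], colnames(raw)[j + 1L]),
           call. = FALSE)
    }
    m[, j] <- num
  }
  dimnames(m) <- list(ids, colnames(raw)[-1L])
  if (orientation == "samples_in_rows") m <- t(m)
  abundance_table(m)
}

#' Write an abundance table to CSV
#'
#' Features in rows, samples in columns, feature identifiers in the first
#' column (named \code{feature}). Values round-trip through
#' \code{\link{read_abundance_table}} to within 1e-9.
#'
#' @param table an \code{abundance_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(feature = table$feature_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a sample-class mapping
#'
#' @param labels named integer vector of 0/1 class codes; names are sample
#'   identifiers.
#' @param class_names character vector of length two giving the display
#'   names for codes 0 and 1 (e.g. \code{c("Thai", "Foreign")}); length one
#'   is tolerated for degenerate single-class tables, but discrimination
#'   methods require both classes.
#' @param extract_type optional named character vector annotating each
#'   sample with an extract type (e.g. \code{"O"}, \code{"M-H"},
#'   \code{"M-E"}).
#' @return an object of class \code{sample_classes}.
#' @export
sample_classes <- function(labels, class_names, extract_type = NULL) {
  if (is.null(names(labels)) || anyNA(names(labels))) {
    stop("'labels' must be named by sample identifier", call. = FALSE)
  }
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup)) {
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (any(!labels %in% c(0L, 1L))) {
    stop("class codes must be 0 or 1", call. = FALSE)
  }
  class_names <- as.character(class_names)
  if (length(class_names) < 1L || length(class_names) > 2L) {
    stop("'class_names' must have length one or two", call. = FALSE)
  }
  if (!is.null(extract_type)) {
    extract_type <- stats::setNames(as.character(extract_type),
                                    names(extract_type))
  }
  structure(list(labels = labels, class_names = class_names,
                 extract_type = extract_type),
            class = "sample_classes")
}

#' @export
print.sample_classes <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat("sample_classes:", length(x$labels), "samples\n")
  print(tab)
  invisible(x)
}

#' Read sample class labels from CSV
#'
#' Expects columns \code{sample_id,class[,extract_type]}. Class names are
#' mapped to codes \{0, 1\} in order of first appearance in the file; the
#' mapping is recorded in \code{class_names} so the coding is reproducible.
#'
#' @param path path to the classes CSV.
#' @return a \code{sample_classes} object.
#' @export
read_classes <- function(path) {
  if (!file.exists(path)) stop("classes file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples in classes file: ", path, call. = FALSE)
  if (ncol(df) < 2L) {
    stop("classes CSV needs at least columns sample_id,class", call. = FALSE)
  }
  ids <- trimws(as.character(df[[1]]))
  cls <- trimws(as.character(df[[2]]))
  lev <- unique(cls)
  if (length(lev) > 2L) {
    stop("more than two distinct class names: ", paste(lev, collapse = ", "),
         call. = FALSE)
  }
  labels <- stats::setNames(match(cls, lev) - 1L, ids)
  extract <- NULL
  if (ncol(df) >= 3L) {
    extract <- stats::setNames(trimws(as.character(df[[3]])), ids)
  }
  sample_classes(labels, class_names = lev, extract_type = extract)
}

#' Write sample class labels to CSV
#'
#' @param classes a \code{sample_classes} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_classes <- function(classes, path) {
  stopifnot(inherits(classes, "sample_classes"))
  df <- data.frame(sample_id = names(classes$labels),
                   class = classes$class_names[classes$labels + 1L],
                   stringsAsFactors = FALSE)
  if (!is.null(classes$extract_type)) {
    df$extract_type <- unname(classes$extract_type[df$sample_id])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Align an abundance table with its class labels
#'
#' Produces the 0/1 label vector in the table's sample (column) order;
#' the column order of the table is never changed.
#'
#' @param table an \code{abundance_table}.
#' @param classes a \code{sample_classes} object covering every sample in
#'   \code{table}.
#' @return a list with elements \code{table} (unchanged), \code{y}
#'   (integer 0/1 vector, one per column of \code{table}), and
#'   \code{class_names}.
#' @export
align <- function(table, classes) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(classes, "sample_classes"))
  missing <- setdiff(table$sample_ids, names(classes$labels))
  if (length(missing)) {
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- unname(classes$labels[table$sample_ids])
  list(table = table, y = y, class_names = classes$class_names)
}
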