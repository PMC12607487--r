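# Two-class PLS-DA: NIPALS PLS1 core, training R2, k-fold cross-validated
# Q2, label-permutation testing, and VIP feature importance.

# NIPALS PLS1 on a scaled X (samples x p) and centered response f.
# For a single response the weight update has a closed form (w = E'f), so
# no inner iteration is needed; X is deflated after each component.
pls1_nipals <- function(X, f, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  E <- X
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w * w))
    if (wn < 1e-14) {
      stop(sprintf("degenerate PLS component %d: no covariance left between X and y", a),
           call. = FALSE)
    }
    w <- w / wn
    t <- E %*% w
    tt <- sum(t * t)
    pl <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, T = Tm, q = q, B = B)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares regression of a 0/1-coded class membership
#' variable on an autoscaled feature matrix, computed by NIPALS with a
#' single response block and deflation of X after each component.
#' Predicted class is \code{1} when the predicted response reaches
#' \code{class_threshold} (0.5 for 0/1 coding).
#'
#' @param X samples x features numeric matrix, or an
#'   \code{abundance_table} (transposed internally). Columns are
#'   autoscaled; a zero-variance column is an error.
#' @param y numeric/integer vector of 0/1 class codes, both classes
#'   present.
#' @param n_components number of latent variables (default 2); must not
#'   exceed \code{min(n_samples - 1, n_features)}.
#' @return an object of class \code{plsda} with unit-norm \code{weights},
#'   \code{x_loadings}, \code{y_loadings}, mutually orthogonal
#'   \code{x_scores}, regression \code{coefficients} (on the scaled X),
#'   the scaling vectors, \code{y_mean}, and training \code{fitted}
#'   values.
#' @export
plsda_fit <- function(X, y, n_components = 2) {
  X <- as_sample_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("length(y) must equal the number of samples", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in y", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("y must be coded 0/1", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1L || n_components > min(n - 1L, p)) {
    stop(sprintf("n_components must be in [1, %d]", min(n - 1L, p)),
         call. = FALSE)
  }
  sc <- autoscale_fast(X)
  ym <- mean(y)
  fit <- pls1_nipals(sc$x, y - ym, n_components)
  fitted <- as.numeric(ym + sc$x %*% fit$B)
  fn <- colnames(X); if (is.null(fn)) fn <- paste0("X", seq_len(p))
  sn <- rownames(X); if (is.null(sn)) sn <- paste0("s", seq_len(n))
  rownames(fit$W) <- rownames(fit$P) <- fn
  rownames(fit$T) <- sn
  structure(list(n_components = n_components,
                 weights = fit$W, x_loadings = fit$P,
                 y_loadings = fit$q, x_scores = fit$T,
                 coefficients = as.numeric(fit$B),
                 x_center = sc$center, x_scale = sc$scale,
                 y_mean = ym, y = y, fitted = fitted,
                 class_threshold = 0.5,
                 feature_ids = fn, sample_ids = sn),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("plsda: %d samples, %d features, %d components\n",
              length(x$y), length(x$feature_ids), x$n_components))
  fs <- r_squared(x)
  cat(sprintf("training R2 = %.4f\n", fs$r2))
  invisible(x)
}

#' Predict from a fitted PLS-DA model
#'
#' @param object a \code{plsda} model.
#' @param newdata samples x features matrix (or \code{abundance_table})
#'   with the training features; scaled with the training statistics.
#' @param ... unused.
#' @return a list with \code{y_hat} (continuous predicted response) and
#'   \code{class} (0/1 decision at the model's class threshold).
#' @export
predict.plsda <- function(object, newdata, ...) {
  X <- as_sample_matrix(newdata)
  if (ncol(X) != length(object$x_center)) {
    stop("newdata has the wrong number of features", call. = FALSE)
  }
  n <- nrow(X)
  Xs <- (X - rep(object$x_center, each = n)) / rep(object$x_scale, each = n)
  y_hat <- as.numeric(object$y_mean + Xs %*% object$coefficients)
  list(y_hat = y_hat,
       class = as.integer(y_hat >= object$class_threshold))
}

#' Training R-squared of a PLS-DA model
#'
#' R2 = 1 - SSE/SST, with SSE the sum of squared residuals between the
#' observed and predicted response and SST the total sum of squares about
#' the response mean.
#'
#' @param model a fitted \code{plsda} model.
#' @param X,y optional data to evaluate on; defaults to the training data
#'   stored in the model.
#' @return an object of class \code{fit_statistics} with \code{r2},
#'   \code{sse}, and \code{sst}.
#' @export
r_squared <- function(model, X = NULL, y = NULL) {
  stopifnot(inherits(model, "plsda"))
  if (is.null(y)) {
    y <- model$y
    y_hat <- model$fitted
  } else {
    if (is.null(X)) stop("supply X together with y", call. = FALSE)
    y <- as.numeric(y)
    y_hat <- predict(model, X)$y_hat
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("constant response: SST is zero", call. = FALSE)
  sse <- sum((y - y_hat)^2)
  structure(list(r2 = 1 - sse / sst, sse = sse, sst = sst),
            class = "fit_statistics")
}

# Stratified fold assignment: within each class, samples are shuffled
# (current RNG state) and dealt round-robin across the k folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (length(unique(fold)) < k) {
    stop("some folds are empty; reduce k", call. = FALSE)
  }
  fold
}

# PRESS/TSS accumulation over the folds of a fixed assignment.
q2_core <- function(X, y, fold, n_components, tss_mean = "train") {
  k <- max(fold)
  press <- 0; tssv <- 0
  gm <- mean(y)
  for (f in seq_len(k)) {
    tr <- fold != f
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) {
      stop("a training fold contains a single class; ",
           "use stratified folds or a smaller k", call. = FALSE)
    }
    sc <- autoscale_fast(X[tr, , drop = FALSE])
    mtr <- mean(ytr)
    fit <- pls1_nipals(sc$x, ytr - mtr, n_components)
    Xte <- X[!tr, , drop = FALSE]
    nte <- nrow(Xte)
    Xte <- (Xte - rep(sc$center, each = nte)) / rep(sc$scale, each = nte)
    y_hat <- mtr + Xte %*% fit$B
    yte <- y[!tr]
    press <- press + sum((yte - y_hat)^2)
    base <- if (tss_mean == "train") mtr else gm
    tssv <- tssv + sum((yte - base)^2)
  }
  list(press = press, tss = tssv, q2 = 1 - press / tssv)
}

#' Cross-validated Q-squared of a PLS-DA model
#'
#' Q2 = 1 - PRESS/TSS over k-fold cross-validation. For each fold the
#' model (including the column scaling) is refitted on the training
#' portion only; PRESS accumulates the held-out squared prediction errors.
#' By default TSS also accumulates held-out squared deviations from the
#' training-fold response mean, so Q2 = 0 corresponds exactly to
#' predicting the training mean; set \code{tss_mean = "global"} to use the
#' overall mean instead. Fold assignment is stratified by class and
#' randomized by \code{seed}.
#'
#' @param X samples x features matrix or \code{abundance_table}.
#' @param y 0/1 class codes.
#' @param k number of folds (default 5); at most the number of samples.
#' @param n_components latent variables per refit (default 2).
#' @param seed integer seed controlling the fold shuffle.
#' @param tss_mean \code{"train"} (default) or \code{"global"}.
#' @return an object of class \code{cv_result} with \code{q2},
#'   \code{press}, \code{tss}, \code{fold_assignments}, \code{k}, and
#'   \code{seed}.
#' @export
q_squared <- function(X, y, k = 5, n_components = 2, seed = 1,
                      tss_mean = c("train", "global")) {
  tss_mean <- match.arg(tss_mean)
  X <- as_sample_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (k < 2L || k > n) stop("k must be in [2, n_samples]", call. = FALSE)
  fold <- with_seed(seed, stratified_folds(y, k))
  res <- q2_core(X, y, fold, n_components, tss_mean)
  sn <- rownames(X); if (is.null(sn)) sn <- paste0("s", seq_len(n))
  structure(list(q2 = res$q2, press = res$press, tss = res$tss,
                 fold_assignments = stats::setNames(fold, sn),
                 k = k, n_components = n_components, seed = seed,
                 tss_mean = tss_mean),
            class = "cv_result")
}

# Permutation p-value per the literal counting rule: the fraction of
# permuted Q2 values that meet or exceed the observed one. The
# (count + 1)/(n + 1) estimator is available via add_one.
perm_p_value <- function(observed, permuted, add_one = FALSE) {
  count <- sum(permuted >= observed)
  if (add_one) (count + 1) / (length(permuted) + 1) else count / length(permuted)
}

#' Permutation test of PLS-DA predictability
#'
#' Builds the null distribution of Q2 by repeatedly permuting the class
#' labels uniformly at random (X fixed) and recomputing the full k-fold
#' cross-validated Q2, with fresh stratified folds per run. The p-value is
#' the fraction of permuted Q2 values that meet or exceed the observed Q2
#' (so 0 is attainable); set \code{add_one = TRUE} for the conventional
#' (count + 1)/(runs + 1) estimator.
#'
#' @inheritParams q_squared
#' @param n_runs number of label permutations (default 1000).
#' @param seed master seed; per-run fold seeds and permutations are drawn
#'   from it, so results are fully reproducible.
#' @param add_one use the (count + 1)/(n + 1) p-value estimator
#'   (default \code{FALSE}).
#' @return an object of class \code{permutation_result} with
#'   \code{observed_q2}, the \code{permuted_q2} vector, \code{n_runs},
#'   \code{p_value}, and \code{seed}.
#' @export
permutation_test <- function(X, y, n_runs = 1000, k = 5, n_components = 2,
                             seed = 1, tss_mean = c("train", "global"),
                             add_one = FALSE) {
  tss_mean <- match.arg(tss_mean)
  if (n_runs < 1L) stop("n_runs must be at least 1", call. = FALSE)
  X <- as_sample_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  draws <- with_seed(seed, {
    list(fold_seeds = sample.int(2147483646L, n_runs + 1L),
         perms = lapply(seq_len(n_runs), function(i) sample.int(n)))
  })
  observed <- q_squared(X, y, k = k, n_components = n_components,
                        seed = draws$fold_seeds[1], tss_mean = tss_mean)$q2
  permuted <- vapply(seq_len(n_runs), function(i) {
    q_squared(X, y[draws$perms[[i]]], k = k, n_components = n_components,
              seed = draws$fold_seeds[i + 1L], tss_mean = tss_mean)$q2
  }, numeric(1))
  structure(list(observed_q2 = observed, permuted_q2 = permuted,
                 n_runs = n_runs,
                 p_value = perm_p_value(observed, permuted, add_one),
                 seed = seed, k = k, n_components = n_components),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed Q2 = %.4f, %d runs, p = %.4g\n",
              x$observed_q2, x$n_runs, x$p_value))
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' The Wold VIP: each feature's squared weights across components,
#' weighted by the response variance each component explains
#' (SSY_a = q_a^2 t_a' t_a) and normalized so the mean squared VIP equals
#' one. Features with VIP above 1 are conventionally read as important
#' for the discrimination.
#'
#' @param model a fitted \code{plsda} model.
#' @param threshold importance cut stored with the result (default 1).
#' @return an object of class \code{vip_vector} with named \code{scores}
#'   and the \code{threshold}.
#' @export
vip <- function(model, threshold = 1) {
  stopifnot(inherits(model, "plsda"))
  W <- model$weights
  ssy <- model$y_loadings^2 * colSums(model$x_scores^2)
  v <- sqrt(nrow(W) * as.numeric(W^2 %*% ssy) / sum(ssy))
  structure(list(scores = stats::setNames(v, model$feature_ids),
                 threshold = threshold),
            class = "vip_vector")
}

#' @export
print.vip_vector <- function(x, ...) {
  cat(sprintf("vip_vector: %d features, %d above threshold %g\n",
              length(x$scores), sum(x$scores >= x$threshold), x$threshold))
  print(sort(x$scores, decreasing = TRUE))
  invisible(x)
}

#' Latent-variable score table for plotting
#'
#' @param model a fitted \code{plsda} model with at least two components.
#' @param classes a \code{sample_classes} object labelling the training
#'   samples.
#' @return a data.frame with columns \code{sample}, \code{LV1},
#'   \code{LV2}, \code{class} (display names), ready to write as CSV.
#' @export
scores_for_plot <- function(model, classes) {
  stopifnot(inherits(model, "plsda"), inherits(classes, "sample_classes"))
  if (model$n_components < 2L) {
    stop("at least two components are required", call. = FALSE)
  }
  lab <- classes$labels[model$sample_ids]
  if (anyNA(lab)) {
    stop("unlabeled sample(s): ",
         paste(model$sample_ids[is.na(lab)], collapse = ", "), call. = FALSE)
  }
  data.frame(sample = model$sample_ids,
             LV1 = model$x_scores[, 1],
             LV2 = model$x_scores[, 2],
             class = classes$class_names[lab + 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}
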