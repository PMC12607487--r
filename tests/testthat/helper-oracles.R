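# Independent oracles used to cross-check the package implementations.
# Each is deliberately written with a different algorithm than the code
# path it validates.

# SIMPLS for a single response (de Jong 1993): returns the regression
# coefficients on the already-scaled X. Cross-checks the NIPALS PLS1 fit.
simpls1_coef <- function(Xs, y0, ncomp) {
  p <- ncol(Xs)
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  s <- crossprod(Xs, y0)
  for (a in seq_len(ncomp)) {
    r <- s
    t <- Xs %*% r
    normt <- sqrt(sum(t^2))
    t <- t / normt
    r <- r / normt
    pa <- crossprod(Xs, t)
    q[a] <- sum(y0 * t)
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    V[, a] <- v
  }
  as.numeric(R %*% q)
}

# Naive O(n^3) average-linkage agglomeration: inter-cluster distance is
# the mean of all original pairwise Euclidean distances. Returns the
# sorted merge heights.
naive_average_linkage_heights <- function(X) {
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Two-pass Pearson correlation: explicit means first, then explicit
# covariance/sd loops, n - 1 convention throughout.
pearson_two_pass <- function(M) {
  nf <- nrow(M)
  ns <- ncol(M)
  mu <- numeric(nf)
  for (i in seq_len(nf)) mu[i] <- sum(M[i, ]) / ns
  out <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    for (j in seq_len(nf)) {
      cv <- sum((M[i, ] - mu[i]) * (M[j, ] - mu[j])) / (ns - 1)
      si <- sqrt(sum((M[i, ] - mu[i])^2) / (ns - 1))
      sj <- sqrt(sum((M[j, ] - mu[j])^2) / (ns - 1))
      out[i, j] <- cv / (si * sj)
    }
  }
  dimnames(out) <- list(rownames(M), rownames(M))
  out
}

# Connected-component count by boolean transitive closure (Warshall).
component_count_closure <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  nrow(unique(reach))
}

# Small labelled abundance fixture used across test files.
toy_table <- function() {
  m <- matrix(c(50, 30, 40, 25,
                20, 10, 15, 30,
                5, 5, 6, 7,
                12, 40, 20, 18),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("linoleic", "clionasterol", "minor1", "oleic"),
                              c("s1", "s2", "s3", "s4")))
  abundance_table(m)
}

toy_classes <- function() {
  sample_classes(stats::setNames(c(0L, 0L, 1L, 1L),
                                 c("s1", "s2", "s3", "s4")),
                 class_names = c("Thai", "Foreign"))
}
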