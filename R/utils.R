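# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Round half away from zero (base round() is round-half-even); used for the
# integer report columns of synergy tables.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Coerce an abundance_table or a plain matrix to features x samples form.
as_feature_matrix <- function(x) {
  if (inherits(x, "abundance_table")) return(x$values)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("input must be numeric", call. = FALSE)
  m
}

# Coerce to the samples x features orientation used by pca()/plsda_fit():
# an abundance_table (features x samples) is transposed, a matrix is taken
# as already being samples x features.
as_sample_matrix <- function(x) {
  if (inherits(x, "abundance_table")) return(t(x$values))
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("input must be numeric", call. = FALSE)
  m
}

# Fast column autoscaling without apply(); errors on zero-variance columns.
autoscale_fast <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  Xc <- X - rep(cm, each = n)
  s <- sqrt(colSums(Xc^2) / (n - 1))
  if (any(s < 1e-12)) {
    bad <- colnames(X)[s < 1e-12]
    if (is.null(bad)) bad <- which(s < 1e-12)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  list(x = Xc / rep(s, each = n), center = cm, scale = s)
}
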