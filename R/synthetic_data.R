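# Generator of class-structured compositional abundance tables and
# bioactivity fixtures, so every pipeline stage is testable without any
# external data.

#' Simulate a two-class GC/MS relative-abundance table
#'
#' Emulates a twelve-sample, two-class metabolite profiling design: two
#' classes of \code{n_per_class} samples (named like hemp-seed cultivar
#' extracts, with extract types O / M-H / M-E cycled within class),
#' \code{n_features} compositional features of which exactly
#' \code{n_major} are guaranteed to reach 10\% relative abundance in at
#' least one sample while every other feature stays below 10\% in all
#' samples, and \code{n_discriminative} class-separated features among
#' the majors.
#'
#' Intensities are drawn log-normally (positive, right-skewed, like GC/MS
#' peak areas) and closed to percent-of-total per sample: minor features
#' share a fixed \code{minor_share} percent of each sample's composition
#' and majors the rest, which keeps the major/minor cutoff guarantees
#' independent. Class separation is applied multiplicatively in log space
#' (delta = \code{effect_size * sigma_log}) to the discriminative
#' features, alternating which class is elevated (feature 1 high in class
#' 0, feature 2 high in class 1, ...), mirroring one dominant marker per
#' class. Each major feature has a "spotlight" sample (cycled over
#' samples; for a discriminative feature, cycled within the class it is
#' elevated in) where a deterministic adjustment loop gently boosts its
#' intensity only when needed, until the >= 10\% / < 10\% guarantees hold
#' exactly — so the downstream cutoff count is reproducible by
#' construction while the injected extra variance stays minimal.
#'
#' @param n_per_class samples per class (default 6, i.e. 12 samples).
#' @param n_features total features (default 61).
#' @param n_major features planted at or above the 10\% cutoff
#'   (default 13).
#' @param n_discriminative class-separated features among the majors
#'   (default 3, named \code{linoleic_acid_like},
#'   \code{clionasterol_like}, \code{vitamin_E_like}).
#' @param effect_size class-mean separation, in units of the log-noise
#'   standard deviation (default 4; 0 gives a null table).
#' @param sigma_log standard deviation of the log-normal intensity noise
#'   (default 0.4).
#' @param minor_share percent of each sample's composition shared by the
#'   minor features (default 25).
#' @param seed integer seed; identical seeds give identical tables.
#' @return a list with \code{table} (an \code{abundance_table}) and
#'   \code{classes} (a \code{sample_classes}; class 0 = "Thai",
#'   class 1 = "Foreign").
#' @export
simulate_abundance <- function(n_per_class = 6, n_features = 61,
                               n_major = 13, n_discriminative = 3,
                               effect_size = 4, sigma_log = 0.4,
                               minor_share = 25, seed = 1) {
  if (n_discriminative > n_major || n_major > n_features) {
    stop("need n_discriminative <= n_major <= n_features", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  n <- 2L * n_per_class
  n_minor <- n_features - n_major
  major_share <- if (n_minor > 0L) 100 - minor_share else 100
  # feasibility: every spotlighted major in a sample must fit >= 10% into
  # the major budget, and minors must be able to stay under 10%
  per_sample <- ceiling(n_major / n)
  if (per_sample * 10 >= major_share) {
    stop("infeasible: too many major features per sample for the 10% guarantee",
         call. = FALSE)
  }
  if (n_minor > 0L && minor_share / n_minor >= 10) {
    stop("infeasible: too few minor features to stay below 10%", call. = FALSE)
  }

  extracts <- c("O", "M-H", "M-E")
  make_ids <- function(prefix) {
    vapply(seq_len(n_per_class), function(i) {
      sprintf("HS-%s-%d-%s", prefix, (i - 1) %/% 3 + 1,
              extracts[(i - 1) %% 3 + 1])
    }, character(1))
  }
  sample_ids <- c(make_ids("TH"), make_ids("FS"))
  y <- rep(c(0L, 1L), each = n_per_class)

  disc_names <- c("linoleic_acid_like", "clionasterol_like", "vitamin_E_like")
  feature_ids <- character(n_features)
  for (j in seq_len(n_features)) {
    feature_ids[j] <- if (j <= n_discriminative && j <= 3L) disc_names[j]
      else if (j <= n_discriminative) sprintf("discriminative_%02d", j)
      else if (j <= n_major) sprintf("major_%02d", j)
      else sprintf("minor_%02d", j)
  }

  pct <- with_seed(seed, {
    raw <- matrix(exp(stats::rnorm(n_features * n, sd = sigma_log)),
                  nrow = n_features, ncol = n)
    # class separation in log space for the discriminative features
    if (n_discriminative > 0L && effect_size > 0) {
      delta <- exp(effect_size * sigma_log)
      for (j in seq_len(n_discriminative)) {
        elevated <- (j - 1L) %% 2L
        raw[j, y == elevated] <- raw[j, y == elevated] * delta
      }
    }
    # spotlight sample per major: the one sample where the adjustment loop
    # may boost the feature so it reaches 10%. Discriminative features are
    # spotlighted inside the class they are elevated in, so any boost
    # reinforces rather than contradicts the class structure.
    spot <- ((seq_len(n_major) - 1L) %% n) + 1L
    if (n_discriminative > 0L) {
      for (j in seq_len(n_discriminative)) {
        elevated <- (j - 1L) %% 2L
        in_class <- which(y == elevated)
        spot[j] <- in_class[((j - 1L) %/% 2L) %% length(in_class) + 1L]
      }
    }
    major_idx <- seq_len(n_major)
    minor_idx <- if (n_minor > 0L) (n_major + 1L):n_features else integer(0)

    share_of <- function(rows, budget) {
      sub <- raw[rows, , drop = FALSE]
      budget * sweep(sub, 2, colSums(sub), "/")
    }
    # enforce: every major reaches >= 10 in some sample
    for (iter in seq_len(200L)) {
      ms <- share_of(major_idx, major_share)
      bad <- which(apply(ms, 1, max) < 10)
      if (!length(bad)) break
      for (j in bad) raw[j, spot[j]] <- raw[j, spot[j]] * 1.25
    }
    if (length(bad <- which(apply(share_of(major_idx, major_share), 1, max) < 10))) {
      stop("major-feature guarantee did not converge", call. = FALSE)
    }
    # enforce: every minor stays < 10 in every sample (margin at 9.5)
    if (n_minor > 0L) {
      for (iter in seq_len(200L)) {
        mn <- share_of(minor_idx, minor_share)
        bad_cell <- which(mn >= 9.5, arr.ind = TRUE)
        if (!nrow(bad_cell)) break
        for (r in seq_len(nrow(bad_cell))) {
          raw[minor_idx[bad_cell[r, 1]], bad_cell[r, 2]] <-
            raw[minor_idx[bad_cell[r, 1]], bad_cell[r, 2]] * 0.5
        }
      }
    }
    out <- matrix(0, n_features, n)
    out[major_idx, ] <- share_of(major_idx, major_share)
    if (n_minor > 0L) out[minor_idx, ] <- share_of(minor_idx, minor_share)
    out
  })

  dimnames(pct) <- list(feature_ids, sample_ids)
  table <- abundance_table(pct)
  classes <- sample_classes(stats::setNames(y, sample_ids),
                            class_names = c("Thai", "Foreign"),
                            extract_type = stats::setNames(
                              rep(extracts[(seq_len(n_per_class) - 1) %% 3 + 1], 2),
                              sample_ids))
  list(table = table, classes = classes)
}

#' Randomly permute class labels
#'
#' Uniform random permutation of the labels across samples, preserving
#' class sizes; used to build null datasets for permutation-calibration
#' checks.
#'
#' @param classes a \code{sample_classes} object with at least two
#'   samples.
#' @param seed integer seed.
#' @return a \code{sample_classes} object with shuffled labels.
#' @export
generate_null_labels <- function(classes, seed = 1) {
  stopifnot(inherits(classes, "sample_classes"))
  labels <- classes$labels
  if (length(labels) < 2L) stop("need at least two samples", call. = FALSE)
  new <- with_seed(seed, stats::setNames(
    unname(labels)[sample.int(length(labels))], names(labels)))
  sample_classes(new, classes$class_names, classes$extract_type)
}

#' Simulate a single/combination bioactivity fixture
#'
#' Three single agents with inhibition near 40\% and three pairwise
#' combinations between 50 and 95\%, constructed from known planted
#' percent improvements relative to the first-listed agent (the first
#' planted improvement is exactly 119). Planted values are returned so
#' recovery can be asserted.
#'
#' @param seed integer seed.
#' @return a list with \code{singles} (data.frame \code{agent,value}),
#'   \code{combos} (data.frame \code{agent_a,agent_b,value}), and
#'   \code{planted} (named integer improvements keyed by
#'   "agent_a+agent_b", reference = agent_a).
#' @export
simulate_bioactivity <- function(seed = 1) {
  with_seed(seed, {
    agents <- c("clionasterol", "linoleic_acid", "vitamin_E")
    singles <- data.frame(agent = agents,
                          value = round(stats::runif(3, 39, 42), 2),
                          stringsAsFactors = FALSE)
    pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    planted <- c(119, round(stats::runif(1, 40, 90)),
                 round(stats::runif(1, 25, 60)))
    combo_value <- singles$value[pairs[, 1]] * (1 + planted / 100)
    combos <- data.frame(agent_a = agents[pairs[, 1]],
                         agent_b = agents[pairs[, 2]],
                         value = combo_value, stringsAsFactors = FALSE)
    names(planted) <- paste(combos$agent_a, combos$agent_b, sep = "+")
    list(singles = singles, combos = combos, planted = planted)
  })
}
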