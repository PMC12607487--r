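test_that("simulate_abundance meets its construction guarantees", {
  sim <- simulate_abundance(seed = 1)
  tab <- sim$table
  expect_equal(dim(tab), c(61L, 12L))
  # valid compositional table: closure to 100% per sample
  expect_true(all(abs(colSums(tab$values) - 100) < 1e-9))
  expect_true(all(tab$values >= 0))

  # exactly 13 features at/above 10% somewhere, the rest below everywhere
  maxima <- apply(tab$values, 1, max)
  expect_equal(sum(maxima >= 10), 13L)
  expect_equal(nrow(cutoff_filter(tab)$values), 13L)

  # classes: 6 + 6 with extract annotation
  expect_equal(unname(table(sim$classes$labels)), c(6L, 6L), ignore_attr = TRUE)
  expect_setequal(unique(sim$classes$extract_type), c("O", "M-H", "M-E"))
})

test_that("simulate_abundance is deterministic under seed", {
  a <- simulate_abundance(seed = 5)
  b <- simulate_abundance(seed = 5)
  c <- simulate_abundance(seed = 6)
  expect_identical(a$table$values, b$table$values)
  expect_false(identical(a$table$values, c$table$values))

  # does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_abundance(seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("effect_size zero removes the class signal", {
  sim <- simulate_abundance(effect_size = 0, seed = 3)
  y <- align(sim$table, sim$classes)$y
  m <- sim$table$values
  tstats <- apply(m, 1, function(v) {
    if (sd(v) < 1e-12) return(0)
    unname(t.test(v[y == 0], v[y == 1])$statistic)
  })
  expect_true(all(abs(tstats) < 4))
})

test_that("infeasible generator configurations are rejected", {
  expect_error(simulate_abundance(n_major = 70), "n_major")
  expect_error(simulate_abundance(n_per_class = 1, n_features = 61,
                                  n_major = 30),
               "infeasible")
  expect_error(simulate_abundance(n_features = 14, n_major = 13),
               "infeasible")  # single minor cannot stay under 10%
  expect_error(simulate_abundance(effect_size = -1), "effect_size")
})

test_that("generate_null_labels permutes labels preserving class sizes", {
  sim <- simulate_abundance(seed = 2)
  shuf <- generate_null_labels(sim$classes, seed = 11)
  expect_equal(sort(unname(shuf$labels)), sort(unname(sim$classes$labels)))
  expect_setequal(names(shuf$labels), names(sim$classes$labels))
  expect_identical(generate_null_labels(sim$classes, seed = 11)$labels,
                   shuf$labels)

  # over many shuffles each sample is in class 0 about half the time
  hits <- rowSums(vapply(1:400, function(i)
    generate_null_labels(sim$classes, seed = i)$labels == 0L,
    logical(12)))
  expect_true(all(hits > 400 * 0.5 - 4 * sqrt(400 * 0.25)))
  expect_true(all(hits < 400 * 0.5 + 4 * sqrt(400 * 0.25)))
})

test_that("bioactivity fixture plants recoverable improvements", {
  fx <- simulate_bioactivity(seed = 4)
  expect_true(all(fx$combos$value <= 100))
  st <- build_synergy_table(fx$singles, fx$combos)
  first_ref <- st$improvements[st$improvements$reference ==
                                 st$improvements$agent_a, ]
  key <- paste(first_ref$agent_a, first_ref$agent_b, sep = "+")
  expect_equal(stats::setNames(first_ref$improvement_rounded, key),
               fx$planted[key])
  expect_equal(unname(fx$planted[1]), 119)

  # round-trips through the CSV interface unchanged
  sp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fx$singles, sp, row.names = FALSE)
  utils::write.csv(fx$combos, cp, row.names = FALSE)
  st2 <- build_synergy_table(read_singles(sp), read_combos(cp))
  expect_equal(st2$improvements$improvement, st$improvements$improvement,
               tolerance = 1e-9)
})

test_that("observed Q2 increases with effect size on average", {
  q2_at <- function(es) {
    vapply(1:20, function(i) {
      sim <- simulate_abundance(effect_size = es, seed = 400 + i)
      filt <- cutoff_filter(sim$table)
      q_squared(t(filt$values), align(filt, sim$classes)$y,
                seed = 400 + i)$q2
    }, numeric(1))
  }
  means <- vapply(c(0, 1, 2, 4), function(es) mean(q2_at(es)), numeric(1))
  expect_true(all(diff(means) > -0.05))
  expect_gt(means[4], means[1] + 0.5)
})

test_that("planted discriminative features clear the VIP threshold", {
  sim <- simulate_abundance(seed = 10)
  filt <- cutoff_filter(sim$table)
  al <- align(filt, sim$classes)
  v <- vip(plsda_fit(t(filt$values), al$y, n_components = 2))
  planted <- c("linoleic_acid_like", "clionasterol_like", "vitamin_E_like")
  expect_true(all(v$scores[planted] > 1))
})
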