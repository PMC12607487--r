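# Published single-agent and combination readouts used as worked examples:
# elastase inhibition means (plain mode) and docking scores (magnitude mode).
elastase_singles <- c(clionasterol = 40.97, linoleic_acid = 41.15,
                      vitamin_E = 40.08)
elastase_combos <- data.frame(
  agent_a = c("clionasterol", "clionasterol", "linoleic_acid"),
  agent_b = c("linoleic_acid", "vitamin_E", "vitamin_E"),
  value = c(89.76, 66.94, 51.88), stringsAsFactors = FALSE)

docking_singles <- c(clionasterol = -6.17, linoleic_acid = 4.14,
                     vitamin_E = -5.26)
docking_combos <- data.frame(
  agent_a = c("clionasterol", "clionasterol", "linoleic_acid"),
  agent_b = c("linoleic_acid", "vitamin_E", "vitamin_E"),
  value = c(-8.03, -10.03, -6.56), stringsAsFactors = FALSE)

test_that("percent_inhibition implements the absorbance formula", {
  expect_equal(percent_inhibition(1.0, 0.5), 50.0)
  expect_equal(percent_inhibition(0.8, 0.8), 0.0)
  expect_equal(percent_inhibition(0.5, 0.6), -20.0)  # activation is negative
  expect_error(percent_inhibition(0, 0.5), "positive")
  # never exceeds 100 for non-negative sample absorbance
  set.seed(1)
  ac <- runif(50, 0.1, 2)
  as_ <- runif(50, 0, 2)
  expect_true(all(percent_inhibition(ac, as_) <= 100))
})

test_that("improvement_pct reproduces the published worked examples", {
  expect_equal(improvement_pct(89.76, 40.97, "plain", rounded = TRUE), 119)
  expect_equal(improvement_pct(89.76, 40.97, "plain"), 119.0844, tolerance = 1e-4)
  expect_equal(improvement_pct(-10.03, -5.26, "magnitude", rounded = TRUE), 91)
  expect_equal(improvement_pct(-8.03, 4.14, "magnitude", rounded = TRUE), 94)
  expect_equal(improvement_pct(5, 5), 0)
  expect_error(improvement_pct(10, 0), "nonzero")
  # antisymmetry around equality
  expect_gt(improvement_pct(6, 5), 0)
  expect_lt(improvement_pct(4, 5), 0)
})

test_that("synergy table reproduces all twelve published bracket integers", {
  st <- build_synergy_table(elastase_singles, elastase_combos, mode = "plain")
  imp <- st$improvements
  get <- function(a, b, ref) imp$improvement_rounded[
    imp$agent_a == a & imp$agent_b == b & imp$reference == ref]
  expect_equal(get("clionasterol", "linoleic_acid", "clionasterol"), 119)
  expect_equal(get("clionasterol", "linoleic_acid", "linoleic_acid"), 118)
  expect_equal(get("clionasterol", "vitamin_E", "vitamin_E"), 67)
  expect_equal(get("clionasterol", "vitamin_E", "clionasterol"), 63)
  expect_equal(get("linoleic_acid", "vitamin_E", "vitamin_E"), 29)
  expect_equal(get("linoleic_acid", "vitamin_E", "linoleic_acid"), 26)

  st4 <- build_synergy_table(docking_singles, docking_combos, mode = "magnitude")
  imp <- st4$improvements
  expect_equal(get("clionasterol", "linoleic_acid", "linoleic_acid"), 94)
  expect_equal(get("clionasterol", "linoleic_acid", "clionasterol"), 30)
  expect_equal(get("clionasterol", "vitamin_E", "vitamin_E"), 91)
  expect_equal(get("clionasterol", "vitamin_E", "clionasterol"), 63)
  expect_equal(get("linoleic_acid", "vitamin_E", "linoleic_acid"), 58)
  expect_equal(get("linoleic_acid", "vitamin_E", "vitamin_E"), 25)
})

test_that("build_synergy_table validates inputs and handles empty combos", {
  expect_error(build_synergy_table(elastase_singles,
                                   data.frame(agent_a = "clionasterol",
                                              agent_b = "mystery",
                                              value = 50)),
               "mystery")
  st <- build_synergy_table(elastase_singles, NULL)
  expect_equal(nrow(st$improvements), 0L)

  # both reference directions present for every combination
  st2 <- build_synergy_table(elastase_singles, elastase_combos)
  expect_equal(nrow(st2$improvements), 6L)
  counts <- table(paste(st2$improvements$agent_a, st2$improvements$agent_b))
  expect_true(all(counts == 2))
})

test_that("synergy CSV interface round-trips", {
  sp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(agent = names(elastase_singles),
                              value = unname(elastase_singles)),
                   sp, row.names = FALSE)
  utils::write.csv(elastase_combos, cp, row.names = FALSE)
  st <- build_synergy_table(read_singles(sp), read_combos(cp))
  expect_setequal(st$improvements$improvement_rounded,
                  c(119, 118, 67, 63, 29, 26))
  op <- withr::local_tempfile(fileext = ".csv")
  write_synergy_table(st, op)
  back <- utils::read.csv(op)
  expect_equal(back$improvement_rounded, st$improvements$improvement_rounded)
})
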