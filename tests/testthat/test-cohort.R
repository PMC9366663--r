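test_that("weekly gate passes bin into the six ordinal categories", {
  x <- c(0, 1, 10, 11, 20, 21, 22, 25, 26, 30, 31, 100)
  expect_equal(categorize_gate_passes(x),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_true(is.na(categorize_gate_passes(NA)))
  expect_error(categorize_gate_passes(-1), "non-negative")
})

test_that("weekly BCU operations bin into the five ordinal categories", {
  x <- c(0, 10, 20, 21, 50, 51, 75, 100, 101, 299, 300, 1000)
  expect_equal(categorize_bcu_ops(x),
               c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_true(is.na(categorize_bcu_ops(NA)))
  expect_error(categorize_bcu_ops(-2), "non-negative")
})

make_cohort <- function(...) {
  base <- tibble::tibble(
    respondent_id = character(), sits_within_3m = logical(),
    gate_label = character(), seat_distance_cm = numeric(),
    hours_in_seat = numeric(), gate_passes_per_week = numeric(),
    uses_bcu = logical(), bcu_label = character(),
    bcu_ops_per_week = numeric())
  rows <- tibble::tibble(...)
  for (col in setdiff(names(base), names(rows))) rows[[col]] <- NA
  rows[names(base)]
}

test_that("cleaning drops blanks and implausible seated hours, with counts", {
  rec <- make_cohort(
    respondent_id = c("a", "b", "c", "d"),
    sits_within_3m = c(TRUE, TRUE, NA, TRUE),
    gate_label = c("gate_i", "gate_i", NA, "gate_ii"),
    hours_in_seat = c(87, 55, NA, 12))
  out <- clean_records(rec)
  expect_equal(out$report$n_input, 4)
  expect_equal(out$report$n_blank_removed, 1)   # row c is fully blank
  expect_equal(out$report$n_outlier_removed, 1) # 87 h/week is implausible
  expect_equal(out$records$respondent_id, c("b", "d"))
  expect_equal(out$report$n_retained, 2)
  # the ceiling is configurable
  expect_equal(clean_records(rec, outlier_ceiling = 90)$report$n_outlier_removed, 0)
})

test_that("imputation preserves observed values and is seed-reproducible", {
  rec <- make_cohort(
    respondent_id = sprintf("r%02d", 1:10),
    sits_within_3m = rep(TRUE, 10),
    gate_label = rep("gate_i", 10),
    gate_passes_per_week = c(22, 22, 5, NA, NA, 12, 0, NA, 35, 35))
  rec$gate_pass_category <- categorize_gate_passes(rec$gate_passes_per_week)
  obs <- rec$gate_pass_category
  out1 <- impute_gate_passes(rec, m = 5, seed = 42)
  out2 <- impute_gate_passes(rec, m = 5, seed = 42)
  expect_identical(out1$gate_pass_category, out2$gate_pass_category)
  expect_equal(out1$gate_pass_category[!is.na(obs)], obs[!is.na(obs)])
  expect_equal(out1$gate_pass_imputed, is.na(obs))
  expect_true(all(out1$gate_pass_category %in% 0:5))
})

test_that("degenerate donor pools impute their single category", {
  rec <- make_cohort(
    respondent_id = c("a", "b", "c"),
    sits_within_3m = rep(TRUE, 3),
    gate_label = rep("gate_iv", 3),
    gate_passes_per_week = c(15, 15, NA))
  rec$gate_pass_category <- categorize_gate_passes(rec$gate_passes_per_week)
  for (seed in 1:5) {
    expect_equal(impute_gate_passes(rec, seed = seed)$gate_pass_category[3], 2L)
  }
})

test_that("imputed draws recover the donor distribution", {
  n_donor <- 500; n_miss <- 1000
  donors <- rep(1:5, each = n_donor / 5)
  rec <- make_cohort(
    respondent_id = sprintf("r%04d", seq_len(n_donor + n_miss)),
    sits_within_3m = rep(TRUE, n_donor + n_miss),
    gate_label = rep("gate_i", n_donor + n_miss),
    gate_passes_per_week = NA_real_)
  rec$gate_pass_category <- c(donors, rep(NA_integer_, n_miss))
  out <- impute_gate_passes(rec, m = 1, seed = 7)  # m = 1: raw draws
  imp <- out$gate_pass_category[(n_donor + 1):(n_donor + n_miss)]
  # multinomial 3 sigma around uniform 1/5
  p <- 0.2; sigma <- sqrt(p * (1 - p) / n_miss)
  props <- as.numeric(table(factor(imp, levels = 1:5))) / n_miss
  expect_true(all(abs(props - p) < 3 * sigma + 1e-12))
})

test_that("strata without donors fall back to the marginal with a warning", {
  rec <- make_cohort(
    respondent_id = c("a", "b", "c"),
    sits_within_3m = c(TRUE, TRUE, FALSE),
    gate_label = c("gate_i", "gate_i", "none"),
    gate_passes_per_week = c(22, 22, NA))
  rec$gate_pass_category <- categorize_gate_passes(rec$gate_passes_per_week)
  expect_warning(out <- impute_gate_passes(rec, seed = 1), "marginal")
  expect_equal(out$gate_pass_category[3], 3L)
})

test_that("pattern classification follows the two source indicators", {
  rec <- make_cohort(
    respondent_id = sprintf("r%d", 1:6),
    sits_within_3m = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    gate_label = c("gate_i", "rfid", "none", "dont_remember_other",
                   "flapper_or_cardreader", "none"),
    uses_bcu = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    bcu_label = c("bcu_i", "bcu_ii", "none", "rf", "none", "bcu_v"))
  expect_equal(classify_pattern(rec), c(1L, 3L, 4L, 2L, 4L, 3L))
  expect_error(classify_pattern(transform(rec, gate_label = "garage")),
               "unknown gate label")
})

test_that("classification is total and single-valued over the vocabulary", {
  gates <- c(paste0("gate_", tolower(as.roman(1:8))), "rfid",
             "flapper_or_cardreader", "dont_remember_other", "none")
  bcus <- c(paste0("bcu_", tolower(as.roman(1:9))), "rf", "other", "none")
  grid <- expand.grid(sits = c(TRUE, FALSE), gate = gates, bcu = bcus,
                      stringsAsFactors = FALSE)
  rec <- make_cohort(
    respondent_id = sprintf("r%03d", seq_len(nrow(grid))),
    sits_within_3m = grid$sits, gate_label = grid$gate, bcu_label = grid$bcu)
  p <- classify_pattern(rec)
  expect_true(all(p %in% 1:4))
  expect_equal(length(p), nrow(grid))
})
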