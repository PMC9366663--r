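test_that("default marginals are valid distributions with surveyed shares", {
  m <- default_marginals()
  expect_s3_class(m, "cohort_marginals")
  expect_equal(m$p_sits_within_3m, 238 / 548)
  expect_equal(sum(m$gate_family_shares), 1)
  expect_equal(unname(m$gate_family_shares["eas_em"]), 178 / 238)
  # "250-300 cm" seat bin share, up to renormalization of the printed column
  expect_equal(unname(m$seat_distance_shares[6]), 36.5 / 100.1, tolerance = 1e-9)
  expect_equal(rowSums(m$bcu_conditional), rep(1, 5), ignore_attr = TRUE)
  # overall EM-BCU prevalence implied by the conditional table
  sit_strata <- paste0("yes|", names(m$gate_family_shares))
  p_em <- m$p_sits_within_3m *
    sum(m$gate_family_shares * m$bcu_conditional[sit_strata, "em"]) +
    (1 - m$p_sits_within_3m) * m$bcu_conditional["no", "em"]
  expect_equal(p_em, 295 / 548)
})

test_that("generation is deterministic in the seed and varies across seeds", {
  a <- generate_cohort(200, seed = 5)
  b <- generate_cohort(200, seed = 5)
  c <- generate_cohort(200, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(nrow(a), 200)
})

test_that("structural dependencies are honored", {
  x <- generate_cohort(2000, seed = 9)
  expect_true(all(is.na(x$seat_distance_cm[!x$sits_within_3m])))
  expect_true(all(x$gate_label[!x$sits_within_3m] == "none"))
  expect_true(all(!is.na(x$seat_distance_cm[x$sits_within_3m])))
  expect_true(all(is.na(x$bcu_ops_per_week[!x$uses_bcu])))
  expect_true(all(x$bcu_label[!x$uses_bcu] == "none"))
  # gate II seats truncated below the configured bin (> 100 cm)
  g2 <- x$seat_distance_cm[x$gate_label == "gate_ii"]
  expect_true(all(g2 > 100))
  m0 <- default_marginals(); m0$missingness_rate <- 0
  y <- generate_cohort(500, m0, seed = 1)
  expect_true(all(!is.na(y$gate_passes_per_week)))
})

test_that("large cohorts recover the marginals within 1 % absolute", {
  n <- 1e5
  x <- generate_cohort(n, seed = 13)
  m <- default_marginals()
  expect_lt(abs(mean(x$sits_within_3m) - m$p_sits_within_3m), 0.01)
  sitters <- x[x$sits_within_3m, ]
  fam <- emfdose:::gate_family(sitters$gate_label)
  fam_props <- table(factor(fam, names(m$gate_family_shares))) / nrow(sitters)
  expect_true(all(abs(fam_props - m$gate_family_shares) < 0.01))
  # seat-distance bins follow the marginal shares, except gate II whose
  # distribution is truncated below bin 3 by design
  not_g2 <- sitters$gate_label != "gate_ii"
  bins <- findInterval(sitters$seat_distance_cm[not_g2], m$seat_distance_edges,
                       rightmost.closed = TRUE)
  bin_props <- tabulate(bins, 6) / sum(not_g2)
  expect_true(all(abs(bin_props - m$seat_distance_shares) < 0.01))
  g2_bins <- findInterval(sitters$seat_distance_cm[!not_g2],
                          m$seat_distance_edges, rightmost.closed = TRUE)
  trunc <- m$seat_distance_shares
  trunc[seq_len(m$gate_ii_min_distance_bin - 1)] <- 0
  trunc <- trunc / sum(trunc)
  expect_true(all(abs(tabulate(g2_bins, 6) / sum(!not_g2) - trunc) < 0.01))
  hbins <- findInterval(sitters$hours_in_seat, m$hours_edges,
                        rightmost.closed = TRUE)
  expect_true(all(abs(tabulate(hbins, 6) / nrow(sitters) - m$hours_shares) < 0.01))
  # gate-pass categories among observed values
  cat_obs <- categorize_gate_passes(x$gate_passes_per_week)
  cat_obs <- cat_obs[!is.na(cat_obs)]
  cat_props <- table(factor(cat_obs, 0:5)) / length(cat_obs)
  expect_true(all(abs(cat_props - m$gate_pass_category_shares) < 0.01))
  expect_lt(abs(mean(is.na(x$gate_passes_per_week)) - m$missingness_rate), 0.01)
  # BCU ops categories among users
  ops <- categorize_bcu_ops(x$bcu_ops_per_week[x$uses_bcu])
  ops_props <- table(factor(ops, 1:5)) / length(ops)
  expect_true(all(abs(ops_props - m$bcu_ops_category_shares) < 0.01))
  # EM BCU model shares among EM users
  em <- x$bcu_label[x$bcu_label %in% names(m$bcu_model_shares)]
  em_props <- table(factor(em, names(m$bcu_model_shares))) / length(em)
  expect_true(all(abs(em_props - m$bcu_model_shares) < 0.01))
})

test_that("survey-sized cohorts hit the published pattern shares", {
  n <- 548
  target <- c(165, 43, 130, 210) / 548
  x <- generate_cohort(n, seed = 21)
  props <- tabulate(classify_pattern(x), 4) / n
  sigma <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(props - target) < 3 * sigma))
})

test_that("invalid marginals are rejected", {
  m <- default_marginals()
  m$gate_family_shares <- c(eas_em = 0.7, rfid = 0.7,
                            flapper_or_cardreader = 0, dont_remember_other = 0)
  expect_error(generate_cohort(10, m), "sum to 1")
  m2 <- default_marginals(); m2$missingness_rate <- 1.5
  expect_error(generate_cohort(10, m2), "\\[0, 1\\]")
})

test_that("fixture cohort reproduces the survey cross-tabulation exactly", {
  fix <- fixture_table3_cohort()
  expect_equal(nrow(fix), 548)
  expect_identical(fix, fixture_table3_cohort())  # byte-stable
  p <- classify_pattern(fix)
  expect_equal(tabulate(p, 4), c(165L, 43L, 130L, 210L))
  # individual cells
  fam <- emfdose:::gate_family(fix$gate_label)
  em_bcu <- fix$bcu_label %in% emfdose:::bcu_model_labels()
  expect_equal(sum(fix$sits_within_3m & fam == "eas_em" & em_bcu), 153)
  expect_equal(sum(!fix$sits_within_3m & fix$bcu_label == "none"), 149)
  expect_equal(sum(em_bcu), 295)
  expect_equal(sum(fix$sits_within_3m), 238)
  # gate II fixture seats observe the truncation
  expect_true(all(fix$seat_distance_cm[fix$gate_label == "gate_ii"] > 100))
})

test_that("synthetic maximum seated exposure stays within the surveyed bound", {
  reg <- load_default_registry()
  worst <- numeric(0)
  for (seed in 1:20) {
    x <- generate_cohort(548, seed = seed)
    res <- run_pipeline(x, reg, seed = seed)
    worst <- c(worst, max(res$profiles$e1, na.rm = TRUE))
  }
  expect_true(all(round(worst) <= 15))
})
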