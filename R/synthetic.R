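#' Default cohort marginals from the library-worker survey
#'
#' The categorical distributions observed in the 548-respondent
#' questionnaire survey, used as sampling marginals by
#' [generate_cohort()]. Shares are stored normalized to sum exactly to 1
#' (the printed percentages carry rounding of order 0.1 %).
#'
#' Two documented departures from full independence across questionnaire
#' dimensions:
#' * the BCU type is drawn conditionally on (sitting status, gate family)
#'   from the survey's published cross-tabulation — EM-gate libraries
#'   predominantly also use EM BCUs, and ignoring that association would
#'   distort the exposure-pattern mix;
#' * gate II (the 14 kHz model) respondents' seat distances are truncated
#'   below at a configurable bin (default: the third bin, >100 cm),
#'   without which unconstrained sampling would produce seated exposures
#'   above the cohort's observed maximum.
#'
#' @return An object of class `cohort_marginals` (a named list).
#' @export
default_marginals <- function() {
  norm <- function(x) x / sum(x)
  m <- list(
    p_sits_within_3m = 238 / 548,
    gate_family_shares = norm(c(eas_em = 178, rfid = 22,
                                flapper_or_cardreader = 8,
                                dont_remember_other = 30)),
    gate_model_shares = stats::setNames(
      norm(c(38.0, 11.5, 0.5, 15.9, 8.2, 1.9, 1.4, 22.6)),
      gate_model_labels()),
    seat_distance_edges = c(0, 50, 100, 150, 200, 250, 300),
    seat_distance_shares = norm(c(1.0, 10.6, 8.7, 33.7, 9.6, 36.5)),
    hours_edges = c(0, 10, 20, 30, 40, 50, 60),
    hours_shares = norm(c(61.1, 20.2, 5.8, 9.1, 3.4, 0.5)),
    gate_pass_category_shares = stats::setNames(
      norm(c(2.4, 16.9, 15.0, 25.6, 18.4, 21.7)), 0:5),
    # P(BCU type | sitting status, gate family), rows = strata
    bcu_conditional = rbind(
      `yes|eas_em`              = c(em = 153, rf = 3, other = 5, none = 17) / 178,
      `yes|rfid`                = c(em = 2, rf = 13, other = 2, none = 5) / 22,
      `yes|flapper_or_cardreader` = c(em = 7, rf = 0, other = 0, none = 1) / 8,
      `yes|dont_remember_other` = c(em = 12, rf = 15, other = 0, none = 3) / 30,
      `no`                      = c(em = 121, rf = 22, other = 18, none = 149) / 310),
    bcu_model_shares = stats::setNames(
      norm(c(41.6, 0.7, 1.7, 2.7, 27.0, 2.4, 0.3, 10.8, 12.8)),
      bcu_model_labels()),
    bcu_ops_category_shares = stats::setNames(
      norm(c(21.4, 21.4, 19.7, 18.6, 19.0)), 1:5),
    missingness_rate = 0.05,
    gate_ii_min_distance_bin = 3L
  )
  structure(m, class = "cohort_marginals")
}

validate_marginals <- function(m) {
  stopifnot(inherits(m, "cohort_marginals"))
  probs <- list(m$gate_family_shares, m$gate_model_shares,
                m$seat_distance_shares, m$hours_shares,
                m$gate_pass_category_shares, m$bcu_model_shares,
                m$bcu_ops_category_shares)
  for (p in probs) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("marginal shares must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (m$p_sits_within_3m < 0 || m$p_sits_within_3m > 1 ||
      m$missingness_rate < 0 || m$missingness_rate > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(m$bcu_conditional) - 1) > 1e-9)) {
    stop("each row of `bcu_conditional` must sum to 1", call. = FALSE)
  }
  invisible(m)
}

# integer count within a sampled frequency bin, used to materialize raw
# weekly counts consistent with the categorizers
gate_pass_count_bins <- list(0L, 1:10, 11:20, 21:25, 26:30, 31:60)
bcu_ops_count_bins <- list(0:20, 21:50, 51:100, 101:299, 300:600)

sample_cat <- function(n, shares) {
  sample.int(length(shares), n, replace = TRUE, prob = shares)
}

#' Generate a synthetic questionnaire cohort
#'
#' Samples respondent records that reproduce the survey's categorical
#' marginals (see [default_marginals()]): sitting prevalence, gate family
#' and model shares, seat-distance and weekly-hours bins (uniform within
#' the sampled bin), weekly gate-pass and BCU-operation categories, and
#' the BCU type conditional on sitting status and gate family. Gate
#' fields are generated only for sitters and BCU fields only for BCU
#' users; gate-pass categories are missing completely at random at
#' `marginals$missingness_rate`.
#'
#' @param n Number of respondents (>= 1).
#' @param marginals A [default_marginals()] object.
#' @param seed Integer seed; the same (n, marginals, seed) always yields
#'   the same cohort.
#' @return A tibble in the questionnaire schema of [read_cohort_csv()].
#' @export
generate_cohort <- function(n, marginals = default_marginals(), seed = 1) {
  stopifnot(n >= 1)
  validate_marginals(marginals)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  m <- marginals

  sits <- stats::runif(n) < m$p_sits_within_3m
  gate_label <- rep("none", n)
  fam <- rep("none", n)
  ns <- sum(sits)
  if (ns > 0) {
    fam_idx <- sample_cat(ns, m$gate_family_shares)
    fam[sits] <- names(m$gate_family_shares)[fam_idx]
    lab <- fam[sits]
    em <- lab == "eas_em"
    lab[em] <- names(m$gate_model_shares)[sample_cat(sum(em), m$gate_model_shares)]
    gate_label[sits] <- lab
  }

  seat_distance_cm <- rep(NA_real_, n)
  hours_in_seat <- rep(NA_real_, n)
  if (ns > 0) {
    bin <- sample_cat(ns, m$seat_distance_shares)
    # gate II seats are truncated below at the configured bin
    is_g2 <- gate_label[sits] == "gate_ii"
    if (any(is_g2)) {
      k <- m$gate_ii_min_distance_bin
      trunc_shares <- m$seat_distance_shares
      trunc_shares[seq_len(k - 1)] <- 0
      bin[is_g2] <- sample_cat(sum(is_g2), trunc_shares)
    }
    lo <- m$seat_distance_edges[bin]; hi <- m$seat_distance_edges[bin + 1]
    seat_distance_cm[sits] <- stats::runif(ns, lo, hi)
    hbin <- sample_cat(ns, m$hours_shares)
    hours_in_seat[sits] <- stats::runif(ns, m$hours_edges[hbin],
                                        m$hours_edges[hbin + 1])
  }

  pass_cat <- sample_cat(n, m$gate_pass_category_shares) - 1L  # categories 0-5
  gate_passes_per_week <- vapply(pass_cat + 1L, function(k) {
    b <- gate_pass_count_bins[[k]]
    b[sample.int(length(b), 1L)]
  }, integer(1))
  miss <- stats::runif(n) < m$missingness_rate
  gate_passes_per_week[miss] <- NA_integer_

  stratum <- ifelse(sits, paste0("yes|", fam), "no")
  cond <- m$bcu_conditional[stratum, , drop = FALSE]
  u <- stats::runif(n)
  cumprob <- t(apply(cond, 1, cumsum))
  bcu_type <- colnames(cond)[max.col(u <= cumprob, ties.method = "first")]
  bcu_label <- bcu_type
  is_em <- bcu_type == "em"
  bcu_label[is_em] <- names(m$bcu_model_shares)[sample_cat(sum(is_em),
                                                           m$bcu_model_shares)]
  uses_bcu <- bcu_type != "none"

  bcu_ops_per_week <- rep(NA_integer_, n)
  nu <- sum(uses_bcu)
  if (nu > 0) {
    ops_cat <- sample_cat(nu, m$bcu_ops_category_shares)
    bcu_ops_per_week[uses_bcu] <- vapply(ops_cat, function(k) {
      b <- bcu_ops_count_bins[[k]]
      b[sample.int(length(b), 1L)]
    }, integer(1))
  }

  tibble::tibble(
    respondent_id = sprintf("r%05d", seq_len(n)),
    sits_within_3m = sits,
    gate_label = gate_label,
    seat_distance_cm = seat_distance_cm,
    hours_in_seat = hours_in_seat,
    gate_passes_per_week = gate_passes_per_week,
    uses_bcu = uses_bcu,
    bcu_label = bcu_label,
    bcu_ops_per_week = bcu_ops_per_week
  )
}

# deterministic proportional allocation of n items to shares p
# (largest-remainder rounding, ties to earlier categories)
alloc_counts <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# deterministic within-bin quantile filling for k values over binned shares
quantile_fill <- function(k, edges, shares) {
  counts <- alloc_counts(k, shares)
  out <- numeric(0)
  for (b in seq_along(counts)) {
    if (counts[b] == 0) next
    lo <- edges[b]; hi <- edges[b + 1]
    out <- c(out, lo + (seq_len(counts[b]) - 0.5) / counts[b] * (hi - lo))
  }
  out
}

#' Deterministic fixture cohort matching the survey cross-tabulation
#'
#' Builds a 548-record cohort whose cross-tabulation of sitting status,
#' gate family and BCU type equals, cell for cell, the published survey
#' counts; gate models, BCU models, frequency categories, seat distances
#' and seated hours are assigned deterministically (largest-remainder
#' allocation of the published shares and within-bin quantile filling),
#' so the fixture is identical across runs.
#'
#' @return A tibble in the questionnaire schema, 548 rows.
#' @export
fixture_table3_cohort <- function() {
  m <- default_marginals()
  cells <- data.frame(
    sits = c(rep(TRUE, 16), rep(FALSE, 4)),
    family = c(rep("eas_em", 4), rep("rfid", 4),
               rep("flapper_or_cardreader", 4), rep("dont_remember_other", 4),
               rep("none", 4)),
    bcu = rep(c("em", "rf", "other", "none"), 5),
    count = c(153, 3, 5, 17,
              2, 13, 2, 5,
              7, 0, 0, 1,
              12, 15, 0, 3,
              121, 22, 18, 149),
    stringsAsFactors = FALSE
  )
  rec <- cells[rep(seq_len(nrow(cells)), cells$count), c("sits", "family", "bcu")]
  n <- nrow(rec)
  stopifnot(n == 548L)

  gate_label <- rec$family
  gate_label[rec$family == "none"] <- "none"
  # the surveyed gate-model counts cover EM sitters plus the unidentified
  # ("other") gates; the 30 unidentified keep their own label, the 178 EM
  # records receive model labels with the unidentified share removed
  em_rows <- which(rec$family == "eas_em")
  model_counts <- c(79, 24, 1, 33, 17, 4, 3, 47 - 30)
  gate_label[em_rows] <- rep(gate_model_labels(),
                             alloc_counts(length(em_rows),
                                          model_counts / sum(model_counts)))

  bcu_label <- rec$bcu
  em_bcu <- which(rec$bcu == "em")
  bcu_label[em_bcu] <- rep(bcu_model_labels(),
                           alloc_counts(length(em_bcu), m$bcu_model_shares))
  uses_bcu <- rec$bcu != "none"

  seat_distance_cm <- rep(NA_real_, n)
  hours_in_seat <- rep(NA_real_, n)
  sit_rows <- which(rec$sits)
  # distances stratified by gate model so the gate II truncation applies
  for (g in unique(gate_label[sit_rows])) {
    rows <- sit_rows[gate_label[sit_rows] == g]
    shares <- m$seat_distance_shares
    if (g == "gate_ii") shares[seq_len(m$gate_ii_min_distance_bin - 1)] <- 0
    seat_distance_cm[rows] <- quantile_fill(length(rows),
                                            m$seat_distance_edges, shares)
  }
  hours_in_seat[sit_rows] <- quantile_fill(length(sit_rows),
                                           m$hours_edges, m$hours_shares)

  pass_reps <- vapply(gate_pass_count_bins, function(b) b[ceiling(length(b) / 2)],
                      integer(1))
  gate_passes_per_week <- rep(pass_reps,
                              alloc_counts(n, m$gate_pass_category_shares))

  bcu_ops_per_week <- rep(NA_integer_, n)
  ops_reps <- vapply(bcu_ops_count_bins, function(b) b[ceiling(length(b) / 2)],
                     integer(1))
  bcu_ops_per_week[uses_bcu] <- rep(ops_reps,
                                    alloc_counts(sum(uses_bcu),
                                                 m$bcu_ops_category_shares))

  tibble::tibble(
    respondent_id = sprintf("f%05d", seq_len(n)),
    sits_within_3m = rec$sits,
    gate_label = gate_label,
    seat_distance_cm = seat_distance_cm,
    hours_in_seat = hours_in_seat,
    gate_passes_per_week = gate_passes_per_week,
    uses_bcu = uses_bcu,
    bcu_label = bcu_label,
    bcu_ops_per_week = bcu_ops_per_week
  )
}
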