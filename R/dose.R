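#' Weekly dose indices D1-D3
#'
#' Weekly ("mid-term") exposure indices are products of an unrounded
#' short-term exposure ratio and a weekly working-condition factor from
#' the questionnaire:
#' * D1 = E1 (% RL) x seated hours per week;
#' * D2 = E2 (% BR) x gate-pass category weight;
#' * D3 = E3 (% peak BR) x BCU-operation category weight.
#'
#' The category weights for the binned weekly frequencies are, by
#' default, the ordinal category codes themselves ({0..5} for gate
#' passes, {1..5} for BCU operations). An alternative scheme uses the
#' bins' representative midpoint counts; it changes the scale of D2/D3
#' but not their ordering. Temporal factors (seconds per gate pass or per
#' BCU operation) are deliberately ignored: the indices rank repeated
#' transient exposure opportunity, they are not time-integrated doses.
#'
#' @param e1,e2,e3 Unrounded short-term exposure ratios, percent.
#' @param hours_in_seat Weekly seated hours (>= 0).
#' @param gate_pass_category Ordinal category 0-5.
#' @param bcu_ops_category Ordinal category 1-5.
#' @param scheme Category weight scheme, `"ordinal"` (default) or
#'   `"midpoint"`.
#' @return Numeric index values (NA in -> NA out).
#' @name dose-indices
NULL

#' @rdname dose-indices
#' @export
d1_index <- function(e1, hours_in_seat) {
  if (any(e1 < 0, na.rm = TRUE) || any(hours_in_seat < 0, na.rm = TRUE)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  e1 * hours_in_seat
}

gate_pass_weights <- function(scheme = c("ordinal", "midpoint")) {
  scheme <- match.arg(scheme)
  # midpoints of the count bins 0, 1-10, 11-20, 21-25, 26-30, >30
  switch(scheme, ordinal = 0:5, midpoint = c(0, 5.5, 15.5, 23, 28, 40))
}

bcu_ops_weights <- function(scheme = c("ordinal", "midpoint")) {
  scheme <- match.arg(scheme)
  # midpoints of the count bins 0-20, 21-50, 51-100, 101-299, >=300
  switch(scheme, ordinal = 1:5, midpoint = c(10, 35.5, 75.5, 200, 350))
}

#' @rdname dose-indices
#' @export
d2_index <- function(e2, gate_pass_category, scheme = c("ordinal", "midpoint")) {
  w <- gate_pass_weights(match.arg(scheme))
  if (any(!is.na(gate_pass_category) &
          (gate_pass_category < 0 | gate_pass_category > 5))) {
    stop("gate-pass category out of range 0-5", call. = FALSE)
  }
  e2 * w[gate_pass_category + 1L]
}

#' @rdname dose-indices
#' @export
d3_index <- function(e3, bcu_ops_category, scheme = c("ordinal", "midpoint")) {
  w <- bcu_ops_weights(match.arg(scheme))
  if (any(!is.na(bcu_ops_category) &
          (bcu_ops_category < 1 | bcu_ops_category > 5))) {
    stop("BCU-operation category out of range 1-5", call. = FALSE)
  }
  e3 * w[bcu_ops_category]
}

#' Population distribution of a dose index from printed marginals
#'
#' Builds the exact discrete distribution of D2 (or D3) implied by the
#' surveyed marginal shares under independence: the gate-type (or
#' BCU-type) respondent shares crossed with the weekly-frequency category
#' shares, each cell's index computed from the unrounded short-term ratio
#' and the category weight.
#'
#' @param index `"d2"` or `"d3"`.
#' @param registry An `emf_registry`.
#' @param marginals A [default_marginals()] object supplying the category
#'   shares.
#' @param scheme Category weight scheme.
#' @return A tibble with columns `value` and `prob` (summing to 1),
#'   sorted by value.
#' @export
index_population_distribution <- function(index = c("d2", "d3"),
                                          registry = load_default_registry(),
                                          marginals = default_marginals(),
                                          scheme = c("ordinal", "midpoint")) {
  index <- match.arg(index)
  scheme <- match.arg(scheme)
  if (index == "d2") {
    ratios <- vapply(seq_len(nrow(registry$gates)), function(i)
      e2_ratio(registry$gates[i, ], registry$reference), numeric(1))
    device_p <- registry$gates$pct_respondents / 100
    weights <- gate_pass_weights(scheme)
    cat_p <- marginals$gate_pass_category_shares
  } else {
    ratios <- vapply(seq_len(nrow(registry$bcus)), function(i)
      e3_ratio(registry$bcus[i, ]), numeric(1))
    device_p <- registry$bcus$pct_respondents / 100
    weights <- bcu_ops_weights(scheme)
    cat_p <- marginals$bcu_ops_category_shares
  }
  device_p <- device_p / sum(device_p)
  cat_p <- cat_p / sum(cat_p)
  grid <- expand.grid(ratio = ratios, weight = weights)
  prob <- as.vector(outer(device_p, cat_p))
  out <- tibble::tibble(value = grid$ratio * grid$weight, prob = prob)
  out <- out[order(out$value), ]
  agg <- stats::aggregate(prob ~ value, data = out, FUN = sum)
  tibble::tibble(value = agg$value, prob = agg$prob)
}

#' Quantile of a discrete distribution
#'
#' Lower quantile of a discrete distribution given as (value, prob):
#' the smallest value whose cumulative probability reaches `p`.
#'
#' @param dist Tibble with columns `value`, `prob`.
#' @param p Probability in (0, 1).
#' @return The quantile value.
#' @export
distribution_quantile <- function(dist, p = 0.5) {
  stopifnot(p > 0, p < 1)
  dist <- dist[order(dist$value), ]
  cum <- cumsum(dist$prob) / sum(dist$prob)
  dist$value[which(cum >= p)[1]]
}

#' Per-pattern summary of exposure ratios and dose indices
#'
#' Summarizes each exposure measure over the respondents for whom it is
#' defined, within each exposure pattern and over patterns 1-3 combined
#' ("total"; pattern 4 carries no exposure so it contributes no rows).
#' Statistics: n, median, mean, sample SD (n-1 denominator), max, min.
#'
#' @param profiles Tibble of per-respondent exposure profiles with a
#'   `pattern` column and the measure columns (any of `e1`, `e2`, `e3`,
#'   `d1`, `d2`, `d3`); `NA` means "index not defined for this
#'   respondent".
#' @param measures Which columns to summarize.
#' @return A tibble with columns `pattern` (`"total"`, `"1"`, `"2"`,
#'   `"3"`), `n` (respondents in the subcohort), then per measure the
#'   statistics as `<measure>_median` etc.
#' @export
summarize_by_pattern <- function(profiles,
                                 measures = intersect(c("e1", "e2", "e3", "d1", "d2", "d3"),
                                                      names(profiles))) {
  stopifnot("pattern" %in% names(profiles))
  groups <- list(total = profiles$pattern %in% 1:3,
                 `1` = profiles$pattern == 1L,
                 `2` = profiles$pattern == 2L,
                 `3` = profiles$pattern == 3L)
  rows <- lapply(names(groups), function(g) {
    sub <- profiles[groups[[g]], , drop = FALSE]
    row <- tibble::tibble(pattern = g, n = nrow(sub))
    for (m in measures) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      stats <- if (length(v) == 0) {
        c(median = NA_real_, average = NA_real_, sd = NA_real_,
          max = NA_real_, min = NA_real_)
      } else {
        c(median = stats::median(v), average = mean(v),
          sd = if (length(v) > 1) stats::sd(v) else NA_real_,
          max = max(v), min = min(v))
      }
      names(stats) <- paste(m, names(stats), sep = "_")
      row <- tibble::tibble(row, !!!as.list(stats))
    }
    row
  })
  do.call(rbind, rows)
}

#' Histogram counts over explicit bin edges
#'
#' Left-closed, right-open binning; the final bin is closed on both
#' sides so the maximum is counted.
#'
#' @param values Finite numeric values within the edge range.
#' @param bin_edges Strictly increasing edges (length >= 2).
#' @return Integer counts, one per bin; they sum to `length(values)`.
#' @export
dose_histogram <- function(values, bin_edges) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing",
                                      call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  k <- length(bin_edges) - 1L
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  if (any(idx < 1L | idx > k)) stop("values outside the bin range", call. = FALSE)
  tabulate(idx, nbins = k)
}

#' Mann-Whitney U test between two exposure groups
#'
#' Rank-sum comparison of two independent groups: the U statistic with
#' tie correction and a two-sided p-value, exact (by enumeration) when
#' both groups are small (min n <= 8) and tie-free, otherwise the normal
#' approximation with continuity correction. Computation is delegated to
#' [stats::wilcox.test()], whose W statistic is U for the first group.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list with `u` and `p_value`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- !ties && min(length(group_a), length(group_b)) <= 8
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(u = unname(res$statistic), p_value = res$p.value)
}
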