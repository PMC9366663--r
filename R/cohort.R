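#' Categorize weekly gate passes
#'
#' Weekly gate-pass counts are collapsed into six ordinal categories:
#' 0 -> 0, 1-10 -> 1, 11-20 -> 2, 21-25 -> 3, 26-30 -> 4, >30 -> 5.
#'
#' @param passes_per_week Non-negative counts (vectorized; `NA` passes
#'   through as `NA`).
#' @return Integer categories 0-5.
#' @export
categorize_gate_passes <- function(passes_per_week) {
  if (any(passes_per_week < 0, na.rm = TRUE)) {
    stop("gate-pass counts must be non-negative", call. = FALSE)
  }
  as.integer(findInterval(passes_per_week, c(1, 11, 21, 26, 31)))
}

#' Categorize weekly BCU operations
#'
#' Weekly book-processing counts are collapsed into five ordinal
#' categories: 0-20 -> 1, 21-50 -> 2, 51-100 -> 3, 101-299 -> 4,
#' >=300 -> 5.
#'
#' @param books_per_week Non-negative counts (vectorized; `NA` passes
#'   through).
#' @return Integer categories 1-5.
#' @export
categorize_bcu_ops <- function(books_per_week) {
  if (any(books_per_week < 0, na.rm = TRUE)) {
    stop("BCU-operation counts must be non-negative", call. = FALSE)
  }
  as.integer(findInterval(books_per_week, c(21, 51, 101, 300)) + 1L)
}

#' Clean questionnaire records
#'
#' Drops fully blank rows and rows whose weekly seated hours exceed a
#' plausibility ceiling (implausible as a weekly schedule), and reports
#' the counts.
#'
#' @param records A cohort tibble in the questionnaire schema (see
#'   [read_cohort_csv()]).
#' @param outlier_ceiling Maximum plausible `hours_in_seat` per week;
#'   rows above it are removed.
#' @return A list with `records` (the retained rows) and `report`, a list
#'   of counts (`n_input`, `n_blank_removed`, `n_outlier_removed`,
#'   `n_retained`).
#' @export
clean_records <- function(records, outlier_ceiling = 80) {
  n_input <- nrow(records)
  content_cols <- setdiff(names(records), "respondent_id")
  blank <- apply(is.na(records[content_cols]) |
                   records[content_cols] == "", 1, all)
  blank[is.na(blank)] <- FALSE
  records <- records[!blank, , drop = FALSE]
  outlier <- !is.na(records$hours_in_seat) &
    records$hours_in_seat > outlier_ceiling
  records <- records[!outlier, , drop = FALSE]
  list(
    records = records,
    report = list(
      n_input = n_input,
      n_blank_removed = sum(blank),
      n_outlier_removed = sum(outlier),
      n_retained = nrow(records)
    )
  )
}

# gate family used for stratification and pattern logic
gate_family <- function(gate_label) {
  fam <- rep(NA_character_, length(gate_label))
  fam[gate_label %in% gate_model_labels()] <- "eas_em"
  fam[gate_label %in% c("rfid")] <- "rfid"
  fam[gate_label %in% c("flapper_or_cardreader")] <- "flapper_or_cardreader"
  fam[gate_label %in% c("dont_remember_other")] <- "dont_remember_other"
  fam[gate_label %in% c("none")] <- "none"
  bad <- !is.na(gate_label) & is.na(fam)
  if (any(bad)) {
    stop("unknown gate label(s): ",
         paste(unique(gate_label[bad]), collapse = ", "), call. = FALSE)
  }
  fam
}

#' Multiple imputation of missing gate-pass categories
#'
#' Stratified hot-deck multiple imputation: missing `gate_pass_category`
#' values are filled by drawing `m` times from the empirical distribution
#' of observed categories within the same stratum (sitting status x gate
#' family); the assigned category is the modal draw, ties resolved to the
#' lower category. Strata without observed donors fall back to the
#' marginal distribution with a warning. Observed values are never
#' altered.
#'
#' @param records Cohort tibble with columns `gate_pass_category`,
#'   `sits_within_3m`, `gate_label`.
#' @param m Number of imputation draws per missing value.
#' @param seed Integer seed for reproducibility.
#' @return `records` with missing categories filled and a logical column
#'   `gate_pass_imputed` recording which rows were imputed.
#' @export
impute_gate_passes <- function(records, m = 5, seed = 1) {
  obs <- !is.na(records$gate_pass_category)
  if (!any(obs)) stop("no observed gate-pass categories to impute from",
                      call. = FALSE)
  records$gate_pass_imputed <- !obs
  if (all(obs)) return(records)

  fam <- gate_family(records$gate_label)
  stratum <- paste(records$sits_within_3m, fam, sep = "|")
  marginal <- records$gate_pass_category[obs]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  for (i in which(!obs)) {
    donors <- records$gate_pass_category[obs & stratum == stratum[i]]
    if (length(donors) == 0L) {
      warning("no donors in stratum '", stratum[i],
              "'; falling back to the marginal distribution", call. = FALSE)
      donors <- marginal
    }
    draws <- donors[sample.int(length(donors), m, replace = TRUE)]
    tab <- table(draws)
    modal <- as.integer(names(tab)[tab == max(tab)])
    records$gate_pass_category[i] <- min(modal)   # ties to the lower category
  }
  records
}

#' Classify a respondent's exposure pattern
#'
#' Four mutually exclusive patterns by presence of the two source types:
#' a respondent is IF-EMF exposed when they sit within 3 m of an EM-EAS
#' gate or of a gate they could not identify (treated as EM), and
#' pulsed-EMF exposed when they use an EM-type BCU. Pattern 1 = both,
#' 2 = IF-EMF only, 3 = pulsed only, 4 = neither.
#'
#' @param records Cohort tibble with columns `sits_within_3m`,
#'   `gate_label`, `bcu_label`.
#' @return Integer vector of patterns 1-4.
#' @export
classify_pattern <- function(records) {
  fam <- gate_family(records$gate_label)
  sits <- records$sits_within_3m
  sits[is.na(sits)] <- FALSE
  if_exposed <- sits & !is.na(fam) & fam %in% c("eas_em", "dont_remember_other")
  bcu <- records$bcu_label
  bad <- !is.na(bcu) & !(bcu %in% c(bcu_model_labels(), bcu_nonsource_labels()))
  if (any(bad)) {
    stop("unknown BCU label(s): ",
         paste(unique(bcu[bad]), collapse = ", "), call. = FALSE)
  }
  pulsed <- !is.na(bcu) & bcu %in% bcu_model_labels()
  ifelse(if_exposed & pulsed, 1L,
         ifelse(if_exposed, 2L,
                ifelse(pulsed, 3L, 4L)))
}
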