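cohort_schema <- c("respondent_id", "sits_within_3m", "gate_label",
                   "seat_distance_cm", "hours_in_seat", "gate_passes_per_week",
                   "uses_bcu", "bcu_label", "bcu_ops_per_week")

#' Read a questionnaire cohort from CSV
#'
#' Expects the header columns `respondent_id, sits_within_3m, gate_label,
#' seat_distance_cm, hours_in_seat, gate_passes_per_week, uses_bcu,
#' bcu_label, bcu_ops_per_week`. Empty cells are missing values (never
#' zero). `sits_within_3m` and `uses_bcu` accept yes/no (or true/false,
#' case-insensitive). Unknown gate or BCU labels are reported with their
#' row numbers.
#'
#' @param path Path to a CSV file.
#' @return A tibble in the cohort schema.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), colClasses = "character")
  missing_cols <- setdiff(cohort_schema, names(tab))
  unknown_cols <- setdiff(names(tab), cohort_schema)
  if (length(missing_cols) || length(unknown_cols)) {
    stop("cohort CSV schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "], unknown: [",
         paste(unknown_cols, collapse = ", "), "]", call. = FALSE)
  }
  parse_yn <- function(x, col) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("yes", "true")] <- TRUE
    out[tolower(x) %in% c("no", "false")] <- FALSE
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) stop("column '", col, "': unrecognized value(s) at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    out
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) stop("column '", col, "': non-numeric value(s) at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    out
  }
  check_labels <- function(x, allowed, col) {
    x <- ifelse(is.na(x), x, tolower(trimws(x)))
    bad <- which(!is.na(x) & !(x %in% allowed))
    if (length(bad)) stop("column '", col, "': unknown label(s) ",
                          paste(unique(x[bad]), collapse = ", "),
                          " at row(s) ", paste(bad, collapse = ", "),
                          call. = FALSE)
    x
  }
  tibble::tibble(
    respondent_id = tab$respondent_id,
    sits_within_3m = parse_yn(tab$sits_within_3m, "sits_within_3m"),
    gate_label = check_labels(tab$gate_label,
                              c(gate_model_labels(), gate_nonsource_labels(),
                                "dont_remember_other"), "gate_label"),
    seat_distance_cm = parse_num(tab$seat_distance_cm, "seat_distance_cm"),
    hours_in_seat = parse_num(tab$hours_in_seat, "hours_in_seat"),
    gate_passes_per_week = parse_num(tab$gate_passes_per_week,
                                     "gate_passes_per_week"),
    uses_bcu = parse_yn(tab$uses_bcu, "uses_bcu"),
    bcu_label = check_labels(tab$bcu_label,
                             c(bcu_model_labels(), bcu_nonsource_labels()),
                             "bcu_label"),
    bcu_ops_per_week = parse_num(tab$bcu_ops_per_week, "bcu_ops_per_week")
  )
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]; logical columns are serialized as
#' yes/no and missing values as empty cells.
#'
#' @param records Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  out <- records[cohort_schema]
  out$sits_within_3m <- ifelse(out$sits_within_3m, "yes", "no")
  out$uses_bcu <- ifelse(out$uses_bcu, "yes", "no")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-respondent exposure profiles
#'
#' Computes, for each (cleaned, imputed) respondent: the short-term
#' exposure ratios E1 (seated whole-body, % of RL), E2 (gate pass, % of
#' BR) and E3 (BCU pulse, % of peak BR); the weekly dose indices D1-D3;
#' the exposure pattern; and quality flags (`distance_clamped`,
#' `substituted_device`, `rough_estimate`). An `NA` ratio or index means
#' the respondent has no such source, not a zero exposure.
#'
#' E1/D1 require a seat near an IF-EMF gate with a known distance; E2/D2
#' an IF-EMF gate (D2 additionally a gate-pass category); E3/D3 an
#' EM-type BCU (D3 additionally an operation category).
#'
#' @param records Cohort tibble with `gate_pass_category` and
#'   `bcu_ops_category` columns already present (see [run_pipeline()] for
#'   the full raw-counts path).
#' @param registry An `emf_registry`.
#' @param scheme Category weight scheme for D2/D3.
#' @return A tibble, one row per respondent.
#' @export
exposure_profiles <- function(records, registry = load_default_registry(),
                              scheme = c("ordinal", "midpoint")) {
  scheme <- match.arg(scheme)
  n <- nrow(records)
  pattern <- classify_pattern(records)

  e1 <- e2 <- e3 <- d1 <- d2 <- d3 <- rep(NA_real_, n)
  distance_clamped <- rep(FALSE, n)
  substituted_device <- rep(FALSE, n)
  rough_estimate <- rep(FALSE, n)

  if_rows <- which(pattern %in% c(1L, 2L))
  for (label in unique(records$gate_label[if_rows])) {
    rows <- if_rows[records$gate_label[if_rows] == label]
    gate <- resolve_gate(label, registry)
    substituted_device[rows] <- !is.na(gate$substituted_from) ||
      label == "dont_remember_other"
    e2[rows] <- e2_ratio(gate, registry$reference)
    has_r <- rows[!is.na(records$seat_distance_cm[rows])]
    if (length(has_r)) {
      v <- e1_ratio(gate, records$seat_distance_cm[has_r])
      e1[has_r] <- as.numeric(v)
      distance_clamped[has_r] <- attr(v, "clamped")
    }
  }
  ok1 <- !is.na(e1) & !is.na(records$hours_in_seat)
  d1[ok1] <- d1_index(e1[ok1], records$hours_in_seat[ok1])
  ok2 <- !is.na(e2) & !is.na(records$gate_pass_category)
  d2[ok2] <- d2_index(e2[ok2], records$gate_pass_category[ok2], scheme)

  pulsed_rows <- which(pattern %in% c(1L, 3L))
  for (label in unique(records$bcu_label[pulsed_rows])) {
    rows <- pulsed_rows[records$bcu_label[pulsed_rows] == label]
    bcu <- resolve_bcu(label, registry)
    substituted_device[rows] <- substituted_device[rows] |
      identical(bcu$estimate_kind, "substituted")
    rough_estimate[rows] <- identical(bcu$estimate_kind, "rough_estimate")
    e3[rows] <- e3_ratio(bcu)
  }
  ok3 <- !is.na(e3) & !is.na(records$bcu_ops_category)
  d3[ok3] <- d3_index(e3[ok3], records$bcu_ops_category[ok3], scheme)

  tibble::tibble(
    respondent_id = records$respondent_id,
    pattern = pattern,
    e1 = e1, e2 = e2, e3 = e3,
    d1 = d1, d2 = d2, d3 = d3,
    distance_clamped = distance_clamped,
    substituted_device = substituted_device,
    rough_estimate = rough_estimate
  )
}

#' Run the full exposure-assessment pipeline
#'
#' Cleans the cohort (blank rows, implausible seated hours), categorizes
#' weekly gate-pass and BCU-operation counts, imputes missing gate-pass
#' categories by stratified hot-deck multiple imputation, resolves
#' devices, computes short-term ratios (E1-E3) and weekly dose indices
#' (D1-D3), classifies exposure patterns and summarizes by pattern.
#' Deterministic given `seed`.
#'
#' @param records Cohort tibble in the raw questionnaire schema (counts,
#'   not categories), e.g. from [read_cohort_csv()] or
#'   [generate_cohort()].
#' @param registry An `emf_registry`.
#' @param outlier_ceiling Plausibility ceiling for weekly seated hours.
#' @param m Number of imputation draws.
#' @param seed Seed for the imputation draws.
#' @param scheme Category weight scheme for D2/D3.
#' @return A list with `profiles` (per-respondent tibble), `summary`
#'   (per-pattern statistics), `clean_report`, and the processed
#'   `records`.
#' @export
run_pipeline <- function(records, registry = load_default_registry(),
                         outlier_ceiling = 80, m = 5, seed = 1,
                         scheme = c("ordinal", "midpoint")) {
  scheme <- match.arg(scheme)
  cleaned <- clean_records(records, outlier_ceiling)
  rec <- cleaned$records
  rec$gate_pass_category <- categorize_gate_passes(rec$gate_passes_per_week)
  rec$bcu_ops_category <- categorize_bcu_ops(rec$bcu_ops_per_week)
  if (any(is.na(rec$gate_pass_category))) {
    rec <- impute_gate_passes(rec, m = m, seed = seed)
  } else {
    rec$gate_pass_imputed <- FALSE
  }
  profiles <- exposure_profiles(rec, registry, scheme)
  list(
    profiles = profiles,
    summary = summarize_by_pattern(profiles),
    clean_report = cleaned$report,
    records = rec
  )
}
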