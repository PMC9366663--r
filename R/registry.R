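#' Constants of the reference gate used for internal-field scaling
#'
#' The transient internal electric field induced while passing an EAS gate
#' was computed by voxel-model numerical dosimetry for a single reference
#' gate (14 kHz, spatially averaged field 111 uT, 99th-percentile internal
#' field 0.88 V/m). All other gates are scaled from it, linearly in
#' frequency and in the spatially averaged field.
#'
#' @return A list with elements `e_ref` (V/m), `f_ref` (Hz), `b_iec_ref` (uT).
#' @export
reference_gate_constants <- function() {
  list(e_ref = 0.88, f_ref = 14000, b_iec_ref = 111)
}

#' Load the bundled device registry
#'
#' Reads the bundled parameter tables for the eight surveyed EAS gate
#' types and nine book-check-unit (BCU) types and resolves derived
#' quantities: each gate's internal electric field (via the
#' frequency-and-field scaling from the reference gate, see
#' [internal_field_scaled()]) and the substitution provenance for devices
#' whose parameters were taken from a measured representative model.
#'
#' Substitutions encoded in the bundled tables: gates III and VIII carry
#' gate I's spatially averaged field, gate VI carries gate IV's; BCUs II,
#' III, IV, VI, VII and IX carry BCU I's peak internal field.
#'
#' @param path Directory containing `gates.tsv` and `bcus.tsv`; defaults
#'   to the files bundled with the package.
#' @return An object of class `emf_registry`: a list with tibbles `gates`
#'   and `bcus` plus the `reference` gate constants.
#' @examples
#' reg <- load_default_registry()
#' reg$gates[reg$gates$gate_id == "gate_ii", c("frequency_hz", "b_iec_ut")]
#' @export
load_default_registry <- function(path = system.file("extdata", package = "emfdose")) {
  gates <- read_registry_table(file.path(path, "gates.tsv"))
  bcus <- read_registry_table(file.path(path, "bcus.tsv"))
  stopifnot(nrow(gates) == 8L, nrow(bcus) == 9L)
  ref <- reference_gate_constants()
  gates$internal_field_vm <- ref$e_ref *
    (gates$frequency_hz / ref$f_ref) * (gates$b_iec_ut / ref$b_iec_ref)
  if (any(gates$frequency_hz <= 0 | gates$b_iec_ut <= 0)) {
    stop("registry gates must have positive frequency and field", call. = FALSE)
  }
  if (any(bcus$ein_peak_vm <= 0)) {
    stop("registry BCUs must have positive peak internal field", call. = FALSE)
  }
  structure(list(gates = gates, bcus = bcus, reference = ref),
            class = "emf_registry")
}

read_registry_table <- function(file) {
  if (!file.exists(file)) stop("registry file not found: ", file, call. = FALSE)
  tab <- utils::read.delim(file, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"), fill = TRUE,
                           stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' @export
print.emf_registry <- function(x, ...) {
  cat("<emf_registry> ", nrow(x$gates), " EAS gate types, ",
      nrow(x$bcus), " BCU types\n", sep = "")
  invisible(x)
}

# Controlled questionnaire vocabularies. Gate answers distinguish the EM
# (IF-EMF emitting) gate models from gate technologies with no IF-EMF
# emission; BCU answers distinguish EM (pulse emitting) models from RF and
# other devices.
gate_model_labels <- function() paste0("gate_", tolower(as.roman(1:8)))
bcu_model_labels <- function() paste0("bcu_", tolower(as.roman(1:9)))
gate_nonsource_labels <- function() c("rfid", "flapper_or_cardreader", "none")
bcu_nonsource_labels <- function() c("rf", "other", "none")

#' Resolve a questionnaire gate answer to a gate model
#'
#' Maps a controlled-vocabulary questionnaire answer to the corresponding
#' gate parameter record. Gate types that could not be identified by the
#' respondent (`"dont_remember_other"`) map to gate VIII, which itself
#' carries gate I's parameters (the most common model). Answers naming a
#' technology with no IF-EMF emission (`"rfid"`,
#' `"flapper_or_cardreader"`, `"none"`) return `NULL`, an explicit
#' no-source marker.
#'
#' @param label Questionnaire answer (case-insensitive).
#' @param registry An `emf_registry`, by default the bundled one.
#' @return A one-row tibble from `registry$gates`, or `NULL` when the
#'   answer names no IF-EMF source.
#' @export
resolve_gate <- function(label, registry = load_default_registry()) {
  label <- tolower(trimws(label))
  stopifnot(length(label) == 1L)
  if (label %in% gate_nonsource_labels()) return(NULL)
  if (label == "dont_remember_other") label <- "gate_viii"
  if (!label %in% gate_model_labels()) {
    stop("unknown gate label: '", label, "'", call. = FALSE)
  }
  registry$gates[registry$gates$gate_id == label, ]
}

#' Resolve a questionnaire BCU answer to a BCU model
#'
#' EM-type BCU answers map to their parameter record (unmeasured EM models
#' carry BCU I's peak internal field, recorded as substituted). Answers
#' `"rf"`, `"other"` and `"none"` name devices with no strong pulsed
#' magnetic field and return `NULL`.
#'
#' @param label Questionnaire answer (case-insensitive).
#' @inheritParams resolve_gate
#' @return A one-row tibble from `registry$bcus`, or `NULL`.
#' @export
resolve_bcu <- function(label, registry = load_default_registry()) {
  label <- tolower(trimws(label))
  stopifnot(length(label) == 1L)
  if (label %in% bcu_nonsource_labels()) return(NULL)
  if (!label %in% bcu_model_labels()) {
    stop("unknown BCU label: '", label, "'", call. = FALSE)
  }
  registry$bcus[registry$bcus$bcu_id == label, ]
}
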