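#' Magnetic flux density near an EAS gate at a seated distance
#'
#' The field around an EM-EAS gate decays with distance r (cm) as a power
#' law calibrated on three-dimensional field maps of measured gates:
#' B(r) = b_iec * 7.84e4 * r^-2.89, with b_iec the 45-point spatially
#' averaged flux density of the gate (uT). The calibration holds for
#' r > 50 cm; smaller distances are clamped to 50 cm (flagged via the
#' `"clamped"` attribute) rather than extrapolated.
#'
#' @param gate A one-row gate record from the registry (needs columns
#'   `b_iec_ut`).
#' @param r_cm Seated distance from the gate in cm (vectorized, > 0).
#' @return Flux density at the seat, microtesla, with attribute
#'   `"clamped"` (logical vector).
#' @export
field_at_distance <- function(gate, r_cm) {
  if (any(!is.finite(r_cm)) || any(r_cm <= 0)) {
    stop("`r_cm` must be positive and finite", call. = FALSE)
  }
  clamped <- r_cm < 50
  r <- pmax(r_cm, 50)
  b <- gate$b_iec_ut * 7.84e4 * r^(-2.89)
  attr(b, "clamped") <- clamped
  b
}

#' E1: seated whole-body exposure ratio against the reference level
#'
#' The flux density at the respondent's seat, as a percentage of the
#' ICNIRP 2010 occupational reference level at the gate's operating
#' frequency.
#'
#' @inheritParams field_at_distance
#' @return Percent of the occupational RL, attribute `"clamped"` as in
#'   [field_at_distance()].
#' @examples
#' reg <- load_default_registry()
#' e1_ratio(resolve_gate("gate_iv", reg), 200)  # ~0.19 %
#' @export
e1_ratio <- function(gate, r_cm) {
  b <- field_at_distance(gate, r_cm)
  out <- 100 * as.numeric(b) / rl_occupational(gate$frequency_hz)
  attr(out, "clamped") <- attr(b, "clamped")
  out
}

#' Internal electric field of a gate, scaled from the reference gate
#'
#' Induced internal electric fields near geometrically similar gates scale
#' linearly with operating frequency and with the spatially averaged flux
#' density, so every gate's internal field is obtained from the one
#' numerically characterized reference gate:
#' E = e_ref * (f / f_ref) * (b_iec / b_iec_ref).
#'
#' @param gate A one-row gate record (columns `frequency_hz`, `b_iec_ut`).
#' @param ref Reference constants, see [reference_gate_constants()].
#' @return Internal electric field, V/m (rms).
#' @export
internal_field_scaled <- function(gate, ref = reference_gate_constants()) {
  if (any(gate$frequency_hz <= 0) || any(gate$b_iec_ut <= 0)) {
    stop("gate parameters must be positive", call. = FALSE)
  }
  ref$e_ref * (gate$frequency_hz / ref$f_ref) * (gate$b_iec_ut / ref$b_iec_ref)
}

#' E2: transient gate-pass exposure ratio against the basic restriction
#'
#' The gate's scaled internal electric field as a percentage of the
#' ICNIRP 2010 occupational basic restriction at the gate's operating
#' frequency.
#'
#' @inheritParams internal_field_scaled
#' @return Percent of the occupational BR.
#' @examples
#' reg <- load_default_registry()
#' e2_ratio(resolve_gate("gate_ii", reg))  # ~23 %
#' @export
e2_ratio <- function(gate, ref = reference_gate_constants()) {
  100 * internal_field_scaled(gate, ref) /
    br_occupational(gate$frequency_hz)
}

# Spectral peak of the monophasic magnetizing pulse; the basic restriction
# is flat below 3 kHz so the exact value within that band is inert.
pulse_spectral_peak_hz <- 200

#' E3: BCU pulse exposure ratio against the peak basic restriction
#'
#' The BCU's peak induced internal electric field as a percentage of the
#' peak-converted occupational basic restriction, evaluated at the pulse's
#' spectral peak (~200 Hz, within the flat sub-3 kHz band).
#'
#' @param bcu A one-row BCU record (column `ein_peak_vm`).
#' @return Percent of the peak-pulse BR.
#' @examples
#' reg <- load_default_registry()
#' e3_ratio(resolve_bcu("bcu_i", reg))  # ~3.4 %
#' @export
e3_ratio <- function(bcu) {
  if (is.null(bcu) || any(is.na(bcu$ein_peak_vm))) {
    stop("BCU has no resolved peak internal field", call. = FALSE)
  }
  100 * bcu$ein_peak_vm / br_peak_for_pulse(pulse_spectral_peak_hz)
}

#' Combined exposure ratio across simultaneous sources
#'
#' Exposure ratios from simultaneously acting sources add; absent sources
#' (NA) contribute zero.
#'
#' @param e1,e2,e3 Short-term exposure ratios in percent (may be `NA` for
#'   "no such source").
#' @return Summed percent ratio.
#' @export
combined_ratio <- function(e1 = NA_real_, e2 = NA_real_, e3 = NA_real_) {
  sum(c(e1, e2, e3), na.rm = TRUE)
}
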