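#' ICNIRP 2010 occupational reference level for magnetic flux density
#'
#' Piecewise occupational reference level (RL) for magnetic flux density
#' as a function of frequency: 1000 uT from 25 to 300 Hz, 3e5/f uT from
#' 300 Hz to 3 kHz, and 100 uT from 3 kHz to 10 MHz. The function is
#' continuous at both band edges; band boundaries belong to the
#' lower-frequency band.
#'
#' @param frequency Frequency in Hz. Vectorized. Must lie in
#'   \[25 Hz, 10 MHz\].
#' @return Magnetic flux density reference level in microtesla.
#' @examples
#' rl_occupational(220)   # 1000
#' rl_occupational(366)   # 819.67...
#' rl_occupational(14e3)  # 100
#' @export
rl_occupational <- function(frequency) {
  check_icnirp_domain(frequency)
  ifelse(frequency <= 300, 1000,
         ifelse(frequency <= 3000, 3e5 / frequency, 100))
}

#' ICNIRP 2010 occupational basic restriction on the internal electric field
#'
#' Occupational basic restriction (BR) on the induced internal electric
#' field, expressed as an rms value for sinusoidal exposure: 0.8 V/m from
#' 25 Hz to 3 kHz and 2.7e-4 * f V/m above 3 kHz up to 10 MHz. The 3 kHz
#' boundary belongs to the lower band (0.8 V/m).
#'
#' @inheritParams rl_occupational
#' @return Internal electric field limit in V/m (rms).
#' @examples
#' br_occupational(220)  # 0.8
#' br_occupational(14e3) # 3.78
#' @export
br_occupational <- function(frequency) {
  check_icnirp_domain(frequency)
  ifelse(frequency <= 3000, 0.8, 2.7e-4 * frequency)
}

#' Peak basic restriction for monophasic pulses
#'
#' The basic restriction is stated as an rms value for sinusoidal
#' waveforms; comparing a pulse's peak induced field against it requires
#' converting to a peak limit, i.e. multiplying by sqrt(2).
#'
#' @inheritParams rl_occupational
#' @return Internal electric field limit in V/m (peak).
#' @examples
#' br_peak_for_pulse(200)  # 0.8 * sqrt(2)
#' @export
br_peak_for_pulse <- function(frequency) {
  br_occupational(frequency) * sqrt(2)
}

# supported band: the frequencies exercised by EAS gates and BCU pulses
check_icnirp_domain <- function(frequency) {
  if (!is.numeric(frequency) || any(!is.finite(frequency))) {
    stop("`frequency` must be finite numeric (Hz)", call. = FALSE)
  }
  if (any(frequency < 25 | frequency > 1e7)) {
    stop("`frequency` outside the supported guideline band [25 Hz, 10 MHz]",
         call. = FALSE)
  }
  invisible(frequency)
}
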