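#' Construct a sampled pulse trace
#'
#' A pulse trace is a uniformly (or near-uniformly) sampled record of a
#' monophasic magnetizing pulse: times in seconds, magnetic flux density
#' in tesla.
#'
#' @param times Strictly increasing sample times in seconds (>= 3 samples).
#' @param fields Magnetic flux density at each sample, tesla.
#' @return An object of class `pulse_trace`.
#' @export
pulse_trace <- function(times, fields) {
  if (!is.numeric(times) || !is.numeric(fields) ||
      length(times) != length(fields)) {
    stop("`times` and `fields` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(times) < 3L) stop("a pulse trace needs >= 3 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(fields))) {
    stop("pulse trace values must be finite", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (max(dt) / min(dt) >= 1.01) {
    stop("pulse trace sampling must be uniform (max/min step ratio < 1.01)",
         call. = FALSE)
  }
  structure(list(times = as.numeric(times), fields = as.numeric(fields)),
            class = "pulse_trace")
}

as_pulse_trace <- function(trace) {
  if (inherits(trace, "pulse_trace")) return(trace)
  pulse_trace(trace$times, trace$fields)
}

#' Temporal peak of a pulse
#'
#' @param trace A [pulse_trace()].
#' @return Maximum absolute flux density over the trace, tesla.
#' @export
pulse_peak <- function(trace) {
  trace <- as_pulse_trace(trace)
  max(abs(trace$fields))
}

#' Full width at half maximum of a monophasic pulse
#'
#' The two half-maximum crossings are located by linear interpolation
#' between the bracketing samples; their separation is the FWHM. Traces
#' whose half-maximum level is crossed fewer or more than exactly twice
#' (i.e. non-monophasic pulses) are rejected.
#'
#' @param trace A [pulse_trace()].
#' @return Width between the half-maximum crossings, seconds.
#' @export
pulse_fwhm <- function(trace) {
  trace <- as_pulse_trace(trace)
  y <- trace$fields
  # orient the pulse positive so a negative monophasic pulse works too
  y <- y * sign(y[which.max(abs(y))])
  half <- max(y) / 2
  s <- y - half
  idx <- which(s[-length(s)] * s[-1] < 0)            # strict sign changes
  on_level <- which(s == 0)
  # samples exactly at the half level count as crossings
  crossings <- c(
    trace$times[idx] + (trace$times[idx + 1] - trace$times[idx]) *
      (-s[idx]) / (s[idx + 1] - s[idx]),
    trace$times[on_level]
  )
  crossings <- sort(unique(crossings))
  if (length(crossings) != 2L) {
    stop("pulse is not monophasic: found ", length(crossings),
         " half-maximum crossings (need exactly 2)", call. = FALSE)
  }
  diff(crossings)
}

#' Peak absolute time-derivative of a pulse
#'
#' By Faraday's law the time-derivative of the incident flux density
#' drives the induced electric field, so the pulse's |dB/dt| peak is the
#' dosimetrically relevant rate quantity. The derivative is estimated by
#' central differences in the interior and one-sided differences at the
#' endpoints.
#'
#' @param trace A [pulse_trace()].
#' @return Maximum of |dB/dt| over the trace, tesla per second.
#' @export
dbdt_peak <- function(trace) {
  trace <- as_pulse_trace(trace)
  t <- trace$times; y <- trace$fields; n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  max(abs(d))
}

#' Proportionality constant between peak dB/dt and peak induced field
#'
#' For a given device geometry the peak induced internal electric field is
#' proportional to the peak time-derivative of the incident flux density;
#' this returns the constant of proportionality for a device whose induced
#' field is known from numerical dosimetry.
#'
#' @param ein_peak Peak induced internal electric field, V/m.
#' @param dbdt_peak Peak |dB/dt| of the incident pulse, T/s.
#' @return Constant in V s / (T m).
#' @examples
#' proportionality_constant(0.038, 0.31)  # ~0.12
#' proportionality_constant(0.054, 0.81)  # ~0.07
#' @export
proportionality_constant <- function(ein_peak, dbdt_peak) {
  if (any(ein_peak <= 0) || any(dbdt_peak <= 0)) {
    stop("inputs must be positive", call. = FALSE)
  }
  ein_peak / dbdt_peak
}

#' Rough estimate of the peak induced field from dB/dt
#'
#' For a device without detailed field-distribution data, the peak induced
#' internal field is estimated as the unweighted mean of the
#' proportionality constants of the numerically characterized devices,
#' multiplied by the device's measured peak |dB/dt|.
#'
#' @param dbdt_peak Peak |dB/dt| of the device's pulse, T/s.
#' @param constants Proportionality constants of characterized devices,
#'   V s / (T m).
#' @return Estimated peak induced internal electric field, V/m.
#' @examples
#' estimate_internal_peak(0.16, c(0.038 / 0.31, 0.054 / 0.81))  # ~0.015
#' @export
estimate_internal_peak <- function(dbdt_peak, constants) {
  if (length(constants) < 1L) stop("need at least one constant", call. = FALSE)
  if (any(dbdt_peak <= 0) || any(constants <= 0)) {
    stop("inputs must be positive", call. = FALSE)
  }
  mean(constants) * dbdt_peak
}

#' Read a pulse waveform from two-column delimited text
#'
#' Expects a header line naming the columns; the second column's unit is
#' taken from its name: `field_t` for tesla, `field_ut` for microtesla
#' (converted to tesla on read). The first column is time in seconds.
#'
#' @param path Path to a delimited text file (tab, comma or whitespace).
#' @return A [pulse_trace()].
#' @export
read_pulse_trace <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) {
    tab <- utils::read.table(path, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 2L) stop("pulse file needs two columns", call. = FALSE)
  unit_col <- tolower(names(tab)[2])
  scale <- if (grepl("_ut$", unit_col)) 1e-6 else if (grepl("_t$", unit_col)) 1
  else stop("second column must be named field_t or field_ut", call. = FALSE)
  pulse_trace(tab[[1]], tab[[2]] * scale)
}

#' Characterize a pulse trace
#'
#' Convenience wrapper returning peak, FWHM and peak |dB/dt| in one call.
#'
#' @param trace A [pulse_trace()].
#' @return A one-row tibble with columns `peak_t`, `fwhm_s`, `dbdt_peak_ts`.
#' @export
characterize_pulse <- function(trace) {
  trace <- as_pulse_trace(trace)
  tibble::tibble(
    peak_t = pulse_peak(trace),
    fwhm_s = pulse_fwhm(trace),
    dbdt_peak_ts = dbdt_peak(trace)
  )
}
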