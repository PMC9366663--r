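# analytic test pulses, built in code at test time

gaussian_trace <- function(amplitude = 1e-4, sigma = 1e-3, n = 2001,
                           span = 6) {
  t <- seq(-span * sigma, span * sigma, length.out = n)
  pulse_trace(t, amplitude * exp(-t^2 / (2 * sigma^2)))
}

triangular_trace <- function(amplitude = 1e-4, half_base = 1e-3, n = 2001) {
  t <- seq(-1.5 * half_base, 1.5 * half_base, length.out = n)
  pulse_trace(t, amplitude * pmax(0, 1 - abs(t) / half_base))
}

rectangular_trace <- function(amplitude = 406e-6, width = 1.95e-3, n = 4001,
                              span = 2) {
  t <- seq(0, span * width, length.out = n)
  pulse_trace(t, ifelse(t >= 0.25 * width & t < 1.25 * width, amplitude, 0))
}

sine_trace <- function(b0 = 1e-4, f = 200, n = 5001, cycles = 2) {
  t <- seq(0, cycles / f, length.out = n)
  pulse_trace(t, b0 * sin(2 * pi * f * t))
}
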