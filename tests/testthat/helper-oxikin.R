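# Shared fixtures, built in code.

default_protocol <- function(...) vessel_protocol(...)

# uninhibited reference parameter set used across tests
ref_params <- function(...) {
  kinetic_params(kp = 1, kt = 1e7, Ri = 1e-7, RH0 = 1, ...)
}

# a gallate-like inhibited run whose closed-form descriptors are convenient
inhibited_params <- function(Ri = 5e-8, AH0 = 2.36e-3, kinh = 1e5, ...) {
  kinetic_params(kp = 1, kt = 1e7, Ri = Ri, RH0 = 1, AH0 = AH0,
                 kinh = kinh, ...)
}

# piecewise-linear toy consumption curve: slope b1 until t_break, then b2,
# continuous at the break; the tangent construction must return t_break
toy_curve <- function(b1 = 5, b2 = 50, t_break = 3e4, t_end = 6e4, by = 10) {
  t <- seq(0, t_end, by = by)
  y <- ifelse(t < t_break, b1 * t, b1 * t_break + b2 * (t - t_break))
  data.frame(time_s = t, consumed_nmol = y)
}

expect_rel <- function(actual, expected, tol, label = NULL) {
  expect_lt(abs(actual - expected) / abs(expected), tol, label = label)
}
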