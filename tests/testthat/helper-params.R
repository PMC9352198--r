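# Shared fixtures: parameter sets and small analytic oracles.

mouse <- function(...) circuit_preset("mouse", ...)

fig3_field <- function(ratio = 4) {
  make_gaussian_field(R1 = ratio, R2 = 1, x1 = 30, x2 = -30, b = 10)
}

# Analytic response of the linearised feedback circuit to a log-input step
# of size s at t = 0 (adapted start): the d-deviation is a difference of two
# exponentials with rates from the characteristic polynomial
#   lambda^2 + omega_d lambda + omega_d omega alpha / d0 = 0.
analytic_step_response <- function(p, s, t) {
  disc <- sqrt(p$omega_d^2 - 4 * p$omega_d * p$omega * p$alpha / p$d0)
  l1 <- (-p$omega_d + disc) / 2
  l2 <- (-p$omega_d - disc) / 2
  A <- p$omega_d * p$mu * s / (l1 - l2)
  A * (exp(l1 * t) - exp(l2 * t))
}

analytic_peak_amplitude <- function(p, s) {
  disc <- sqrt(p$omega_d^2 - 4 * p$omega_d * p$omega * p$alpha / p$d0)
  l1 <- (-p$omega_d + disc) / 2
  l2 <- (-p$omega_d - disc) / 2
  tstar <- log(l2 / l1) / (l1 - l2)
  analytic_step_response(p, s, tstar)
}
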