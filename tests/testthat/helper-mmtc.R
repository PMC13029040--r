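# Canonical ciliate functional response used across tests (Imax in cells
# ciliate^-1 d^-1, kd in cells mL^-1).
ciliate_fr <- function() fr_params(Imax = 38, kd = 1093)

# Midpoint-of-range NPMZ parameters and the benchmark initial state.
midpoint_params <- function() npmz_params()
benchmark_state <- function() npmz_state(1.0, 0.5, 0.1, 0.05)

# Random admissible NPMZ parameters drawn uniformly within the published
# calibration ranges (gZ drawn from the GZ range, which has no published
# range of its own).
random_npmz_params <- function() {
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  npmz_params(rmax = runif1(0.5, 2), kN = runif1(0.1, 1),
              gM = runif1(0.3, 1.5), gZ = runif1(0.2, 1.2),
              GZ = runif1(0.2, 1.2), gammaM = runif1(0.2, 0.4),
              gammaZ = runif1(0.2, 0.4), lPN = runif1(0.05, 0.2),
              lMN = runif1(0.05, 0.2), lZN = runif1(0.05, 0.2))
}

random_npmz_state <- function() {
  v <- stats::runif(4, 0.01, 2)
  npmz_state(v[1], v[2], v[3], v[4])
}
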