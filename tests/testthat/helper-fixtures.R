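# Shared fixtures: small deterministic curves and parameter sets used across
# test files. Everything is built in code at test time.

default_acq <- function() acquisition_params()

# a calibration object with known psi, bypassing baseline estimation
fixed_cal <- function(psi = 1000, native_t1 = 1.2, n_baseline = 5L) {
  structure(list(psi = psi, native_t1 = native_t1,
                 n_baseline = as.integer(n_baseline)),
            class = "mbf_calibration")
}

# standard synthetic AIF under default study conditions
fixture_aif <- function(...) generate_aif(sim_config(...))

# brute-force O(N^2) causal convolution oracle, independent of the FFT path
conv_oracle <- function(a, r, dt) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(r[seq_len(i)] * a[i:1]) * dt
  out
}

# trapezoidal area
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
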