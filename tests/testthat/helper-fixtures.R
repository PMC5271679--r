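# Shared fixtures for the suite: everything is generated in code.

# Noiseless time course + protocol for a named preset, with overrides.
fixture_tc <- function(name = "blue-1200", ...) {
  p <- scenario_preset(name, ...)
  tc <- make_timecourse(p)
  list(preset = p, tc = tc, protocol = attr(tc, "protocol"))
}

# Closed-form closure after total dose D at rho = 0 (Poisson target theory):
# the independent oracle for the per-flashlet brute-force recursion.
closure_poisson <- function(sigma, dose) 1 - exp(-sigma * dose)

# Closed-form OLS through the normal equations, independent of lm.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}
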