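# Shared test utilities: effective sample size for autocorrelated series and
# small object builders used across files.

# Integrated-autocorrelation-corrected effective sample size (initial positive
# sequence truncation of the empirical ACF).
ess <- function(x, max_lag = min(length(x) - 1, 2000)) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  pos <- which(a <= 0)
  if (length(pos) > 0) a <- a[seq_len(pos[1] - 1)]
  length(x) / (1 + 2 * sum(a))
}

# A flat-bottomed "free" system: negligible well so the axial landscape is
# effectively flat between the soft walls.
flat_system <- function(axial_range = c(-20, 20), wall_stiffness = 10, ...) {
  toy_system(well_depth = 1e-9, well_width = 1.5, axial_range = axial_range,
             wall_stiffness = wall_stiffness, ...)
}

# Build a pmf_profile directly from zeta/free-energy vectors.
make_pmf <- function(zeta, free_energy) {
  out <- data.frame(zeta = zeta, free_energy = free_energy, stderr = NA_real_)
  class(out) <- c("pmf_profile", "data.frame")
  out
}

kBT_298 <- 0.0019872041 * 298.15

# Absolute-tolerance comparison (testthat's tolerance is relative for values
# of magnitude > tolerance, which is too strict for small printed statistics).
expect_near <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
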