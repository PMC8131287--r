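test_that("analytic PMF is anchored at the bound pose and plateaus at the well depth", {
  sys <- toy_system(well_depth = 5, well_width = 1.5)
  expect_equal(analytic_pmf(sys, 0), 0)
  expect_equal(analytic_pmf(sys, 12), 5, tolerance = 1e-10)
  expect_equal(analytic_pmf(sys, -12.5), 5, tolerance = 1e-10)
  expect_error(analytic_pmf(sys, 15), "outside")
})

test_that("analytic PMF agrees with a 2-D quadrature of the marginal Boltzmann density", {
  sys <- toy_system(well_depth = 4, well_width = 1.2, radial_stiffness = 0.4)
  beta <- thermal_beta(sys)
  # marginal density over (z, r): p(z) ~ exp(-beta U_ax) * Int 2 pi r exp(-beta a r^2) dr;
  # the radial factor is constant in z, so -kBT log p - min equals the PMF.
  zs <- seq(-8, 8, by = 0.5)
  pz <- vapply(zs, function(z) {
    radial <- stats::integrate(function(r)
      2 * pi * r * exp(-beta * sys$radial_stiffness * r^2), 0, Inf)$value
    exp(-beta * (analytic_pmf(sys, z) - sys$well_depth)) * radial
  }, numeric(1))
  f_quad <- -log(pz) / beta
  f_quad <- f_quad - min(f_quad)
  expect_lt(max(abs(f_quad - analytic_pmf(sys, zs))), 1e-6)
})

test_that("Langevin sampling reproduces harmonic variance and equipartition", {
  flat <- flat_system()
  kBT <- 1 / thermal_beta(flat)
  # harmonic axial landscape a z^2 realised through an umbrella on a flat system
  tr <- simulate_trajectory(flat, umbrella_window(0, 1), n_steps = 200000,
                            seed = 7, record_stride = 10)
  v_hat <- stats::var(tr$zeta)
  se_v <- v_hat * sqrt(2 / ess(tr$zeta))
  expect_lt(abs(v_hat - kBT / 2), 3 * se_v)
  # equipartition: kBT/2 per degree of freedom
  ke_hat <- mean(tr$kinetic)
  se_ke <- stats::sd(tr$kinetic) / sqrt(ess(tr$kinetic))
  expect_lt(abs(ke_hat - 1.5 * kBT), 3 * se_ke)
})

test_that("trajectories are bit-identical for identical seeds", {
  sys <- toy_system()
  bias <- list(umbrella_window(-2, 1.25), cylindrical_restraint())
  a <- simulate_trajectory(sys, bias, n_steps = 2000, seed = 42)
  b <- simulate_trajectory(sys, bias, n_steps = 2000, seed = 42)
  expect_identical(a, b)
  c <- simulate_trajectory(sys, bias, n_steps = 2000, seed = 43)
  expect_false(identical(a$zeta, c$zeta))
})

test_that("exact biased sampler matches Gaussian closed forms and its own grid density", {
  flat <- flat_system()
  kBT <- 1 / thermal_beta(flat)
  z <- sample_biased_exact(flat, umbrella_window(2, 1), n = 50000, seed = 3)
  expect_lt(abs(mean(z) - 2), 3 * sqrt(kBT / 2 / 50000))
  expect_lt(abs(stats::var(z) - kBT / 2), 3 * (kBT / 2) * sqrt(2 / 50000))
  expect_length(sample_biased_exact(flat, NULL, n = 1, seed = 1), 1)

  # two-sided well: histogram against the grid density, chi-square at alpha = 0.01
  sys <- toy_system()
  zz <- sample_biased_exact(sys, umbrella_window(0, 0.05), n = 20000, seed = 9)
  edges <- seq(-4.5, 4.5, by = 0.5)
  counts <- tabulate(findInterval(zz[zz >= -4.5 & zz <= 4.5], edges,
                                  rightmost.closed = TRUE, all.inside = TRUE),
                     nbins = length(edges) - 1)
  beta <- thermal_beta(sys)
  dens <- function(x) exp(-beta * (analytic_pmf(sys, x) +
                                   umbrella_energy(umbrella_window(0, 0.05), x)))
  probs <- vapply(seq_len(length(edges) - 1), function(i)
    stats::integrate(dens, edges[i], edges[i + 1])$value, numeric(1))
  norm <- stats::integrate(dens, -13, 14)$value
  pfit <- suppressWarnings(stats::chisq.test(counts, p = probs / norm,
                                             rescale.p = TRUE))
  expect_gt(pfit$p.value, 0.01)
})

test_that("Langevin and exact samplers agree at distribution level", {
  sys <- toy_system()
  w <- umbrella_window(-1, 1.25)
  tr <- simulate_trajectory(sys, w, n_steps = 300000, seed = 11,
                            record_stride = 500)  # thinned ~ decorrelated
  ref <- sample_biased_exact(sys, w, n = 20000, seed = 12)
  ks <- suppressWarnings(stats::ks.test(tr$zeta, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("uniform annular-cylinder fixtures have the expected effective volume", {
  pos <- generate_unbound_positions(2, 4, 10, n = 50000, seed = 5)
  ev <- effective_volume(pos)
  expect_equal(ev$V_eff, pi * (16 - 4) * 10, tolerance = 0.01)
  pos0 <- generate_unbound_positions(0, 3, 5, n = 50000, seed = 6)
  expect_equal(effective_volume(pos0)$V_eff, pi * 9 * 5, tolerance = 0.02)
  expect_error(generate_unbound_positions(2, 4, 10, n = 0), "positive")
  expect_error(effective_volume(matrix(c(1, 0, 0), 1, 3)), "at least 2")
})

test_that("particle states validate and kinetic energy is non-negative", {
  st <- particle_state(c(1, 2, 3), c(-1, 0, 1))
  expect_gte(kinetic_energy(st, 100), 0)
  expect_equal(kinetic_energy(particle_state(), 100), 0)
  expect_error(particle_state(c(1, 2, Inf)))
})

test_that("trajectory text round-trips through the whitespace format", {
  sys <- toy_system()
  tr <- simulate_trajectory(sys, NULL, n_steps = 500, seed = 2,
                            record_stride = 10)
  path <- withr::local_tempfile(fileext = ".dat")
  write_trajectory(tr, path, comments = "toy run")
  back <- read_trajectory(path)
  expect_equal(back$zeta, tr$zeta, tolerance = 1e-12)
  expect_true(all(diff(back$step) > 0))
})
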