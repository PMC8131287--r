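beta_ref <- 1 / kBT_298

test_that("histograms conserve counts and reject out-of-range or empty windows", {
  lad <- build_window_ladder(span = c(0, 1), n_windows = 2,
                             dense_region = NULL)
  edges <- seq(-1, 2, by = 0.5)
  series <- list(c(0.1, 0.2, 0.3), c(0.9, 1.1))
  h <- build_histograms(series, edges, lad)
  expect_equal(h$N, c(3, 2))
  expect_equal(rowSums(h$counts), h$N)
  # all samples in one bin
  h1 <- build_histograms(list(rep(0.1, 5), 0.9), edges, lad)
  expect_equal(max(h1$counts[1, ]), 5)
  expect_equal(sum(h1$counts[1, ] > 0), 1)
  expect_error(build_histograms(list(c(0.1, 5), 0.9), edges, lad), "outside")
  expect_error(build_histograms(list(numeric(), 0.9), edges, lad),
               "no samples")
  # disjoint windows are visible in the overlap matrix
  hd <- build_histograms(list(c(-0.9, -0.8), c(1.8, 1.9)), edges, lad)
  ov <- overlap_matrix(hd)
  expect_equal(ov[1, 2], 0)
  expect_error(solve_wham(hd, beta_ref), "disconnected")
})

test_that("degenerate WHAM cases reduce to empirical histograms", {
  # single window with (numerically) zero bias: p = n/N, f = 0
  lad1 <- list(umbrella_window(0, 1e-12))
  class(lad1) <- c("window_ladder", "list")
  set.seed(4)
  z <- stats::runif(2000, -1, 1)
  edges <- seq(-1, 1, by = 0.25)
  h <- build_histograms(list(z), edges, lad1)
  fit <- solve_wham(h, beta_ref)
  expect_equal(fit$f, 0)
  expect_equal(fit$p, as.numeric(h$counts[1, ] / sum(h$counts)),
               tolerance = 1e-9)
  # two identical windows with identical data match the pooled single window
  lad2 <- list(umbrella_window(0, 0.8), umbrella_window(0, 0.8))
  class(lad2) <- c("window_ladder", "list")
  sysf <- flat_system(axial_range = c(-1, 1))
  zz <- sample_biased_exact(sysf, lad2[[1]], n = 3000, seed = 5)
  h2 <- build_histograms(list(zz, zz), edges, lad2)
  h1 <- build_histograms(list(c(zz, zz)), edges, lad2[1]) # pooled
  fit2 <- solve_wham(h2, beta_ref)
  fit1 <- solve_wham(h1, beta_ref)
  expect_equal(fit2$p, fit1$p, tolerance = 1e-9)
  expect_equal(fit2$f[1], fit2$f[2], tolerance = 1e-9)
})

test_that("WHAM solution is invariant to window order and to splitting a window", {
  sys <- toy_system()
  lad <- build_window_ladder(span = c(-2, 2), n_windows = 3,
                             dense_region = NULL, stiffness = 1.25)
  series <- lapply(seq_along(lad), function(i)
    sample_biased_exact(sys, lad[[i]], n = 4000, seed = 40 + i))
  edges <- seq(-6, 6, by = 0.2)
  h <- build_histograms(series, edges, lad)
  fit <- solve_wham(h, beta_ref)
  # reorder windows
  ord <- c(3, 1, 2)
  lad_r <- lad[ord]; class(lad_r) <- c("window_ladder", "list")
  fit_r <- solve_wham(build_histograms(series[ord], edges, lad_r), beta_ref)
  expect_equal(fit_r$p, fit$p, tolerance = 1e-6)
  expect_equal(fit_r$f - fit_r$f[2], fit$f[ord] - fit$f[1], tolerance = 1e-6)
  # split the middle window's data into two identical windows
  lad_s <- list(lad[[1]], lad[[2]], lad[[2]], lad[[3]])
  class(lad_s) <- c("window_ladder", "list")
  half <- seq_len(2000)
  series_s <- list(series[[1]], series[[2]][half], series[[2]][-half],
                   series[[3]])
  fit_s <- solve_wham(build_histograms(series_s, edges, lad_s), beta_ref)
  expect_equal(fit_s$p, fit$p, tolerance = 1e-6)
  # gauge: f[1] = 0 exactly
  expect_identical(fit$f[1], 0)
})

test_that("self-consistent WHAM agrees with direct likelihood minimisation", {
  sys <- toy_system()
  lad <- build_window_ladder(span = c(-2, 2), n_windows = 3,
                             dense_region = NULL, stiffness = 1.25)
  series <- lapply(seq_along(lad), function(i)
    sample_biased_exact(sys, lad[[i]], n = 4000, seed = 30 + i))
  h <- build_histograms(series, seq(-6, 6, by = 0.2), lad)
  f_sc <- solve_wham(h, beta_ref, tol = 1e-10)$f
  f_ml <- wham_mle(h, beta_ref)$f
  expect_lt(max(abs(f_sc - f_ml)), 1e-6)
})

test_that("PMF construction anchors the minimum at zero and honours log identities", {
  # uniform probabilities give a flat profile at zero
  flat <- pmf_from_wham(rep(0.25, 4), beta_ref, centers = 1:4)
  expect_equal(flat$free_energy, rep(0, 4))
  # two bins with p ratio e^-1 differ by exactly kBT
  two <- pmf_from_wham(c(exp(-1) * 0.3, 0.3), beta_ref, centers = 1:2)
  expect_equal(two$free_energy[1] - two$free_energy[2], kBT_298)
  expect_equal(min(two$free_energy), 0)
  # empty bins are undefined
  withp0 <- pmf_from_wham(c(0.5, 0, 0.5), beta_ref, centers = 1:3)
  expect_true(is.na(withp0$free_energy[2]))
  expect_error(pmf_from_wham(c(0, 0), beta_ref, centers = 1:2), "all-zero")
})

test_that("pulling free energy extraction matches the two conventions", {
  z <- seq(-10, 10, by = 0.2)
  flat <- make_pmf(z, rep(0, length(z)))
  expect_equal(as.numeric(delta_g_reus(flat, c(-3, 3), mode = "depth",
                                       beta = beta_ref)), 0)
  expect_equal(as.numeric(delta_g_reus(flat, c(-3, 3), mode = "integrated",
                                       beta = beta_ref)), 0)
  # single well of depth 5 against a flat plateau, depth mode -> -5
  well <- make_pmf(z, ifelse(abs(z) < 1, 0, 5))
  expect_equal(as.numeric(delta_g_reus(well, c(-3, 3), mode = "depth",
                                       beta = beta_ref)), -5)
  expect_error(delta_g_reus(flat, c(50, 60), beta = beta_ref), "empty")

  # integrated mode against direct quadrature of Boltzmann integrals on the toy PMF
  sys <- toy_system()
  beta <- thermal_beta(sys)
  zfine <- seq(-12.9, 13.9, by = 0.05)
  pmf <- make_pmf(zfine, analytic_pmf(sys, zfine))
  got <- delta_g_reus(pmf, c(-3, 3), mode = "integrated", beta = beta)
  regs <- attr(got, "regions")
  qmean <- function(r) {
    f <- stats::integrate(function(x) exp(-beta * analytic_pmf(sys, x)),
                          r[1], r[2])$value
    f / (r[2] - r[1])
  }
  want <- -log(qmean(c(-3, 3)) /
               mean(vapply(regs$unbound, qmean, numeric(1)))) / beta
  expect_near(as.numeric(got), want, tol = 0.02)
})

test_that("asymmetry score is zero for even profiles and equals a constant offset", {
  z <- seq(-6, 6, by = 0.1)
  even <- make_pmf(z, z^2 / 4)
  expect_lt(check_symmetry(even, 0), 1e-10)
  shifted <- make_pmf(z, z^2 / 4 + ifelse(z > 0, 0.7, 0))
  expect_equal(check_symmetry(shifted, 0), 0.7, tolerance = 0.05)
  expect_error(check_symmetry(make_pmf(z[z > 0], z[z > 0]), 0), "both sides")
})

test_that("block bootstrap has sound degenerate behaviour and sqrt(n) scaling", {
  # whole-series blocks force identical resamples -> zero spread
  s <- list(stats::rnorm(100))
  b0 <- bootstrap_uncertainty(s, function(x) mean(x[[1]]), n_boot = 2,
                              block = 100, seed = 1)
  expect_equal(b0$stderr, 0)
  expect_error(bootstrap_uncertainty(s, function(x) mean(x[[1]]), n_boot = 2,
                                     block = 200, seed = 1), "block longer")
  # i.i.d. Gaussian: bootstrap stderr of the mean tracks sigma/sqrt(n)
  set.seed(10)
  n <- 400; sigma <- 2
  x <- list(stats::rnorm(n, sd = sigma))
  b1 <- bootstrap_uncertainty(x, function(s) mean(s[[1]]), n_boot = 200,
                              block = 1, seed = 2)
  expect_lt(abs(b1$stderr - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.30)
  # 4x the samples halves the error
  x4 <- list(stats::rnorm(4 * n, sd = sigma))
  b4 <- bootstrap_uncertainty(x4, function(s) mean(s[[1]]), n_boot = 200,
                              block = 1, seed = 3)
  expect_gt(b1$stderr / b4$stderr, 1.4)
  expect_lt(b1$stderr / b4$stderr, 2.8)
})
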