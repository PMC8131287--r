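test_that("exchange exponent matches hand evaluation and is antisymmetric", {
  w0 <- umbrella_window(0, 1); w1 <- umbrella_window(1, 1)
  expect_equal(exchange_delta(w0, w1, 0, 1, beta = 1), 2)
  expect_equal(exchange_delta(w0, w1, 0.7, 0.7, beta = 2.3), 0)
  d <- exchange_delta(w0, w1, -0.4, 1.3, beta = 1.7)
  expect_equal(exchange_delta(w0, w1, 1.3, -0.4, beta = 1.7), -d)
})

test_that("Metropolis rule accepts downhill always and uphill by exp(-delta)", {
  expect_true(metropolis_accept(-1, 0.999999))
  expect_true(metropolis_accept(0, 0.999999))
  expect_true(metropolis_accept(2, 0.10))   # exp(-2) ~ 0.1353
  expect_false(metropolis_accept(2, 0.20))
})

test_that("exchange sweeps keep the permutation a bijection and accept trivially for identical coordinates", {
  lad <- build_window_ladder(span = c(-3, 3), n_windows = 6,
                             dense_region = NULL)
  beta <- 1 / kBT_298
  state <- list(window_of = 1:6, zeta = rep(0.4, 6))
  set.seed(5)
  sw <- attempt_neighbor_exchanges(state, lad, "odd", beta)
  expect_true(all(sw$records$delta == 0))
  expect_true(all(sw$records$accepted))
  expect_setequal(sw$state$window_of, 1:6)
  expect_equal(sw$records$pair_lo, c(1, 3, 5))
  sw2 <- attempt_neighbor_exchanges(sw$state, lad, "even", beta)
  expect_equal(sw2$records$pair_lo, c(2, 4))
  expect_setequal(sw2$state$window_of, 1:6)

  # two windows, one attempt: decision matches hand evaluation of the criterion
  lad2 <- lad[1:2]; class(lad2) <- c("window_ladder", "list")
  st <- list(window_of = 1:2, zeta = c(-2.6, -1.0))
  d_hand <- beta * (umbrella_energy(lad2[[1]], -1.0) -
                    umbrella_energy(lad2[[1]], -2.6) -
                    umbrella_energy(lad2[[2]], -1.0) +
                    umbrella_energy(lad2[[2]], -2.6))
  set.seed(8); draw <- stats::runif(1)
  set.seed(8)
  sw3 <- attempt_neighbor_exchanges(st, lad2, "odd", beta)
  expect_equal(sw3$records$delta, d_hand)
  expect_equal(sw3$records$accepted, d_hand <= 0 || draw < exp(-d_hand))
})

test_that("two-window exchange with exact resampling reproduces the analytic acceptance", {
  # Flat landscape: both biased marginals are Gaussians with var = kBT/(2k);
  # the mean Metropolis acceptance has the closed form 2 Phi(-s sqrt(beta k)).
  k <- 1.25; s <- 1.0
  beta <- 1 / kBT_298
  sd_z <- sqrt(kBT_298 / (2 * k))
  w0 <- umbrella_window(0, k); w1 <- umbrella_window(s, k)
  n <- 20000
  set.seed(17)
  zi <- stats::rnorm(n, 0, sd_z)
  zj <- stats::rnorm(n, s, sd_z)
  acc <- vapply(seq_len(n), function(t) {
    metropolis_accept(exchange_delta(w0, w1, zi[t], zj[t], beta),
                      stats::runif(1))
  }, logical(1))
  p_hat <- mean(acc)
  p_true <- 2 * stats::pnorm(-s * sqrt(beta * k))
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("acceptance bookkeeping counts per neighbour pair", {
  empty <- acceptance_rates(data.frame(step = integer(), pair_lo = integer(),
                                       pair_hi = integer(), delta = numeric(),
                                       accepted = logical()))
  expect_equal(nrow(empty$per_pair), 0)
  expect_true(is.na(empty$mean))
  log1 <- data.frame(step = 1:10, pair_lo = 3L, pair_hi = 4L, delta = 0,
                     accepted = c(rep(TRUE, 3), rep(FALSE, 7)))
  ar <- acceptance_rates(log1)
  expect_equal(ar$per_pair$rate, 0.30)
  log2 <- data.frame(step = 1:4, pair_lo = 1L, pair_hi = 2L, delta = -1,
                     accepted = TRUE)
  expect_equal(acceptance_rates(log2)$mean, 1.0)
})

test_that("REUS runs are reproducible, conserve window labels, and mix replicas", {
  sys <- toy_system()
  lad <- build_window_ladder(span = c(-4, 4), n_windows = 8,
                             dense_region = NULL, stiffness = 1.25)
  cyl <- cylindrical_restraint()
  pull <- steered_pull(sys, start = -4, end = 4, n_steps = 20000, seed = 21,
                       cylinder = cyl)
  init <- assign_snapshots(pull, lad)
  cfg <- reus_config(n_cycles = 1500, seed = 31)
  run <- run_reus(sys, lad, cyl, cfg, init)
  run2 <- run_reus(sys, lad, cyl, cfg, init)
  expect_identical(run$records, run2$records)
  expect_identical(run$series, run2$series)
  # label conservation at the end of the run
  expect_setequal(run$state$window_of, 1:8)
  # every cycle fills every window slot exactly once
  expect_true(all(!is.na(run$series[[1]]$zeta)))
  # replica traces are contiguous and visit several windows
  visits <- vapply(1:8, function(r) {
    tr <- replica_trace(run$records, r, 8)
    expect_true(all(abs(diff(tr$window)) <= 1))
    length(unique(tr$window))
  }, numeric(1))
  expect_true(all(visits >= 3))
  # zero-cycle runs return the seeds untouched with an empty log
  run0 <- run_reus(sys, lad, cyl, reus_config(n_cycles = 0, seed = 1), init)
  expect_equal(nrow(run0$records), 0)
  expect_error(run_reus(sys, lad, cyl, cfg, init[1:5, ]),
               "one initial configuration per window")
})

test_that("replica traces replay the exchange log", {
  rec <- data.frame(step = c(1, 1, 2, 3), pair_lo = c(1L, 3L, 2L, 1L),
                    pair_hi = c(2L, 4L, 3L, 2L),
                    delta = 0, accepted = c(TRUE, FALSE, TRUE, TRUE))
  # replica 1: swaps to window 2 at step 1, to 3 at step 2, stays at 3
  expect_equal(replica_trace(rec, 1, 4)$window, c(2, 3, 3))
  # replica 2: to window 1 at step 1; swapped back to 2 at step 3
  expect_equal(replica_trace(rec, 2, 4)$window, c(1, 1, 2))
  none <- rec; none$accepted <- FALSE
  expect_equal(replica_trace(none, 3, 4)$window, c(3, 3, 3))
  expect_error(replica_trace(rec, 9, 4), "unknown replica")
})
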