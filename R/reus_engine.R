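#' REUS run configuration
#'
#' @param steps_per_cycle Dynamics steps between exchange attempts (the toy
#'   analogue of the 2 ps attempt interval).
#' @param n_cycles Number of dynamics/exchange cycles.
#' @param dt Time step (ps).
#' @param friction Langevin friction (1/ps).
#' @param seed Integer master seed for the run.
#' @param parity_alternation Alternate even/odd neighbour pairs between sweeps
#'   (`TRUE`, default) or attempt odd pairs every sweep.
#' @return An object of class `reus_config`.
#' @export
reus_config <- function(steps_per_cycle = 20, n_cycles = 20000, dt = 0.002,
                        friction = 1, seed = 1L, parity_alternation = TRUE) {
  stopifnot(steps_per_cycle >= 1, n_cycles >= 0, dt > 0, friction > 0)
  structure(list(steps_per_cycle = as.integer(steps_per_cycle),
                 n_cycles = as.integer(n_cycles), dt = dt,
                 friction = friction, seed = as.integer(seed),
                 parity_alternation = isTRUE(parity_alternation)),
            class = "reus_config")
}

#' Exchange criterion exponent for neighbouring windows
#'
#' \eqn{\Delta = \beta (V_m(\zeta_j) - V_m(\zeta_i) - V_{m+1}(\zeta_j) +
#' V_{m+1}(\zeta_i))} for replica i holding window m and replica j holding
#' window m+1.  Antisymmetric under swapping i and j.
#'
#' @param window_m,window_m1 The two [umbrella_window()]s.
#' @param zeta_i,zeta_j Current reaction coordinates of the two replicas (A).
#' @param beta Inverse temperature (mol/kcal).
#' @return Dimensionless exponent.
#' @export
exchange_delta <- function(window_m, window_m1, zeta_i, zeta_j, beta) {
  d <- beta * (umbrella_energy(window_m, zeta_j) -
               umbrella_energy(window_m, zeta_i) -
               umbrella_energy(window_m1, zeta_j) +
               umbrella_energy(window_m1, zeta_i))
  if (!is.finite(d)) stop("non-finite exchange exponent")
  d
}

#' Metropolis acceptance for an exchange attempt
#'
#' Accept with probability 1 for \eqn{\Delta \le 0} and \eqn{e^{-\Delta}}
#' otherwise.
#'
#' @param delta Exchange exponent.
#' @param uniform_draw A uniform draw in `[0, 1)`.
#' @return Logical: accept the exchange?
#' @export
metropolis_accept <- function(delta, uniform_draw) {
  stopifnot(is.finite(delta))
  delta <= 0 || uniform_draw < exp(-delta)
}

#' One neighbour-exchange sweep
#'
#' Attempts one exchange for every neighbour pair (m, m+1) with m of the given
#' parity.  On acceptance the two replicas swap window labels (equivalent to
#' exchanging the umbrella potentials); the replica-to-window permutation stays
#' a bijection.
#'
#' @param state List with `window_of` (window index held by each replica) and
#'   `zeta` (current reaction coordinate of each replica).
#' @param ladder A `window_ladder`.
#' @param parity `"odd"` or `"even"`: parity of m in the attempted pairs.
#' @param beta Inverse temperature (mol/kcal).
#' @param step Step index recorded in the log.
#' @return List with the updated `state` and a data frame `records` with
#'   columns `step`, `pair_lo`, `pair_hi`, `delta`, `accepted`.
#' @export
attempt_neighbor_exchanges <- function(state, ladder, parity = c("odd", "even"),
                                       beta, step = 0L) {
  parity <- match.arg(parity)
  M <- length(ladder)
  replica_at <- integer(M)            # inverse permutation: window -> replica
  replica_at[state$window_of] <- seq_len(M)
  first <- if (parity == "odd") 1L else 2L
  ms <- seq(first, M - 1L, by = 2L)
  n <- length(ms)
  rec <- data.frame(step = rep(as.integer(step), n), pair_lo = ms,
                    pair_hi = ms + 1L, delta = numeric(n),
                    accepted = logical(n))
  draws <- stats::runif(n)
  for (idx in seq_along(ms)) {
    m <- ms[idx]
    i <- replica_at[m]; j <- replica_at[m + 1L]
    delta <- exchange_delta(ladder[[m]], ladder[[m + 1L]],
                            state$zeta[i], state$zeta[j], beta)
    acc <- metropolis_accept(delta, draws[idx])
    rec$delta[idx] <- delta
    rec$accepted[idx] <- acc
    if (acc) {
      state$window_of[i] <- m + 1L
      state$window_of[j] <- m
      replica_at[m] <- j; replica_at[m + 1L] <- i
    }
  }
  list(state = state, records = rec)
}

#' Run a replica-exchange umbrella sampling simulation
#'
#' Alternates Langevin dynamics segments (each replica under its current
#' umbrella window plus the cylindrical restraint) with Metropolis
#' neighbour-exchange sweeps of alternating parity.  One reaction-coordinate
#' sample per window is recorded at the end of every cycle, already sorted by
#' window label.  Deterministic given the seed in `config`.
#'
#' @param system A `toy_system`.
#' @param ladder A `window_ladder` of length M.
#' @param cylinder Optional [cylindrical_restraint()].
#' @param config A [reus_config()].
#' @param initial_positions M x 3 matrix of starting positions, row m seeding
#'   the replica that starts in window m (e.g. from [assign_snapshots()]).
#' @return An object of class `reus_run`: list with `series` (per-window data
#'   frames `cycle`, `zeta`, `radial`), `records` (exchange log), `ladder`,
#'   `config`, and the final ensemble state.
#' @export
run_reus <- function(system, ladder, cylinder = NULL, config = reus_config(),
                     initial_positions) {
  M <- length(ladder)
  stopifnot(is.matrix(initial_positions), ncol(initial_positions) == 3)
  if (nrow(initial_positions) != M)
    stop("need one initial configuration per window (", M, " rows), got ",
         nrow(initial_positions))
  set.seed(config$seed)
  beta <- thermal_beta(system)
  kBT <- 1 / beta
  centers <- ladder_centers(ladder)
  ks <- ladder_stiffness(ladder)
  cyl_on <- !is.null(cylinder)

  pos <- initial_positions
  sd_v <- sqrt(kBT * KCAL_TO_AKMA / system$mass)
  vel <- matrix(stats::rnorm(3 * M, sd = sd_v), M, 3)
  state <- list(window_of = seq_len(M), zeta = pos[, 3])

  n <- config$n_cycles
  zmat <- matrix(NA_real_, n, M)   # window-sorted zeta samples
  rmat <- matrix(NA_real_, n, M)
  recs <- vector("list", n)
  for (cyc in seq_len(n)) {
    seg <- .propagate_ensemble_cpp(
      unclass(system), pos, vel, system$mass, kBT, config$dt, config$friction,
      config$steps_per_cycle,
      ks[state$window_of], centers[state$window_of],
      cyl_on,
      if (cyl_on) cylinder$radius else 0,
      if (cyl_on) cylinder$stiffness else 0)
    pos <- seg$pos; vel <- seg$vel
    state$zeta <- seg$zeta
    zmat[cyc, state$window_of] <- seg$zeta
    rmat[cyc, state$window_of] <- seg$radial
    parity <- if (!config$parity_alternation || cyc %% 2L == 1L) "odd" else "even"
    sw <- attempt_neighbor_exchanges(state, ladder, parity, beta, step = cyc)
    state <- sw$state
    recs[[cyc]] <- sw$records
  }
  records <- if (n > 0) do.call(rbind, recs) else
    data.frame(step = integer(), pair_lo = integer(), pair_hi = integer(),
               delta = numeric(), accepted = logical())
  series <- lapply(seq_len(M), function(m)
    data.frame(cycle = seq_len(n), zeta = zmat[, m], radial = rmat[, m]))
  names(series) <- sprintf("window_%02d", seq_len(M))
  structure(list(series = series, records = records, ladder = ladder,
                 config = config,
                 state = list(window_of = state$window_of, positions = pos,
                              velocities = vel)),
            class = "reus_run")
}

#' @export
print.reus_run <- function(x, ...) {
  ar <- acceptance_rates(x$records)
  cat(sprintf("REUS run: %d windows, %d cycles, mean exchange acceptance %.3f\n",
              length(x$ladder), x$config$n_cycles, ar$mean))
  invisible(x)
}

#' Exchange acceptance rates
#'
#' @param records Exchange log (data frame with `pair_lo`, `pair_hi`,
#'   `accepted`), e.g. `run$records`.
#' @return List with `per_pair` (data frame `pair_lo`, `pair_hi`, `attempts`,
#'   `accepted`, `rate`) and the overall `mean` rate (NA on an empty log).
#' @export
acceptance_rates <- function(records) {
  if (nrow(records) == 0)
    return(list(per_pair = data.frame(pair_lo = integer(), pair_hi = integer(),
                                      attempts = integer(), accepted = integer(),
                                      rate = numeric()),
                mean = NA_real_))
  agg <- stats::aggregate(cbind(attempts = rep(1L, nrow(records)),
                                accepted = as.integer(records$accepted)),
                          by = list(pair_lo = records$pair_lo,
                                    pair_hi = records$pair_hi), FUN = sum)
  agg <- agg[order(agg$pair_lo), ]
  rownames(agg) <- NULL
  agg$rate <- agg$accepted / agg$attempts
  list(per_pair = agg, mean = mean(agg$rate))
}

#' Reconstruct the window-label trace of one replica
#'
#' Replays the accepted swaps in the exchange log, starting from the identity
#' permutation (replica m starts in window m), and returns the window label
#' held by the requested replica after each attempt step.
#'
#' @param records Exchange log of a single run.
#' @param replica Replica index.
#' @param n_windows Number of windows in the run.
#' @return Data frame `step`, `window` (one row per logged attempt step).
#' @export
replica_trace <- function(records, replica, n_windows) {
  replica <- as.integer(replica)
  if (replica < 1L || replica > n_windows) stop("unknown replica index")
  steps <- unique(records$step)
  window_of <- seq_len(n_windows)
  replica_at <- seq_len(n_windows)
  out <- integer(length(steps))
  for (s in seq_along(steps)) {
    sub <- records[records$step == steps[s] & records$accepted, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      m <- sub$pair_lo[r]
      i <- replica_at[m]; j <- replica_at[m + 1L]
      window_of[i] <- m + 1L; window_of[j] <- m
      replica_at[m] <- j; replica_at[m + 1L] <- i
    }
    out[s] <- window_of[replica]
  }
  data.frame(step = steps, window = out)
}

#' Write the exchange log as CSV
#'
#' @param records Exchange log data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_exchange_log <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
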