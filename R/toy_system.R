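# Boltzmann constant in kcal/mol/K and the kcal/mol -> amu A^2/ps^2 factor.
KB_KCAL <- 0.0019872041
KCAL_TO_AKMA <- 418.4

#' Separable cylindrical toy binding model
#'
#' A single guest-sized particle in a separable potential
#' \eqn{U(z, r) = U_{ax}(z) + U_{rad}(r)} standing in for a solvated
#' host--guest complex.  The axial term is a Gaussian binding well of depth
#' `well_depth` centred at \eqn{z = 0} (the bound pose) that relaxes to a flat
#' plateau, with soft harmonic walls outside `axial_range`; the radial term is
#' harmonic, \eqn{U_{rad}(r) = a r^2}.  Separability makes the marginal free
#' energy along the reaction coordinate \eqn{\zeta = z} equal to
#' \eqn{U_{ax}(z)} up to an additive constant, so the true PMF and the true
#' binding free energy are available in closed form or by 1-D quadrature.
#'
#' @param well_depth Depth of the axial binding well (kcal/mol, > 0).
#' @param well_width Gaussian width of the well (Angstrom).
#' @param axial_range Closed interval covered by the reaction coordinate
#'   (Angstrom); soft walls act outside it.
#' @param radial_stiffness Harmonic constant of the confining radial term
#'   (kcal/mol/A^2).
#' @param temperature Temperature in Kelvin.
#' @param mass Particle mass (amu); default a guest-sized 100 amu.
#' @param wall_stiffness Harmonic constant of the axial soft walls
#'   (kcal/mol/A^2).
#' @return An object of class `toy_system`.
#' @examples
#' sys <- toy_system()
#' analytic_pmf(sys, 0)     # anchored minimum
#' analytic_pmf(sys, 12)    # unbound plateau ~ well_depth
#' @export
toy_system <- function(well_depth = 5, well_width = 1.5,
                       axial_range = c(-13, 14), radial_stiffness = 0.3,
                       temperature = 298.15, mass = 100,
                       wall_stiffness = 10) {
  stopifnot(well_depth > 0, well_width > 0, length(axial_range) == 2,
            axial_range[1] < axial_range[2], radial_stiffness > 0,
            temperature > 0, mass > 0, wall_stiffness >= 0)
  structure(list(well_depth = well_depth, well_width = well_width,
                 axial_range = as.numeric(axial_range),
                 radial_stiffness = radial_stiffness,
                 temperature = temperature, kB = KB_KCAL, mass = mass,
                 wall_stiffness = wall_stiffness),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Cylindrical toy binding system\n")
  cat(sprintf("  well: depth %.3g kcal/mol, width %.3g A at z = 0\n",
              x$well_depth, x$well_width))
  cat(sprintf("  axial range: [%.3g, %.3g] A; radial stiffness %.3g kcal/mol/A^2\n",
              x$axial_range[1], x$axial_range[2], x$radial_stiffness))
  cat(sprintf("  T = %.2f K (kBT = %.5f kcal/mol), mass %.3g amu\n",
              x$temperature, x$kB * x$temperature, x$mass))
  invisible(x)
}

#' Inverse temperature of a system
#'
#' @param system A `toy_system`.
#' @return \eqn{\beta = 1/(k_B T)} in mol/kcal.
#' @export
thermal_beta <- function(system) 1 / (system$kB * system$temperature)

# Bare axial potential (walls included), unanchored; vectorised over z.
axial_potential <- function(system, z) {
  u <- -system$well_depth * exp(-0.5 * z^2 / system$well_width^2)
  hi <- z > system$axial_range[2]
  lo <- z < system$axial_range[1]
  u[hi] <- u[hi] + system$wall_stiffness * (z[hi] - system$axial_range[2])^2
  u[lo] <- u[lo] + system$wall_stiffness * (z[lo] - system$axial_range[1])^2
  u
}

#' Analytic potential of mean force along the reaction coordinate
#'
#' Exact marginal free energy of the toy system along \eqn{\zeta}, anchored so
#' that the global minimum (the bound pose at \eqn{z = 0}) is zero.  Because
#' the potential is separable, this equals \eqn{U_{ax}(z) + D} with no
#' quadrature error; far from the well it approaches `well_depth`.
#'
#' @param system A `toy_system`.
#' @param z Reaction-coordinate value(s) in Angstrom, inside `axial_range`.
#' @return Free energy in kcal/mol (vectorised).
#' @export
analytic_pmf <- function(system, z) {
  if (any(z < system$axial_range[1] | z > system$axial_range[2]))
    stop("z outside the axial range [", system$axial_range[1], ", ",
         system$axial_range[2], "]")
  axial_potential(system, z) + system$well_depth
}

#' Particle state
#'
#' Position and momentum of the single guest particle.
#'
#' @param position 3-vector, Angstrom.
#' @param momentum 3-vector, amu A/ps.
#' @return An object of class `particle_state`.
#' @export
particle_state <- function(position = c(0, 0, 0), momentum = c(0, 0, 0)) {
  stopifnot(length(position) == 3, length(momentum) == 3,
            all(is.finite(position)), all(is.finite(momentum)))
  structure(list(position = as.numeric(position),
                 momentum = as.numeric(momentum)),
            class = "particle_state")
}

#' Kinetic energy of a particle state
#'
#' @param state A `particle_state`.
#' @param mass Mass in amu.
#' @return Kinetic energy in kcal/mol (always >= 0).
#' @export
kinetic_energy <- function(state, mass) {
  sum(state$momentum^2) / (2 * mass) / KCAL_TO_AKMA
}

# Normalise the heterogeneous ways a bias can be passed (NULL, a single
# restraint object, or a list of them) into umbrella/cylinder components.
split_bias <- function(bias) {
  out <- list(umbrella = NULL, cylinder = NULL)
  if (is.null(bias)) return(out)
  if (inherits(bias, "umbrella_window")) { out$umbrella <- bias; return(out) }
  if (inherits(bias, "cylindrical_restraint")) { out$cylinder <- bias; return(out) }
  if (is.list(bias)) {
    for (b in bias) {
      if (inherits(b, "umbrella_window")) out$umbrella <- b
      else if (inherits(b, "cylindrical_restraint")) out$cylinder <- b
      else if (!is.null(b)) stop("unsupported bias component of class ",
                                 paste(class(b), collapse = "/"))
    }
    return(out)
  }
  stop("bias must be NULL, a restraint object, or a list of restraint objects")
}

# Draw Maxwell-Boltzmann velocities (A/ps).
maxwell_velocities <- function(system) {
  sd <- sqrt(system$kB * system$temperature * KCAL_TO_AKMA / system$mass)
  stats::rnorm(3, sd = sd)
}

#' Langevin dynamics trajectory on the toy system
#'
#' BAOAB-discretised Langevin dynamics under the toy potential plus an optional
#' bias (umbrella window and/or cylindrical restraint).  In the long-time limit
#' the recorded reaction coordinate samples the biased Boltzmann density at the
#' system temperature.  Deterministic for a given `seed`.
#'
#' @param system A `toy_system`.
#' @param bias `NULL`, an [umbrella_window()], a [cylindrical_restraint()], or
#'   a list containing both.
#' @param n_steps Number of integration steps.
#' @param dt Time step in ps.
#' @param friction Langevin friction coefficient in 1/ps.
#' @param seed Integer RNG seed (optional; uses the current RNG stream if
#'   `NULL`).
#' @param start Initial position (3-vector, Angstrom).
#' @param velocity Initial velocity (3-vector, A/ps); Maxwell-Boltzmann drawn
#'   when `NULL`.
#' @param record_stride Record every `record_stride`-th step.
#' @param keep_positions Keep the full 3-D positions of recorded frames (as an
#'   attribute) in addition to the reaction-coordinate columns.
#' @return A data frame with columns `step`, `zeta` (A), `radial` (A),
#'   `bias_energy` (kcal/mol), plus a `kinetic` column (kcal/mol) and, as
#'   attributes, the final `particle_state` and optionally the recorded
#'   positions.
#' @export
simulate_trajectory <- function(system, bias = NULL, n_steps, dt = 0.002,
                                friction = 1, seed = NULL,
                                start = c(0, 0, 0), velocity = NULL,
                                record_stride = 1, keep_positions = FALSE) {
  stopifnot(inherits(system, "toy_system"), n_steps >= 1, dt > 0, friction > 0,
            record_stride >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(velocity)) velocity <- maxwell_velocities(system)
  bb <- split_bias(bias)
  umb_on <- !is.null(bb$umbrella)
  cyl_on <- !is.null(bb$cylinder)
  res <- .simulate_path_cpp(
    unclass(system), as.numeric(start), as.numeric(velocity),
    system$mass, system$kB * system$temperature, dt, friction,
    as.integer(n_steps), as.integer(record_stride),
    umb_on,
    if (umb_on) bb$umbrella$stiffness else 0,
    if (umb_on) bb$umbrella$center else 0,
    if (umb_on) bb$umbrella$center else 0,
    cyl_on,
    if (cyl_on) bb$cylinder$radius else 0,
    if (cyl_on) bb$cylinder$stiffness else 0)
  out <- data.frame(step = res$step, zeta = res$zeta, radial = res$radial,
                    bias_energy = res$bias_energy, kinetic = res$kinetic)
  attr(out, "final_state") <- particle_state(res$final_position,
                                             res$final_velocity * system$mass)
  if (keep_positions) attr(out, "positions") <- res$positions
  out
}

# Grid density of the biased 1-D marginal along zeta (umbrella component only:
# the radial terms factor out of the marginal by separability).
biased_grid_density <- function(system, bias, grid_points = 4096) {
  bb <- split_bias(bias)
  z <- seq(system$axial_range[1], system$axial_range[2],
           length.out = grid_points)
  u <- axial_potential(system, z)
  if (!is.null(bb$umbrella)) u <- u + umbrella_energy(bb$umbrella, z)
  beta <- thermal_beta(system)
  logw <- -beta * (u - min(u))
  w <- exp(logw)
  norm <- sum((w[-1] + w[-length(w)]) / 2) * diff(z[1:2])
  if (!is.finite(norm) || norm <= 0)
    stop("grid density underflowed everywhere; cannot normalise")
  list(z = z, density = w / norm)
}

#' Exact i.i.d. samples from the biased reaction-coordinate marginal
#'
#' Independent draws from the exact 1-D biased Boltzmann marginal of
#' \eqn{\zeta}, by inverse-CDF sampling on a fine grid.  Serves as the
#' distribution-level oracle against which the Langevin sampler and the WHAM
#' estimator are validated.
#'
#' @param system A `toy_system`.
#' @param bias As in [simulate_trajectory()].
#' @param n Number of draws (> 0).
#' @param seed Optional integer seed.
#' @param grid_points Grid resolution over `axial_range`.
#' @return Numeric vector of `n` reaction-coordinate values (Angstrom).
#' @export
sample_biased_exact <- function(system, bias = NULL, n, seed = NULL,
                                grid_points = 4096) {
  stopifnot(inherits(system, "toy_system"), n > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- biased_grid_density(system, bias, grid_points)
  dz <- diff(g$z[1:2])
  cdf <- c(0, cumsum((g$density[-1] + g$density[-length(g$density)]) / 2 * dz))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  # invert by linear interpolation on the strictly increasing part
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], g$z[keep], xout = u, rule = 2)$y
}

#' Uniform positions in an annular cylinder
#'
#' Draws positions uniformly over the annulus `r_lo <= r <= r_hi`, axial extent
#' `[0, h]`, around the z axis.  Fixture generator for testing the effective
#' unbound volume (the extrema-based cylinder-volume formula is exact on it).
#'
#' @param r_lo,r_hi Inner and outer radius (A), `0 <= r_lo < r_hi`.
#' @param h Axial extent (A, > 0).
#' @param n Number of positions (> 0).
#' @param seed Optional integer seed.
#' @return An `n` x 3 matrix of positions.
#' @export
generate_unbound_positions <- function(r_lo, r_hi, h, n, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  stopifnot(r_lo >= 0, r_hi > r_lo, h > 0)
  if (!is.null(seed)) set.seed(seed)
  r <- sqrt(r_lo^2 + stats::runif(n) * (r_hi^2 - r_lo^2))
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, 0, h)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Write / read a trajectory series as whitespace-delimited text
#'
#' Columns `step`, `zeta` (A), `radial` (A), `bias_energy` (kcal/mol); header
#' lines are prefixed with `#`.
#'
#' @param trajectory A data frame as returned by [simulate_trajectory()].
#' @param path Output file.
#' @param comments Character vector of extra header lines.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines("# step zeta radial bias_energy", con)
  utils::write.table(trajectory[, c("step", "zeta", "radial", "bias_energy")],
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- utils::read.table(path, comment.char = "#",
                           col.names = c("step", "zeta", "radial", "bias_energy"))
  out
}
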