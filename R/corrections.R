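#' Effective unbound volume from sampled positions
#'
#' Cylinder-shell estimate \eqn{V_{eff} = \pi (r_{max}^2 - r_{min}^2) h_{max}}
#' from the radial extrema of the centre of mass about the restraint axis and
#' its maximal axial excursion, all measured in the first (unbound) replica.
#' Sample extrema are used exactly as defined; a percentile variant
#' (`trim > 0`) is available but off by default.
#'
#' @param positions n x 3 matrix of COM positions (Angstrom), n >= 2.
#' @param axis,origin Restraint axis definition.
#' @param trim Optional tail fraction (e.g. 0.005) replaced by quantiles
#'   instead of hard extrema; 0 (default) uses min/max.
#' @return List with `V_eff` (A^3), `r_max`, `r_min`, `h_max` (A).
#' @export
effective_volume <- function(positions, axis = c(0, 0, 1),
                             origin = c(0, 0, 0), trim = 0) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (nrow(positions) < 2) stop("need at least 2 positions")
  axis <- axis / sqrt(sum(axis^2))
  rel <- sweep(positions, 2, origin)
  along <- drop(rel %*% axis)
  perp <- rel - outer(along, axis)
  r <- sqrt(rowSums(perp^2))
  if (trim > 0) {
    r_max <- stats::quantile(r, 1 - trim, names = FALSE)
    r_min <- stats::quantile(r, trim, names = FALSE)
    h_max <- diff(stats::quantile(along, c(trim, 1 - trim), names = FALSE))
  } else {
    r_max <- max(r); r_min <- min(r)
    h_max <- max(along) - min(along)
  }
  if (r_max <= r_min || h_max <= 0)
    stop("degenerate extent: r_max must exceed r_min and h_max must be positive")
  list(V_eff = pi * (r_max^2 - r_min^2) * h_max,
       r_max = r_max, r_min = r_min, h_max = h_max)
}

#' Standard-state (restraint-release) volume correction
#'
#' \eqn{\Delta G^{rest-off} = -k_B T \ln(V_0 / V_{eff})}: zero when the
#' restrained unbound volume equals the standard-state volume, negative when
#' the restraint confines the guest below it.
#'
#' @param V_eff Effective unbound volume (A^3, > 0).
#' @param T Temperature (K).
#' @param V0 Standard-state volume (A^3); the 1 M value 1649.76 by default.
#' @return Correction in kcal/mol.
#' @export
restraint_off_correction <- function(V_eff, T = 298.15, V0 = 1649.76) {
  if (V_eff <= 0) stop("V_eff must be positive")
  -KB_KCAL * T * log(V0 / V_eff)
}

#' Thermodynamic-integration schedule
#'
#' @param lambdas Coupling values, strictly monotone within `[0, 1]` with both
#'   endpoints present (default the 10-point production schedule
#'   1, 0.95, 0.9, 0.85, 0.8, 0.7, 0.5, 0.3, 0.1, 0).
#' @param n_equil,n_prod Per-lambda equilibration and production steps (toy
#'   stand-ins for the 100/200 ps NVT runs).
#' @param n_poses Number of bound poses averaged over.
#' @return An object of class `ti_schedule`.
#' @export
ti_schedule <- function(lambdas = c(1, 0.95, 0.9, 0.85, 0.8, 0.7, 0.5, 0.3,
                                    0.1, 0),
                        n_equil = 2000, n_prod = 10000, n_poses = 5) {
  stopifnot(all(lambdas >= 0 & lambdas <= 1),
            all(diff(lambdas) < 0) || all(diff(lambdas) > 0),
            1 %in% lambdas, 0 %in% lambdas,
            n_equil >= 0, n_prod > 0, n_poses >= 1)
  structure(list(lambdas = lambdas, n_equil = as.integer(n_equil),
                 n_prod = as.integer(n_prod), n_poses = as.integer(n_poses)),
            class = "ti_schedule")
}

#' Restraint-on correction by thermodynamic integration
#'
#' Free-energy cost of switching on the bound-pose reaction-coordinate
#' restraint, \eqn{\Delta G = \int_0^1 \langle \partial V(\lambda) / \partial
#' \lambda \rangle_\lambda \, d\lambda} with linear coupling
#' \eqn{V(\lambda) = \lambda V_{restraint}}, so the integrand is
#' \eqn{\langle V_{restraint} \rangle_\lambda}.  Each lambda state is sampled
#' by Langevin dynamics started from a bound pose; the integral is taken by
#' the trapezoidal rule on the (non-uniform) lambda grid and averaged over
#' poses.  The cylindrical restraint is omitted: in the bound poses the guest
#' never leaves its flat-bottom interior.
#'
#' @param system A `toy_system`.
#' @param poses Matrix of starting positions (one row per pose) drawn from the
#'   bound state; rows are recycled over `schedule$n_poses`.
#' @param restraint The [umbrella_window()] at the bound center being switched
#'   on (full stiffness at lambda = 1).
#' @param schedule A [ti_schedule()].
#' @param dt,friction Langevin parameters.
#' @param seed Optional integer seed.
#' @return List with `value` (kcal/mol), `stderr`, `per_lambda` (data frame
#'   `lambda`, `mean_dVdl`, `stderr`), and `per_pose` values.
#' @export
ti_restraint_on <- function(system, poses, restraint,
                            schedule = ti_schedule(), dt = 0.002, friction = 1,
                            seed = NULL) {
  if (!is.matrix(poses)) poses <- matrix(poses, nrow = 1)
  stopifnot(ncol(poses) == 3)
  if (!is.null(seed)) set.seed(seed)
  if (restraint$stiffness == 0) {
    return(list(value = 0, stderr = 0, per_lambda = NULL, per_pose = rep(0, schedule$n_poses)))
  }
  lam <- sort(schedule$lambdas)       # integrate 0 -> 1
  n_pose <- schedule$n_poses
  means <- matrix(NA_real_, n_pose, length(lam))
  for (ip in seq_len(n_pose)) {
    start <- poses[(ip - 1L) %% nrow(poses) + 1L, ]
    for (il in seq_along(lam)) {
      k_eff <- lam[il] * restraint$stiffness
      bias <- if (k_eff > 0)
        umbrella_window(restraint$center, k_eff, restraint$label) else NULL
      vel <- maxwell_velocities(system)
      res <- .simulate_path_cpp(
        unclass(system), as.numeric(start), vel, system$mass,
        system$kB * system$temperature, dt, friction,
        schedule$n_equil + schedule$n_prod, 1L,
        !is.null(bias),
        if (is.null(bias)) 0 else bias$stiffness,
        if (is.null(bias)) 0 else bias$center,
        if (is.null(bias)) 0 else bias$center,
        FALSE, 0, 0)
      zeta <- res$zeta[res$step > schedule$n_equil]
      v_full <- umbrella_energy(restraint, zeta)  # dV/dlambda = V_restraint
      if (!all(is.finite(v_full))) stop("non-finite TI integrand; unequilibrated divergence")
      means[ip, il] <- mean(v_full)
    }
  }
  trapz <- function(y) sum(diff(lam) * (y[-1] + y[-length(y)]) / 2)
  per_pose <- apply(means, 1, trapz)
  value <- mean(per_pose)
  stderr <- if (n_pose > 1) stats::sd(per_pose) / sqrt(n_pose) else NA_real_
  per_lambda <- data.frame(lambda = lam, mean_dVdl = colMeans(means),
                           stderr = if (n_pose > 1)
                             apply(means, 2, stats::sd) / sqrt(n_pose)
                           else NA_real_)
  list(value = value, stderr = stderr, per_lambda = per_lambda,
       per_pose = per_pose)
}

#' Assemble the binding free energy
#'
#' Plain sum \eqn{\Delta G^{bind} = \Delta G^{REUS} + \Delta G^{rest-off} +
#' \Delta G^{rest-on}} -- the convention under which the reference tabulation
#' of per-guest components is internally consistent.  (The alternative sign
#' bookkeeping that negates every component describes the reverse, unbinding
#' direction.)
#'
#' @param reus Pulling free energy (kcal/mol).
#' @param rest_off Volume correction (kcal/mol).
#' @param rest_on Restraint-on correction (kcal/mol).
#' @return \eqn{\Delta G^{bind}} in kcal/mol.
#' @export
assemble_binding_free_energy <- function(reus, rest_off, rest_on) {
  stopifnot(is.finite(reus), is.finite(rest_off), is.finite(rest_on))
  reus + rest_off + rest_on
}

#' Average binding free energy over stereoisomers
#'
#' Arithmetic mean of the R and S stereoisomer binding free energies; the
#' reported uncertainty follows the RMS-of-errors convention,
#' \eqn{\sqrt{(\sigma_R^2 + \sigma_S^2)/2}}.
#'
#' @param dG_R,dG_S Stereoisomer binding free energies (kcal/mol).
#' @param err_R,err_S Their uncertainties (optional).
#' @return List with `value` and `stderr` (NA when errors are missing).
#' @export
stereoisomer_average <- function(dG_R, dG_S, err_R = NA, err_S = NA) {
  stopifnot(is.finite(dG_R), is.finite(dG_S))
  list(value = (dG_R + dG_S) / 2,
       stderr = if (is.na(err_R) || is.na(err_S)) NA_real_
                else sqrt((err_R^2 + err_S^2) / 2))
}

#' Binding free-energy result record
#'
#' @param guest Guest label.
#' @param reus,rest_off,rest_on Components (kcal/mol).
#' @param reus_err,rest_off_err,rest_on_err Their uncertainties.
#' @param parameter_set Parameter-set label.
#' @return An object of class `binding_result` with the assembled `bind` value
#'   and its propagated error.
#' @export
binding_result <- function(guest, reus, rest_off, rest_on,
                           reus_err = NA, rest_off_err = NA, rest_on_err = NA,
                           parameter_set = NA_character_) {
  bind <- assemble_binding_free_energy(reus, rest_off, rest_on)
  errs <- c(reus_err, rest_off_err, rest_on_err)
  bind_err <- if (all(is.finite(errs))) sqrt(sum(errs^2)) else NA_real_
  structure(list(guest = guest, parameter_set = parameter_set,
                 reus = reus, reus_err = reus_err,
                 rest_off = rest_off, rest_off_err = rest_off_err,
                 rest_on = rest_on, rest_on_err = rest_on_err,
                 bind = bind, bind_err = bind_err),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("Binding free energy for %s%s\n", x$guest,
              if (is.na(x$parameter_set)) "" else paste0(" (", x$parameter_set, ")")))
  cat(sprintf("  REUS pulling : %8.3f kcal/mol\n", x$reus))
  cat(sprintf("  rest-off     : %8.3f kcal/mol\n", x$rest_off))
  cat(sprintf("  rest-on      : %8.3f kcal/mol\n", x$rest_on))
  cat(sprintf("  assembled    : %8.3f +/- %.3f kcal/mol\n", x$bind,
              x$bind_err))
  invisible(x)
}
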