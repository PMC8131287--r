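#' Harmonic umbrella window
#'
#' One biasing potential \eqn{V_m(\zeta) = k_m (\zeta - d_m)^2}.  Note the
#' CHARMM convention: no factor 1/2 in front of the stiffness.
#'
#' @param center Window center \eqn{d_m} (Angstrom).
#' @param stiffness Stiffness \eqn{k_m} (kcal/mol/A^2, > 0).
#' @param label Integer window label.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, stiffness, label = 1L) {
  stopifnot(is.finite(center), stiffness > 0)
  structure(list(center = center, stiffness = stiffness,
                 label = as.integer(label)),
            class = "umbrella_window")
}

#' Umbrella bias energy
#'
#' @param window An [umbrella_window()].
#' @param zeta Reaction-coordinate value(s), Angstrom.
#' @return \eqn{k_m (\zeta - d_m)^2} in kcal/mol (vectorised; zero only at the
#'   center).
#' @export
umbrella_energy <- function(window, zeta) {
  stopifnot(all(is.finite(zeta)))
  window$stiffness * (zeta - window$center)^2
}

#' Flat-bottom cylindrical restraint
#'
#' Zero inside a cylinder of radius `radius` around `axis` through `origin`;
#' grows as `stiffness * (rho - radius)^2` outside.  Keeps the guest inside the
#' cylinder defined by the host portals without exerting any interior force.
#'
#' @param axis Cylinder axis (normalised internally).
#' @param origin A point on the axis (Angstrom).
#' @param radius Flat-bottom radius (A); default 7.5.
#' @param stiffness Harmonic constant outside the radius (kcal/mol/A^2);
#'   default 5.
#' @return An object of class `cylindrical_restraint`.
#' @export
cylindrical_restraint <- function(axis = c(0, 0, 1), origin = c(0, 0, 0),
                                  radius = 7.5, stiffness = 5) {
  stopifnot(length(axis) == 3, length(origin) == 3, radius > 0, stiffness >= 0)
  nrm <- sqrt(sum(axis^2))
  stopifnot(nrm > 0)
  structure(list(axis = axis / nrm, origin = as.numeric(origin),
                 radius = radius, stiffness = stiffness),
            class = "cylindrical_restraint")
}

# Perpendicular distance(s) of positions from the restraint axis.
perp_distance <- function(restraint, position) {
  pos <- if (is.matrix(position)) position else matrix(position, nrow = 1)
  rel <- sweep(pos, 2, restraint$origin)
  along <- drop(rel %*% restraint$axis)
  perp <- rel - outer(along, restraint$axis)
  sqrt(rowSums(perp^2))
}

#' Cylindrical restraint energy
#'
#' @param restraint A [cylindrical_restraint()].
#' @param position A 3-vector or an n x 3 matrix of positions.
#' @return Energy (kcal/mol): 0 at or inside the radius, harmonic outside.
#' @export
cylindrical_energy <- function(restraint, position) {
  rho <- perp_distance(restraint, position)
  out <- ifelse(rho > restraint$radius,
                restraint$stiffness * (rho - restraint$radius)^2, 0)
  if (length(out) == 1) out[[1]] else out
}

#' Reaction-coordinate definition
#'
#' The reaction coordinate is the signed projection onto `axis` of the vector
#' from the centre of mass of a reference selection (the host portal oxygens)
#' to the centre of mass of the guest selection.
#'
#' @param guest_selection Integer indices of guest atoms.
#' @param reference_selection Integer indices of reference atoms (disjoint from
#'   the guest).
#' @param axis Projection axis (normalised internally).
#' @return An object of class `reaction_coordinate_spec`.
#' @export
reaction_coordinate_spec <- function(guest_selection, reference_selection,
                                     axis = c(0, 0, 1)) {
  if (length(guest_selection) == 0 || length(reference_selection) == 0)
    stop("selections must be non-empty")
  if (length(intersect(guest_selection, reference_selection)) > 0)
    stop("guest and reference selections must be disjoint")
  nrm <- sqrt(sum(axis^2))
  stopifnot(nrm > 0)
  structure(list(guest_selection = as.integer(guest_selection),
                 reference_selection = as.integer(reference_selection),
                 axis = axis / nrm),
            class = "reaction_coordinate_spec")
}

com <- function(coordinates, masses, idx) {
  m <- masses[idx]
  if (sum(m) <= 0) stop("zero total mass in selection")
  colSums(coordinates[idx, , drop = FALSE] * m) / sum(m)
}

#' Evaluate the reaction coordinate
#'
#' @param spec A [reaction_coordinate_spec()].
#' @param coordinates n x 3 matrix covering both selections (Angstrom).
#' @param masses Length-n masses (amu).
#' @return Signed axial COM separation in Angstrom.
#' @export
compute_reaction_coordinate <- function(spec, coordinates, masses) {
  stopifnot(is.matrix(coordinates), ncol(coordinates) == 3,
            length(masses) == nrow(coordinates))
  if (max(c(spec$guest_selection, spec$reference_selection)) > nrow(coordinates))
    stop("coordinates do not cover the selections")
  d <- com(coordinates, masses, spec$guest_selection) -
       com(coordinates, masses, spec$reference_selection)
  sum(d * spec$axis)
}

#' Build the umbrella-window ladder
#'
#' Places `n_windows` centers over `span` with a fixed dense spacing inside
#' `dense_region` (to sample the bound poses more finely) and the remaining
#' windows spread uniformly over the two flanks, split in proportion to flank
#' length.  The first and last centers sit exactly at the span endpoints.
#'
#' @param span Reaction-coordinate interval covered (Angstrom).
#' @param n_windows Total number of windows (>= 2).
#' @param dense_region Sub-interval receiving fixed `dense_spacing` (set to
#'   `NULL` for an equidistant ladder).
#' @param dense_spacing Center spacing inside `dense_region` (A).
#' @param stiffness Umbrella stiffness, either a scalar applied to all windows
#'   or a length-`n_windows` vector (kcal/mol/A^2).
#' @return A list of [umbrella_window()]s (class `window_ladder`), ordered by
#'   center.
#' @export
build_window_ladder <- function(span = c(-13, 14), n_windows = 32,
                                dense_region = c(-3, 3), dense_spacing = 0.5,
                                stiffness = 1.25) {
  stopifnot(length(span) == 2, span[1] < span[2], n_windows >= 2)
  if (is.null(dense_region)) {
    centers <- seq(span[1], span[2], length.out = n_windows)
  } else {
    stopifnot(dense_region[1] >= span[1], dense_region[2] <= span[2],
              dense_region[1] < dense_region[2], dense_spacing > 0)
    dense <- seq(dense_region[1], dense_region[2], by = dense_spacing)
    n_flank <- n_windows - length(dense)
    if (n_flank < 0)
      stop("infeasible: dense region alone needs ", length(dense),
           " windows but n_windows = ", n_windows)
    len_l <- dense_region[1] - span[1]
    len_r <- span[2] - dense_region[2]
    n_l <- round(n_flank * len_l / (len_l + len_r))
    n_r <- n_flank - n_l
    left <- if (n_l > 0) seq(span[1], dense_region[1],
                             length.out = n_l + 1)[seq_len(n_l)] else numeric()
    right <- if (n_r > 0) seq(dense_region[2], span[2],
                              length.out = n_r + 1)[-1] else numeric()
    centers <- c(left, dense, right)
  }
  if (any(diff(centers) <= 0)) stop("window centers are not strictly increasing")
  ks <- rep_len(stiffness, n_windows)
  ladder <- mapply(function(d, k, m) umbrella_window(d, k, m),
                   centers, ks, seq_along(centers), SIMPLIFY = FALSE)
  class(ladder) <- c("window_ladder", "list")
  ladder
}

#' @export
print.window_ladder <- function(x, ...) {
  cc <- ladder_centers(x)
  cat(sprintf("Umbrella ladder: %d windows over [%.3g, %.3g] A\n",
              length(x), min(cc), max(cc)))
  invisible(x)
}

#' Centers / stiffnesses of a ladder
#'
#' @param ladder A `window_ladder`.
#' @return Numeric vector.
#' @export
ladder_centers <- function(ladder) vapply(ladder, `[[`, numeric(1), "center")

#' @rdname ladder_centers
#' @export
ladder_stiffness <- function(ladder) vapply(ladder, `[[`, numeric(1), "stiffness")

#' Serialise a ladder to JSON
#'
#' @param ladder A `window_ladder`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  df <- data.frame(label = vapply(ladder, `[[`, integer(1), "label"),
                   center = ladder_centers(ladder),
                   stiffness = ladder_stiffness(ladder))
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' @rdname write_ladder
#' @export
read_ladder <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  ladder <- mapply(function(d, k, m) umbrella_window(d, k, m),
                   df$center, df$stiffness, df$label, SIMPLIFY = FALSE)
  class(ladder) <- c("window_ladder", "list")
  ladder
}

#' Steered pull across the host
#'
#' Drags a moving harmonic restraint linearly from `start` to `end` along the
#' reaction coordinate, recording snapshots along the way, to generate one
#' initial configuration per umbrella window.
#'
#' @param system A `toy_system`.
#' @param start,end Initial and final restraint center (Angstrom); must differ.
#' @param stiffness Pulling stiffness (kcal/mol/A^2); default the host
#'   protocol's 5.
#' @param n_steps Number of steps for the pull.
#' @param dt,friction,seed As in [simulate_trajectory()].
#' @param cylinder Optional [cylindrical_restraint()] active during the pull.
#' @param record_stride Snapshot recording stride.
#' @return A data frame of snapshots (`step`, `zeta`, `radial`, `bias_energy`)
#'   with the recorded 3-D positions in attribute `"positions"`.
#' @export
steered_pull <- function(system, start = -13, end = 14, stiffness = 5,
                         n_steps = 100000, dt = 0.002, friction = 1,
                         seed = NULL, cylinder = NULL, record_stride = 10) {
  if (start == end) stop("start and end of the pull must differ")
  if (!is.null(seed)) set.seed(seed)
  vel <- maxwell_velocities(system)
  cyl_on <- !is.null(cylinder)
  res <- .simulate_path_cpp(
    unclass(system), c(0, 0, start), vel,
    system$mass, system$kB * system$temperature, dt, friction,
    as.integer(n_steps), as.integer(record_stride),
    TRUE, stiffness, start, end,
    cyl_on,
    if (cyl_on) cylinder$radius else 0,
    if (cyl_on) cylinder$stiffness else 0)
  out <- data.frame(step = res$step, zeta = res$zeta, radial = res$radial,
                    bias_energy = res$bias_energy)
  attr(out, "positions") <- res$positions
  out
}

#' Assign pull snapshots to ladder windows
#'
#' For every window, picks the recorded snapshot whose reaction coordinate is
#' nearest the window center.
#'
#' @param pull Result of [steered_pull()].
#' @param ladder A `window_ladder`.
#' @return A length-`M` x 3 matrix of initial positions (rows ordered by window
#'   label), with the per-window `|zeta - d_m|` gap in attribute `"gap"`.
#' @export
assign_snapshots <- function(pull, ladder) {
  pos <- attr(pull, "positions")
  if (is.null(pos)) stop("pull carries no recorded positions")
  centers <- ladder_centers(ladder)
  idx <- vapply(centers, function(d) which.min(abs(pull$zeta - d)), integer(1))
  out <- pos[idx, , drop = FALSE]
  attr(out, "gap") <- abs(pull$zeta[idx] - centers)
  out
}
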