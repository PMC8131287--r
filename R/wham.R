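#' Build the per-window histogram set
#'
#' Bins every window's reaction-coordinate series on shared edges and
#' tabulates each window's umbrella bias at the bin centres (midpoint rule).
#' The cylindrical restraint is constant along the reaction coordinate by
#' construction and therefore drops out of the reweighting.
#'
#' @param series List (ordered like the ladder) of numeric zeta vectors, or of
#'   data frames with a `zeta` column as produced by [run_reus()].
#' @param edges Strictly increasing bin edges covering every sample (A).
#' @param ladder The `window_ladder` the series were generated under.
#' @return An object of class `histogram_set`: `counts` (M x B), `bias`
#'   (M x B, kcal/mol), `N`, `edges`, `centers`.
#' @export
build_histograms <- function(series, edges, ladder) {
  stopifnot(length(series) == length(ladder), all(diff(edges) > 0))
  zlist <- lapply(series, function(s) if (is.data.frame(s)) s$zeta else s)
  M <- length(ladder)
  B <- length(edges) - 1L
  counts <- matrix(0L, M, B)
  for (m in seq_len(M)) {
    z <- zlist[[m]]
    z <- z[!is.na(z)]
    if (length(z) == 0) stop("window ", m, " has no samples")
    if (any(z < edges[1] | z > edges[length(edges)]))
      stop("window ", m, " has samples outside the bin edges")
    idx <- findInterval(z, edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts[m, ] <- tabulate(idx, nbins = B)
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bias <- t(vapply(ladder, function(w) umbrella_energy(w, centers),
                   numeric(B)))
  structure(list(counts = counts, bias = bias, N = rowSums(counts),
                 edges = edges, centers = centers),
            class = "histogram_set")
}

#' Window-overlap matrix
#'
#' Number of bins in which both windows have counts; used to check that the
#' overlap graph is connected before reweighting.
#'
#' @param hist A `histogram_set`.
#' @return M x M integer matrix of shared-support bin counts.
#' @export
overlap_matrix <- function(hist) {
  occ <- hist$counts > 0
  tcrossprod(occ * 1L)
}

# Are all windows connected through shared-support bins?
overlap_connected <- function(hist) {
  adj <- overlap_matrix(hist) > 0
  M <- nrow(adj)
  seen <- logical(M)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Solve the WHAM equations
#'
#' Self-consistent iteration of the standard discrete WHAM equations
#' \deqn{p_b \propto \frac{\sum_m n_{mb}}{\sum_m N_m e^{\beta f_m - \beta
#' V_m(\zeta_b)}}, \qquad f_m = -\frac{1}{\beta} \ln \sum_b p_b e^{-\beta
#' V_m(\zeta_b)}} iterated until `max |delta f_m| < tol`, with the gauge fixed
#' by `f_1 = 0` and the unbiased probabilities normalised.
#'
#' @param hist A `histogram_set` with a connected overlap graph.
#' @param beta Inverse temperature (mol/kcal).
#' @param tol Convergence tolerance on the window free energies (kcal/mol).
#' @param max_iter Iteration cap.
#' @return An object of class `wham_fit`: `f` (per-window free energies,
#'   kcal/mol, `f[1] = 0`), `p` (unbiased per-bin probabilities), `centers`,
#'   `iterations`, `residual`, `converged`.
#' @export
solve_wham <- function(hist, beta, tol = 1e-7, max_iter = 1e5) {
  stopifnot(inherits(hist, "histogram_set"), beta > 0)
  if (!overlap_connected(hist))
    stop("window overlap graph is disconnected; WHAM solution is not unique")
  C <- colSums(hist$counts)
  res <- .wham_iterate_cpp(-beta * hist$bias, hist$N, C, beta, tol,
                           as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                 as.integer(max_iter), res$residual))
  structure(list(f = res$f, p = res$p, centers = hist$centers,
                 iterations = res$iterations, residual = res$residual,
                 converged = res$converged),
            class = "wham_fit")
}

#' WHAM negative log-likelihood in the window free energies
#'
#' Profile likelihood of the binned WHAM model as a function of the window
#' free-energy offsets (gauge `f[1] = 0`); its stationary point satisfies the
#' self-consistent WHAM equations, so direct minimisation is an independent
#' route to the same solution.
#'
#' @param f Per-window free energies (kcal/mol), `f[1]` fixed at 0 by
#'   convention.
#' @param hist A `histogram_set`.
#' @param beta Inverse temperature.
#' @return Scalar negative log-likelihood (up to an additive constant).
#' @export
wham_neg_loglik <- function(f, hist, beta) {
  C <- colSums(hist$counts)
  lse <- log(colSums(hist$N * exp(beta * f - beta * hist$bias)))
  sum(C * lse) - sum(hist$N * beta * f)
}

#' Direct-minimisation WHAM solution
#'
#' Minimises [wham_neg_loglik()] over `f[-1]` with analytic gradient
#' (L-BFGS-B), as a cross-check on [solve_wham()].
#'
#' @inheritParams solve_wham
#' @return A `wham_fit` (same structure as [solve_wham()]).
#' @export
wham_mle <- function(hist, beta, tol = 1e-12) {
  M <- nrow(hist$counts)
  C <- colSums(hist$counts)
  obj <- function(ftail) wham_neg_loglik(c(0, ftail), hist, beta)
  grad <- function(ftail) {
    f <- c(0, ftail)
    w <- hist$N * exp(beta * f - beta * hist$bias)  # M x B
    frac <- sweep(w, 2, colSums(w), "/")
    g <- beta * (as.numeric(frac %*% C) - hist$N)
    g[-1]
  }
  fit <- stats::optim(rep(0, M - 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 10000, factr = tol / .Machine$double.eps))
  f <- c(0, fit$par)
  w <- colSums(hist$N * exp(beta * f - beta * hist$bias))
  p <- ifelse(C > 0, C / w, 0)
  p <- p / sum(p)
  structure(list(f = f, p = p, centers = hist$centers,
                 iterations = fit$counts[1], residual = NA_real_,
                 converged = fit$convergence == 0),
            class = "wham_fit")
}

#' Potential of mean force from WHAM probabilities
#'
#' \eqn{F(\zeta_b) = -(1/\beta)\ln p_b}, shifted so the minimum over populated
#' bins is zero; empty bins are NA.
#'
#' @param fit A `wham_fit` (or a bare probability vector plus `centers`).
#' @param beta Inverse temperature (mol/kcal).
#' @param centers Bin centres, required when `fit` is a bare vector.
#' @param stderr Optional per-bin bootstrap standard errors.
#' @return An object of class `pmf_profile`: data frame `zeta`, `free_energy`
#'   (kcal/mol), `stderr`.
#' @export
pmf_from_wham <- function(fit, beta, centers = NULL, stderr = NULL) {
  p <- if (inherits(fit, "wham_fit")) fit$p else fit
  if (is.null(centers)) centers <- fit$centers
  if (all(p <= 0)) stop("all-zero probabilities")
  f <- ifelse(p > 0, -log(p) / beta, NA_real_)
  f <- f - min(f, na.rm = TRUE)
  out <- data.frame(zeta = centers, free_energy = f,
                    stderr = if (is.null(stderr)) NA_real_ else stderr)
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Write a PMF as CSV
#'
#' @param pmf A `pmf_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  utils::write.csv(as.data.frame(pmf), path, row.names = FALSE)
  invisible(path)
}

# Resolve unbound_region defaults: outermost `flank` A of each populated side
# (both flanks bidirectional; pass a single interval or a list of intervals).
resolve_regions <- function(pmf, bound_region, unbound_region, flank = 3) {
  ok <- !is.na(pmf$free_energy)
  zmin <- min(pmf$zeta[ok]); zmax <- max(pmf$zeta[ok])
  if (is.null(unbound_region)) {
    unbound_region <- list(c(zmin, zmin + flank))
    if (zmax - flank > bound_region[2])
      unbound_region <- c(unbound_region, list(c(zmax - flank, zmax)))
  } else if (!is.list(unbound_region)) {
    unbound_region <- list(unbound_region)
  }
  unbound_region
}

in_any <- function(z, regions) {
  hit <- rep(FALSE, length(z))
  for (r in regions) hit <- hit | (z >= r[1] & z <= r[2])
  hit
}

#' Pulling free energy from a PMF
#'
#' Extracts the free energy of pulling the guest into the binding region.  Two
#' conventions are provided: `"depth"` reads the well depth (free energy at the
#' bound minimum minus the mean over the unbound plateau; negative for a
#' binding well), while `"integrated"` Boltzmann-averages each region,
#' \eqn{-(1/\beta)\ln[\langle e^{-\beta F}\rangle_{bound} / \langle e^{-\beta
#' F}\rangle_{unbound}]}, which is the convention that composes exactly with
#' the volume and restraint corrections.
#'
#' @param pmf A `pmf_profile`.
#' @param bound_region Interval (A) containing the bound pose.
#' @param unbound_region Interval, list of intervals, or `NULL` (default: the
#'   outermost 3 A of each populated flank).
#' @param mode `"depth"` or `"integrated"`.
#' @param beta Inverse temperature (mol/kcal).
#' @return Pulling free energy (kcal/mol) with attributes `mode` and
#'   `regions`.
#' @export
delta_g_reus <- function(pmf, bound_region = c(-3, 3), unbound_region = NULL,
                         mode = c("depth", "integrated"), beta) {
  mode <- match.arg(mode)
  unbound_region <- resolve_regions(pmf, bound_region, unbound_region)
  ok <- !is.na(pmf$free_energy)
  bsel <- ok & pmf$zeta >= bound_region[1] & pmf$zeta <= bound_region[2]
  usel <- ok & in_any(pmf$zeta, unbound_region)
  if (!any(bsel) || !any(usel)) stop("empty bound or unbound region")
  fb <- pmf$free_energy[bsel]; fu <- pmf$free_energy[usel]
  val <- if (mode == "depth") {
    min(fb) - mean(fu)
  } else {
    -log(mean(exp(-beta * fb)) / mean(exp(-beta * fu))) / beta
  }
  attr(val, "mode") <- mode
  attr(val, "regions") <- list(bound = bound_region, unbound = unbound_region)
  val
}

#' PMF asymmetry score
#'
#' RMS difference between the profile at `center + x` and `center - x` over
#' the overlapping mirrored range (linear interpolation).  Zero for a profile
#' even about `center`; equal to `c` when one side is offset by a constant `c`.
#'
#' @param pmf A `pmf_profile`.
#' @param center Mirror point (A), default the bound pose at 0.
#' @return RMS asymmetry in kcal/mol.
#' @export
check_symmetry <- function(pmf, center = 0) {
  ok <- !is.na(pmf$free_energy)
  z <- pmf$zeta[ok]; f <- pmf$free_energy[ok]
  span_r <- max(z) - center
  span_l <- center - min(z)
  half <- min(span_r, span_l)
  if (half <= 0) stop("profile does not span both sides of the center")
  x <- seq(0, half, length.out = 200)
  fr <- stats::approx(z, f, xout = center + x)$y
  fl <- stats::approx(z, f, xout = center - x)$y
  keep <- !is.na(fr) & !is.na(fl)
  sqrt(mean((fr[keep] - fl[keep])^2))
}

# Moving-block bootstrap resample of one series (returns same length).
block_resample <- function(z, block) {
  n <- length(z)
  if (block > n) stop("block longer than series")
  n_blocks <- ceiling(n / block)
  starts <- sample.int(n - block + 1L, n_blocks, replace = TRUE)
  idx <- as.vector(outer(seq_len(block) - 1L, starts, `+`))[seq_len(n)]
  z[idx]
}

#' Block-bootstrap uncertainty of a pipeline statistic
#'
#' Resamples each window's reaction-coordinate series in moving blocks (to
#' respect serial correlation), reruns the supplied statistic on every
#' resample, and reports the standard deviation over replicates.
#' Seed-deterministic.
#'
#' @param series Per-window series (as accepted by [build_histograms()]).
#' @param statistic Function taking a resampled `series` list and returning a
#'   scalar (e.g. histograms -> WHAM -> [delta_g_reus()]).
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param block Block length in samples (>= 1).
#' @param seed Optional integer seed.
#' @return List with `stderr` and the vector of `replicates`.
#' @export
bootstrap_uncertainty <- function(series, statistic, n_boot = 50, block = 50,
                                  seed = NULL) {
  stopifnot(n_boot >= 2, block >= 1)
  if (!is.null(seed)) set.seed(seed)
  zlist <- lapply(series, function(s) if (is.data.frame(s)) s$zeta else s)
  reps <- vapply(seq_len(n_boot), function(b) {
    res <- lapply(zlist, block_resample, block = block)
    statistic(res)
  }, numeric(1))
  list(stderr = stats::sd(reps), replicates = reps)
}
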