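#' Paired prediction/experiment set
#'
#' @param guest Guest labels.
#' @param computed Computed binding free energies (kcal/mol).
#' @param experimental Experimental binding free energies (kcal/mol), paired
#'   by guest.
#' @param label Parameter-set label.
#' @return An object of class `prediction_set` (a data frame).
#' @export
prediction_set <- function(guest, computed, experimental, label = NA_character_) {
  stopifnot(length(guest) == length(computed),
            length(computed) == length(experimental),
            length(computed) >= 1,
            all(is.finite(computed)), all(is.finite(experimental)))
  out <- data.frame(guest = guest, computed = computed,
                    experimental = experimental)
  attr(out, "label") <- label
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Root-mean-square error
#'
#' \eqn{\sqrt{\sum (calc - exp)^2 / n}} with population denominator n.
#'
#' @param pred A [prediction_set()].
#' @return RMSE in kcal/mol.
#' @export
rmse <- function(pred) {
  sqrt(mean((pred$computed - pred$experimental)^2))
}

#' Pearson correlation between computed and experimental values
#'
#' @param pred A [prediction_set()] with n >= 3 and nonzero variance on both
#'   sides.
#' @return List with `r` and `r_squared`.
#' @export
pearson_r <- function(pred) {
  if (nrow(pred) < 3) stop("need at least 3 pairs")
  if (stats::sd(pred$computed) == 0 || stats::sd(pred$experimental) == 0)
    stop("zero variance")
  r <- stats::cor(pred$computed, pred$experimental)
  list(r = r, r_squared = r^2)
}

#' Kendall rank correlation (tau-a)
#'
#' \eqn{(C - D) / (n (n-1) / 2)} with no tie correction; ties are treated as
#' an error because tau-a is undefined on them.
#'
#' @param pred A [prediction_set()] with n >= 2.
#' @return Kendall's tau-a.
#' @export
kendall_tau <- function(pred) {
  x <- pred$computed; y <- pred$experimental
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  if (anyDuplicated(x) || anyDuplicated(y))
    stop("ties present; tau-a is undefined (no tie correction implemented)")
  s <- 0
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s / (n * (n - 1) / 2)
}

#' Mean absolute error and mean (signed) error
#'
#' MAE = mean |calc - exp|; ME = mean (exp - calc), the direction in which the
#' reference tabulation reports it.  Always `|ME| <= MAE`.
#'
#' @param pred A [prediction_set()].
#' @return Named list with `mae` and `me` (kcal/mol).
#' @export
mae_me <- function(pred) {
  list(mae = mean(abs(pred$computed - pred$experimental)),
       me = mean(pred$experimental - pred$computed))
}

#' Benchmark statistics table for one or more parameter sets
#'
#' @param computed Data frame with columns `guest`, `parameter_set`, `bind`
#'   (kcal/mol), e.g. stacked [binding_result()]s or a per-guest table.
#' @param experimental Named numeric vector (or two-column data frame
#'   `guest`, `dG`) of experimental values; every computed guest must be
#'   present.
#' @return List with `per_guest` (computed vs experimental long table) and
#'   `stats` (one row per parameter set: n, rmse, r, r_squared, tau, mae, me).
#' @export
build_report <- function(computed, experimental) {
  if (is.data.frame(experimental)) {
    exp_map <- stats::setNames(experimental[[2]], experimental[[1]])
  } else exp_map <- experimental
  if (length(exp_map) == 0) stop("empty experimental map")
  missing <- setdiff(unique(computed$guest), names(exp_map))
  if (length(missing) > 0)
    stop("missing experimental entries for: ", paste(missing, collapse = ", "))
  per_guest <- data.frame(computed,
                          experimental = unname(exp_map[computed$guest]))
  sets <- unique(computed$parameter_set)
  stats_rows <- lapply(sets, function(s) {
    sub <- per_guest[per_guest$parameter_set == s, ]
    ps <- prediction_set(sub$guest, sub$bind, sub$experimental, s)
    degenerate <- nrow(ps) < 3
    mm <- mae_me(ps)
    data.frame(parameter_set = s, n = nrow(ps), rmse = rmse(ps),
               r = if (degenerate) NA_real_ else pearson_r(ps)$r,
               r_squared = if (degenerate) NA_real_ else pearson_r(ps)$r_squared,
               tau = if (nrow(ps) < 2) NA_real_ else kendall_tau(ps),
               mae = mm$mae, me = mm$me)
  })
  list(per_guest = per_guest, stats = do.call(rbind, stats_rows))
}

#' Reference per-guest component table (FM-MP2 set)
#'
#' Transcription of the published per-guest free-energy components for the
#' FM-MP2 parameter set: volume correction, restraint-on correction, REUS
#' pulling free energy, assembled binding free energy, and the
#' stereoisomer-averaged column, all with uncertainties (kcal/mol).
#'
#' @return Data frame, one row per guest/stereoisomer state.
#' @export
published_components_table <- function() {
  path <- system.file("extdata", "table1_fm_mp2.csv", package = "reusbind",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference binding free energies for all parameter sets
#'
#' Transcription of the published averaged binding free energies for the three
#' parameter sets (FM-MP2, C36-S6, FM-PM6) next to the experimental values
#' (kcal/mol).  `G5N`/`G5P` are the neutral/protonated ketamine states and
#' `G5*` the pH-corrected entry.
#'
#' @return Data frame, one row per guest.
#' @export
published_binding_table <- function() {
  path <- system.file("extdata", "table2_binding.csv", package = "reusbind",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
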