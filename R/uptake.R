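#' Internalised and membrane-bound fractions over time
#'
#' Empirical uptake-kinetics model for receptor-mediated radioligand
#' binding at tracer concentration: the internalised fraction grows
#' linearly with incubation time while the specific membrane-bound
#' fraction stays at a constant plateau,
#' `f_int(t) = slope * t`, `f_mem(t) = plateau`. Units are percent of
#' applied activity (%IA); the default parameters are a slope of
#' 0.096 %IA/min and a membrane plateau of 0.56 %IA.
#'
#' @param t_min Incubation time in minutes (>= 0), vectorised.
#' @param slope Internalisation rate, %IA per minute.
#' @param f_mem_const Membrane plateau, %IA.
#' @return Data frame with columns `t_min`, `f_int`, `f_mem` (%IA).
#' @export
internalized_fraction <- function(t_min, slope = 0.096, f_mem_const = 0.56) {
  if (any(t_min < 0)) stop("t_min must be >= 0", call. = FALSE)
  if (slope < 0 || f_mem_const < 0) {
    stop("slope and f_mem_const must be >= 0", call. = FALSE)
  }
  data.frame(t_min = t_min, f_int = slope * t_min, f_mem = f_mem_const)
}

#' Total uptake as a function of peptide concentration
#'
#' Empirical single-exponential model of total cell-associated activity
#' versus applied peptide concentration,
#' \eqn{u([M]) = A e^{-k [M]} + B} (%A), monotone non-increasing in
#' concentration: uptake saturates towards the plateau `B` as unlabelled
#' peptide competes for the receptors. Defaults are the fitted values
#' A = 1.0 %A, k = 39 umol^-1, B = 0.38 %A.
#'
#' @param conc_umol Concentration in umol/L (>= 0), vectorised.
#' @param A Amplitude, %A.
#' @param k Decay constant, umol^-1 (strictly: per (umol/L)).
#' @param B Plateau, %A.
#' @return Uptake in %A.
#' @export
uptake_at_concentration <- function(conc_umol, A = 1.0, k = 39, B = 0.38) {
  if (any(conc_umol < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (A < 0 || k < 0 || B < 0) {
    stop("A, k and B must be >= 0", call. = FALSE)
  }
  A * exp(-k * conc_umol) + B
}

#' Fit the concentration-uptake model to assay data
#'
#' Nonlinear least squares for \eqn{A e^{-k[M]} + B} with non-negative
#' parameters, via Levenberg-Marquardt. Start values default to a crude
#' moment guess from the data.
#'
#' @param conc_umol Concentrations, umol/L.
#' @param uptake_pct Measured uptake, %A.
#' @param start Optional named list/vector with `A`, `k`, `B`.
#' @return List with `par` (named estimates), `se` (named standard
#'   errors), `fit` (the `nls` object).
#' @export
fit_concentration_uptake <- function(conc_umol, uptake_pct, start = NULL) {
  stopifnot(length(conc_umol) == length(uptake_pct), length(conc_umol) >= 4)
  if (is.null(start)) {
    B0 <- max(min(uptake_pct), 1e-6)
    A0 <- max(max(uptake_pct) - B0, 1e-6)
    start <- list(A = A0, k = 1 / max(mean(conc_umol), 1e-9), B = B0)
  }
  df <- data.frame(x = conc_umol, y = uptake_pct)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-k * x) + B, data = df, start = start,
    lower = c(A = 0, k = 0, B = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  sm <- summary(fit)
  list(par = stats::coef(fit), se = sm$coefficients[, "Std. Error"],
       fit = fit)
}

#' Fit the linear internalisation time course
#'
#' Least-squares slope through the origin for the internalised fraction
#' (`f_int = slope * t`) and the mean plateau for the membrane-bound
#' fraction.
#'
#' @param t_min Time points, minutes.
#' @param f_int_pct Internalised fraction measurements, %IA.
#' @param f_mem_pct Optional membrane-fraction measurements, %IA.
#' @return List with `slope`, `slope_se`, and (if membrane data given)
#'   `f_mem_const`, `f_mem_se`.
#' @export
fit_uptake_timecourse <- function(t_min, f_int_pct, f_mem_pct = NULL) {
  stopifnot(length(t_min) == length(f_int_pct), length(t_min) >= 2)
  fit <- stats::lm(f_int_pct ~ 0 + t_min)
  out <- list(slope = unname(stats::coef(fit)[1]),
              slope_se = unname(sqrt(diag(stats::vcov(fit)))[1]))
  if (!is.null(f_mem_pct)) {
    out$f_mem_const <- mean(f_mem_pct)
    out$f_mem_se <- stats::sd(f_mem_pct) / sqrt(length(f_mem_pct))
  }
  out
}

#' Rescale a fractional uptake to a different cell number
#'
#' Dilute-limit proportional extrapolation of a percent-of-applied
#' uptake measured with `n_assay` cells to `n_target` cells: with
#' receptors far from saturation each cell binds the same share, so the
#' well-level fraction scales with cell count. Used to carry uptake
#' measured at 0.5e6 cells to the 500-cell clonogenic wells.
#'
#' @param f_measured Uptake at `n_assay` cells, %A.
#' @param n_assay,n_target Cell counts (> 0).
#' @return Uptake at `n_target` cells, %A.
#' @export
scale_uptake <- function(f_measured, n_assay, n_target) {
  if (n_assay <= 0 || n_target <= 0) {
    stop("cell counts must be positive", call. = FALSE)
  }
  if (any(f_measured < 0)) stop("uptake must be >= 0", call. = FALSE)
  f_measured * n_target / n_assay
}

#' Radioligand molecules bound per cell
#'
#' Converts an applied activity and molar activity into bound molecule
#' numbers: \eqn{(A/MA)} nmol of labelled peptide applied,
#' \eqn{\times 10^{-9} N_A} molecules per nmol, times the bound fraction,
#' divided by the number of cells.
#'
#' @param A_applied Applied activity, MBq (> 0).
#' @param MA Molar activity, MBq/nmol (> 0).
#' @param f_bound Fraction of applied activity bound (>= 0; a fraction,
#'   not a percent).
#' @param n_cells Number of cells sharing the bound amount (> 0).
#' @return Molecules per cell.
#' @examples
#' molecules_per_cell(1, 53, 1e-6, 500)  # ~2.3e4
#' @export
molecules_per_cell <- function(A_applied, MA, f_bound, n_cells) {
  if (MA <= 0) stop("molar activity must be > 0", call. = FALSE)
  if (A_applied <= 0 || n_cells <= 0) {
    stop("A_applied and n_cells must be > 0", call. = FALSE)
  }
  if (f_bound < 0) stop("f_bound must be >= 0", call. = FALSE)
  avogadro <- 6.02214076e23
  (A_applied / MA) * 1e-9 * avogadro * f_bound / n_cells
}
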