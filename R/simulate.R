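#' Configuration for the synthetic assay generators
#'
#' Bundles the seed, design grids, noise levels and true model
#' parameters for the three simulated assays. Defaults reproduce the
#' study designs the generators emulate: 8 external-beam doses from
#' 0.5 to 10 Gy in triplicate with 500 cells seeded and plating
#' efficiency 0.4; uptake time courses to 60 min with slope
#' 0.096 %IA/min and membrane plateau 0.56 %IA; concentration series
#' over 15-390 nM with the exponential parameters A = 1.0 %A,
#' k = 39 umol^-1, B = 0.38 %A.
#'
#' @param seed Integer seed; fixes every generated dataset bit-for-bit.
#' @param n_replicates Replicate wells per design point.
#' @param doses_Gy Dose grid for clonogenic simulation.
#' @param seeded Cells seeded per well.
#' @param pe True plating efficiency.
#' @param alpha,beta True LQ parameters (Gy^-1, Gy^-2); `beta = 0`
#'   gives the linear-exponential model.
#' @param times_min Time grid for the internalisation time course.
#' @param slope,f_mem_const True time-course parameters (%IA/min, %IA).
#' @param conc_umol Concentration grid, umol/L (default 15-390 nM).
#' @param A,k,B True concentration-uptake parameters.
#' @param sigma_pct Gaussian noise SD for uptake measurements, %A.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_replicates = 3L,
                       doses_Gy = c(0.5, 1, 2, 4, 5, 6, 8, 10),
                       seeded = 500L,
                       pe = 0.4,
                       alpha = 0.21,
                       beta = 0.05,
                       times_min = c(5, 10, 15, 20, 30, 45, 60),
                       slope = 0.096,
                       f_mem_const = 0.56,
                       conc_umol = seq(0.015, 0.39, length.out = 12),
                       A = 1.0, k = 39, B = 0.38,
                       sigma_pct = 0.1) {
  stopifnot(length(doses_Gy) >= 1, length(times_min) >= 1,
            length(conc_umol) >= 1, n_replicates >= 1,
            sigma_pct >= 0, pe > 0, pe <= 1, seeded > 0,
            alpha >= 0, beta >= 0, slope >= 0, f_mem_const >= 0,
            A >= 0, k >= 0, B >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Run `expr` under the config's seed without disturbing the caller's
# RNG state, so generators are pure functions of their config.
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a clonogenic assay
#'
#' Colony counts are Poisson with mean
#' `seeded * pe * SF(D)`, `SF(D) = exp(-alpha D - beta D^2)`, per
#' replicate well, plus 0-dose control wells (mean `seeded * pe`) used
#' downstream to estimate the plating efficiency.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with columns `dose_Gy`, `replicate`, `colonies`,
#'   `seeded`; control wells have `dose_Gy = 0`.
#' @export
simulate_clonogenic <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    doses <- c(0, cfg$doses_Gy)
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        dose_Gy = doses)[, 2:1]
    sf <- sf_model(cfg$alpha, grid$dose_Gy, beta = cfg$beta)
    mu <- cfg$seeded * cfg$pe * sf
    grid$colonies <- stats::rpois(nrow(grid), mu)
    grid$seeded <- cfg$seeded
    rownames(grid) <- NULL
    grid
  })
}

#' Simulate an internalisation time course
#'
#' Linear internalised fraction `slope * t` and constant membrane
#' fraction, each with additive homoscedastic Gaussian noise of SD
#' `sigma_pct` (%IA), per replicate and time point.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with columns `t_min`, `replicate`, `f_int`,
#'   `f_mem` (%IA).
#' @export
simulate_uptake_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        t_min = cfg$times_min)[, 2:1]
    n <- nrow(grid)
    grid$f_int <- pmax(0, cfg$slope * grid$t_min +
                         stats::rnorm(n, 0, cfg$sigma_pct))
    grid$f_mem <- pmax(0, cfg$f_mem_const +
                         stats::rnorm(n, 0, cfg$sigma_pct))
    rownames(grid) <- NULL
    grid
  })
}

#' Simulate a concentration-uptake series
#'
#' Total uptake `A * exp(-k [M]) + B` with additive Gaussian noise of
#' SD `sigma_pct` (%A) on the configured concentration grid.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with columns `conc_umol`, `replicate`,
#'   `uptake_pct` (%A).
#' @export
simulate_concentration_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        conc_umol = cfg$conc_umol)[, 2:1]
    n <- nrow(grid)
    grid$uptake_pct <- pmax(0, uptake_at_concentration(
      grid$conc_umol, cfg$A, cfg$k, cfg$B) +
        stats::rnorm(n, 0, cfg$sigma_pct))
    rownames(grid) <- NULL
    grid
  })
}
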