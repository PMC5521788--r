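#' Surviving fraction from colony counts
#'
#' Clonogenic surviving fraction
#' \eqn{SF = \mathrm{colonies} / (\mathrm{seeded} \times PE)} with the
#' plating efficiency PE taken from untreated control wells. The
#' standard error uses the binomial approximation on the colony-forming
#' probability \eqn{p = \mathrm{colonies}/\mathrm{seeded}}:
#' \eqn{SE(SF) = \sqrt{p(1-p)/\mathrm{seeded}} / PE}.
#'
#' @param colonies Colonies counted (vectorised, 0 <= colonies <= seeded).
#' @param seeded Cells seeded per well (> 0).
#' @param pe Plating efficiency in (0, 1].
#' @return Data frame with columns `sf` and `se`.
#' @examples
#' surviving_fraction(30, 500, 0.4)  # SF = 0.15
#' @export
surviving_fraction <- function(colonies, seeded, pe) {
  if (any(pe <= 0 | pe > 1)) stop("pe must be in (0, 1]", call. = FALSE)
  if (any(seeded <= 0)) stop("seeded must be > 0", call. = FALSE)
  if (any(colonies < 0) || any(colonies > seeded)) {
    stop("colonies must lie in [0, seeded]", call. = FALSE)
  }
  p <- colonies / seeded
  data.frame(sf = p / pe, se = sqrt(p * (1 - p) / seeded) / pe)
}

#' Fit a clonogenic survival curve
#'
#' Least-squares fit of the linear-quadratic model
#' \eqn{-\ln SF = \alpha D + \beta D^2} (or the one-phase
#' linear-exponential model with \eqn{\beta = 0}) to clonogenic data.
#' The fit is unweighted in the log-survival domain, joint over all
#' replicate points, with non-negativity constraints on both
#' coefficients enforced by an active-set search over the four boundary
#' configurations (interior, alpha = 0, beta = 0, both 0). When a
#' constraint binds, the pinned coefficient is reported as 0 with `NA`
#' standard error and flagged.
#'
#' Wells with SF exactly 0 (log undefined) are excluded with a warning;
#' high-LET alpha-emitter data typically fit the linear model, photon
#' reference data the LQ model.
#'
#' @param dose_Gy Absorbed doses, Gy.
#' @param sf Surviving fractions (>= 0); values of exactly 0 are
#'   excluded from the log-domain fit with a warning, and noisy wells
#'   above 1 (colonies exceeding the control expectation) are accepted.
#' @param model `"LQ"` or `"linear"`.
#' @return Object of class `survival_fit`: list with `model`, `alpha`,
#'   `alpha_se`, `beta`, `beta_se` (`NA` for linear model), covariance
#'   `vcov`, `r_squared`, logical flags `alpha_at_bound`,
#'   `beta_at_bound`, `n_points`.
#' @examples
#' d <- c(0.5, 1, 2, 4, 5, 6, 8, 10)
#' sf <- exp(-0.21 * d - 0.05 * d^2)
#' fit_survival(d, sf, "LQ")
#' @export
fit_survival <- function(dose_Gy, sf, model = c("LQ", "linear")) {
  model <- match.arg(model)
  stopifnot(length(dose_Gy) == length(sf))
  if (any(dose_Gy < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(sf < 0)) {
    stop("surviving fractions must be >= 0", call. = FALSE)
  }
  keep <- sf > 0 & dose_Gy > 0
  if (any(sf == 0)) {
    warning(sum(sf == 0), " point(s) with SF = 0 excluded from the ",
            "log-domain fit", call. = FALSE)
  }
  if (!any(keep)) stop("no usable (positive-SF, positive-dose) points",
                       call. = FALSE)
  D <- dose_Gy[keep]
  y <- -log(sf[keep])
  n_distinct <- length(unique(D))
  if (model == "LQ" && n_distinct < 3) {
    stop("LQ fit needs >= 3 distinct positive doses", call. = FALSE)
  }
  if (model == "linear" && n_distinct < 2) {
    stop("linear fit needs >= 2 distinct positive doses", call. = FALSE)
  }

  fit_lin <- function() {
    f <- stats::lm(y ~ 0 + D)
    a <- unname(stats::coef(f)[1])
    list(alpha = a, beta = 0, vc = stats::vcov(f), rss = sum(stats::resid(f)^2),
         pinned = c(alpha = FALSE, beta = TRUE), keepable = a >= 0)
  }
  fit_quad_only <- function() {
    D2 <- D^2
    f <- stats::lm(y ~ 0 + D2)
    b <- unname(stats::coef(f)[1])
    list(alpha = 0, beta = b, vc = stats::vcov(f), rss = sum(stats::resid(f)^2),
         pinned = c(alpha = TRUE, beta = FALSE), keepable = b >= 0)
  }

  if (model == "linear") {
    cand <- fit_lin()
    if (!cand$keepable) stop("linear fit yields negative alpha", call. = FALSE)
    alpha <- cand$alpha; beta <- NA_real_
    alpha_se <- sqrt(cand$vc[1, 1]); beta_se <- NA_real_
    vc <- matrix(cand$vc[1, 1], 1, 1, dimnames = list("alpha", "alpha"))
    pinned <- c(alpha = FALSE, beta = FALSE)
    rss <- cand$rss
  } else {
    D2 <- D^2
    f <- stats::lm(y ~ 0 + D + D2)
    co <- stats::coef(f)
    if (all(co >= 0)) {
      alpha <- unname(co[1]); beta <- unname(co[2])
      vc <- stats::vcov(f)
      dimnames(vc) <- list(c("alpha", "beta"), c("alpha", "beta"))
      alpha_se <- sqrt(vc[1, 1]); beta_se <- sqrt(vc[2, 2])
      pinned <- c(alpha = FALSE, beta = FALSE)
      rss <- sum(stats::resid(f)^2)
    } else {
      # active-set: evaluate both single-coefficient boundary fits
      cands <- Filter(function(cc) cc$keepable, list(fit_lin(), fit_quad_only()))
      if (length(cands) == 0L) {
        # both single fits infeasible -> flat curve, reject
        stop("no non-negative LQ fit exists (all-zero response?)",
             call. = FALSE)
      }
      best <- cands[[which.min(vapply(cands, `[[`, 0, "rss"))]]
      alpha <- best$alpha; beta <- best$beta
      pinned <- best$pinned
      free_se <- sqrt(best$vc[1, 1])
      alpha_se <- if (pinned["alpha"]) NA_real_ else free_se
      beta_se <- if (pinned["beta"]) NA_real_ else free_se
      vc <- best$vc
      rss <- best$rss
    }
  }
  if (alpha == 0 && (is.na(beta) || beta == 0)) {
    stop("fitted curve is flat (alpha = beta = 0)", call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  structure(
    list(model = model, alpha = alpha, alpha_se = alpha_se,
         beta = beta, beta_se = beta_se, vcov = vc,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         alpha_at_bound = unname(pinned["alpha"]),
         beta_at_bound = unname(pinned["beta"]),
         n_points = length(D)),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> %s model, n = %d\n", x$model, x$n_points))
  cat(sprintf("  alpha = %.4g Gy^-1 (SE %.3g)%s\n", x$alpha, x$alpha_se,
              if (isTRUE(x$alpha_at_bound)) " [at 0 bound]" else ""))
  if (x$model == "LQ") {
    cat(sprintf("  beta  = %.4g Gy^-2 (SE %.3g)%s\n", x$beta, x$beta_se,
                if (isTRUE(x$beta_at_bound)) " [at 0 bound]" else ""))
  }
  cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Fit a survival curve to colony counts (Poisson regression)
#'
#' Count-level companion to [fit_survival()] for inference: colony
#' counts are modelled as Poisson,
#' \deqn{\log \mu = \log(\mathrm{seeded}) + \log PE - \alpha D - \beta D^2,}
#' a log-link GLM whose intercept estimates the log plating efficiency
#' jointly from the 0-dose control wells, so PE uncertainty propagates
#' into the coefficient covariance. Unlike the log-survival
#' least-squares fit, zero-colony wells enter the likelihood directly
#' (no log-domain exclusion) and the heavy-tailed noise of near-zero
#' counts at high doses is weighted correctly, which keeps the Wald
#' intervals calibrated. Non-negativity of alpha and beta is enforced
#' by the same active-set search as in [fit_survival()], comparing
#' residual deviance across boundary configurations.
#'
#' @param dose_Gy Absorbed dose per well, Gy; include the 0-dose
#'   control wells.
#' @param colonies Colonies counted per well.
#' @param seeded Cells seeded per well (scalar or per-well vector).
#' @param model `"LQ"` or `"linear"`.
#' @return A `survival_fit` (as in [fit_survival()]) with additional
#'   elements `pe` (fitted plating efficiency) and `deviance`;
#'   `r_squared` is the deviance-based pseudo R-squared.
#' @examples
#' cfg <- sim_config(seed = 1)
#' dat <- simulate_clonogenic(cfg)
#' fit_survival_counts(dat$dose_Gy, dat$colonies, dat$seeded, "LQ")
#' @export
fit_survival_counts <- function(dose_Gy, colonies, seeded,
                                model = c("LQ", "linear")) {
  model <- match.arg(model)
  n <- length(dose_Gy)
  seeded <- rep_len(seeded, n)
  stopifnot(length(colonies) == n)
  if (any(dose_Gy < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(colonies < 0)) stop("colonies must be >= 0", call. = FALSE)
  if (!any(dose_Gy == 0)) {
    stop("count-level fit needs 0-dose control wells for the plating ",
         "efficiency intercept", call. = FALSE)
  }
  if (all(colonies[dose_Gy > 0] == 0)) {
    stop("all treated wells have zero colonies; survival cannot be fit",
         call. = FALSE)
  }
  n_distinct <- length(unique(dose_Gy[dose_Gy > 0]))
  if (model == "LQ" && n_distinct < 3) {
    stop("LQ fit needs >= 3 distinct positive doses", call. = FALSE)
  }
  if (model == "linear" && n_distinct < 2) {
    stop("linear fit needs >= 2 distinct positive doses", call. = FALSE)
  }

  D <- dose_Gy
  D2 <- D^2
  off <- log(seeded)
  glm_fit <- function(formula) {
    stats::glm(formula, family = stats::poisson(), offset = off)
  }
  extract <- function(f, has_a, has_b) {
    co <- stats::coef(f)
    vc <- stats::vcov(f)
    a <- if (has_a) -unname(co["D"]) else 0
    b <- if (has_b) -unname(co["D2"]) else if (model == "LQ") 0 else NA_real_
    list(fit = f, alpha = a, beta = b,
         alpha_se = if (has_a) sqrt(vc["D", "D"]) else NA_real_,
         beta_se = if (has_b) sqrt(vc["D2", "D2"]) else NA_real_,
         dev = stats::deviance(f),
         feasible = (!has_a || a >= 0) && (!has_b || b >= 0),
         pinned = c(alpha = !has_a, beta = !has_b))
  }

  if (model == "linear") {
    cand <- extract(glm_fit(colonies ~ 1 + D), TRUE, FALSE)
    if (!cand$feasible) {
      stop("linear fit yields negative alpha (no dose response)",
           call. = FALSE)
    }
    best <- cand
  } else {
    full <- extract(glm_fit(colonies ~ 1 + D + D2), TRUE, TRUE)
    if (full$feasible) {
      best <- full
    } else {
      cands <- Filter(
        function(cc) cc$feasible,
        list(extract(glm_fit(colonies ~ 1 + D), TRUE, FALSE),
             extract(glm_fit(colonies ~ 1 + D2), FALSE, TRUE)))
      if (length(cands) == 0L) {
        stop("no non-negative LQ fit exists (no dose response)",
             call. = FALSE)
      }
      best <- cands[[which.min(vapply(cands, `[[`, 0, "dev"))]]
    }
  }

  f <- best$fit
  null_dev <- f$null.deviance
  vc_full <- stats::vcov(f)
  structure(
    list(model = model, alpha = best$alpha, alpha_se = best$alpha_se,
         beta = best$beta, beta_se = best$beta_se, vcov = vc_full,
         r_squared = if (null_dev > 0) 1 - best$dev / null_dev
                     else NA_real_,
         alpha_at_bound = unname(best$pinned["alpha"]),
         beta_at_bound = unname(best$pinned["beta"]),
         pe = unname(exp(stats::coef(f)["(Intercept)"])),
         deviance = best$dev,
         n_points = n),
    class = "survival_fit"
  )
}

#' Model surviving fraction at a dose
#'
#' \eqn{SF(D) = e^{-\alpha D - \beta D^2}} for a fitted curve or
#' explicit coefficients.
#'
#' @param fit A `survival_fit`, or a numeric alpha (with `beta` given).
#' @param dose_Gy Dose(s), Gy.
#' @param beta Quadratic coefficient when `fit` is numeric.
#' @return Surviving fraction(s).
#' @export
sf_model <- function(fit, dose_Gy, beta = 0) {
  if (inherits(fit, "survival_fit")) {
    a <- fit$alpha
    b <- if (is.na(fit$beta)) 0 else fit$beta
  } else {
    a <- fit; b <- beta
  }
  exp(-a * dose_Gy - b * dose_Gy^2)
}

#' Dose at a fixed survival level
#'
#' Inverts the fitted survival curve: solves
#' \eqn{\alpha D + \beta D^2 = -\ln S} for the positive root. With
#' \eqn{\beta = 0} this is \eqn{-\ln S / \alpha}. `S_target = 0.1`
#' gives the D10, `0.2` the D20.
#'
#' @param fit A `survival_fit`, or numeric alpha.
#' @param S_target Target surviving fraction in (0, 1].
#' @param beta Quadratic coefficient when `fit` is numeric.
#' @return Dose in Gy.
#' @examples
#' dose_at_survival(0.21, 0.1, beta = 0.05)  # ~5.0 Gy
#' @export
dose_at_survival <- function(fit, S_target, beta = 0) {
  if (inherits(fit, "survival_fit")) {
    a <- fit$alpha
    b <- if (is.na(fit$beta)) 0 else fit$beta
  } else {
    a <- fit; b <- beta
  }
  if (S_target <= 0 || S_target > 1) {
    stop("S_target must be in (0, 1]", call. = FALSE)
  }
  if (a < 0 || b < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (a == 0 && b == 0) stop("flat curve: alpha = beta = 0", call. = FALSE)
  L <- -log(S_target)
  if (L == 0) return(0)
  if (b == 0) return(L / a)
  (-a + sqrt(a^2 + 4 * b * L)) / (2 * b)
}

#' Relative biological effectiveness
#'
#' RBE at a common endpoint: the ratio of the reference-radiation dose
#' to the test-radiation dose producing the same effect (here, the same
#' surviving fraction), \eqn{RBE = D_{ref} / D_{test}}.
#'
#' @param D_reference Reference-radiation dose, Gy (> 0).
#' @param D_test Test-radiation dose, Gy (> 0).
#' @return Dimensionless ratio.
#' @examples
#' rbe(5.1, 2.6)   # ~2.0
#' rbe(17.8, 3.3)  # ~5.4
#' @export
rbe <- function(D_reference, D_test) {
  if (any(D_reference <= 0) || any(D_test <= 0)) {
    stop("doses must be > 0", call. = FALSE)
  }
  D_reference / D_test
}

#' alpha/beta ratio of an LQ fit
#'
#' The dose at which linear and quadratic cell kill contribute equally,
#' \eqn{\alpha/\beta} (Gy), with a first-order (delta-method) standard
#' error propagated from the fit covariance. With alpha pinned at the
#' zero bound the ratio is 0; with beta = 0 the ratio is unbounded and
#' flagged.
#'
#' @param fit A `survival_fit` from the LQ model.
#' @return List with `ratio` (Gy), `se`, and logical `unbounded`.
#' @export
alpha_beta_ratio <- function(fit) {
  stopifnot(inherits(fit, "survival_fit"))
  if (fit$model != "LQ") stop("alpha/beta requires an LQ fit", call. = FALSE)
  if (is.na(fit$beta) || fit$beta == 0) {
    return(list(ratio = Inf, se = NA_real_, unbounded = TRUE))
  }
  if (fit$alpha == 0) {
    return(list(ratio = 0, se = NA_real_, unbounded = FALSE))
  }
  r <- fit$alpha / fit$beta
  va <- fit$alpha_se^2
  vb <- fit$beta_se^2
  vc <- fit$vcov
  cab <- if (!is.null(rownames(vc)) && all(c("D", "D2") %in% rownames(vc))) {
    vc["D", "D2"]  # cov(-alpha, -beta) = cov(alpha, beta)
  } else if (all(dim(vc) == c(2, 2))) {
    vc[1, 2]
  } else 0
  se <- abs(r) * sqrt(va / fit$alpha^2 + vb / fit$beta^2 -
                        2 * cab / (fit$alpha * fit$beta))
  list(ratio = r, se = se, unbounded = FALSE)
}
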