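# Independent numerical oracles used across the test files.

# Runge-Kutta/LSODA oracle for chain cumulated activities: integrates the
# atom-number ODEs dN/dt = inflow - lambda*N together with the cumulated
# activities C_i = int lambda_i N_i dt, with daughters zero at t = 0.
# Independent of the package's closed forms.
ode_cumulated_activity <- function(A0, chain, t0, t1, rtol = 1e-9) {
  skip_if_not_installed("deSolve")
  lam <- sapply(chain$nuclides, function(n) n$lambda)
  nms <- names(lam)
  edges <- chain$edges
  pa_i <- match(edges$parent, nms)
  da_i <- match(edges$daughter, nms)
  rhs <- function(t, y, p) {
    N <- y[seq_along(nms)]
    dN <- -lam * N
    for (i in seq_along(pa_i)) {
      dN[da_i[i]] <- dN[da_i[i]] +
        edges$branching_ratio[i] * lam[pa_i[i]] * N[pa_i[i]]
    }
    list(c(dN, lam * N))
  }
  y0 <- c(A0 / lam[[chain$root]] * (nms == chain$root), rep(0, length(nms)))
  times <- unique(c(0, t0, t1))
  out <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = 1e-14,
                        maxsteps = 1e6)
  C <- out[, 1 + length(nms) + seq_along(nms), drop = FALSE]
  res <- C[nrow(out), ] - C[match(t0, times), ]
  names(res) <- nms
  res
}

# Brute-force LQ least-squares oracle: coarse grid over the non-negative
# (alpha, beta) quadrant minimising the residual sum of squares of
# -log(SF), refined by box-constrained quasi-Newton from the grid best.
# Independent of the package's linear-model fit path.
lq_grid_oracle <- function(dose, sf) {
  y <- -log(sf)
  rss <- function(p) sum((y - p[1] * dose - p[2] * dose^2)^2)
  grid <- expand.grid(a = seq(0, 2, by = 0.02), b = seq(0, 0.5, by = 0.005))
  vals <- apply(grid, 1, rss)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, rss, method = "L-BFGS-B",
                      lower = c(0, 0),
                      control = list(factr = 10, maxit = 5000))
  c(alpha = opt$par[1], beta = opt$par[2])
}

# Convenience: a fresh random chain of 2-3 members with distinct,
# well-separated decay constants (avoids the near-degenerate Bateman
# denominators the closed forms do not special-case).
random_chain <- function(n = 3, hl_range = c(1e-1, 1e5), min_ratio = 1.2) {
  repeat {
    hl <- 10^stats::runif(n, log10(hl_range[1]), log10(hl_range[2]))
    r <- sort(hl)
    if (all(r[-1] / r[-n] > min_ratio)) break
  }
  nucs <- lapply(seq_len(n), function(i) {
    nuclide(paste0("N", i), hl[i])
  })
  edges <- data.frame(
    parent = paste0("N", seq_len(n - 1)),
    daughter = paste0("N", seq_len(n - 1) + 1),
    branching_ratio = stats::runif(n - 1, 0.1, 1)
  )
  decay_chain(nucs, edges)
}
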