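# Shared fixtures: small random regression instances built in code.

random_instance <- function(n = 20, d = 3, theta = NULL, q = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    if (is.null(theta)) theta <- c(0.5, rnorm(d))
    data <- lq_data(x, rep(0, n))
    y <- theta[1L] + drop(data$x %*% theta[-1L]) + rqnormal(n, 0, 1, q)
    list(data = lq_data(data$x, y, standardize = FALSE), theta = theta,
         x = x, y = y)
  })
}

# Per-coordinate penalty from the printed closed forms (oracle side).
pen_each <- function(t, spec) {
  t <- abs(t)
  lam <- spec$lambda
  switch(spec$family,
    lasso = lam * t,
    scad = {
      a <- spec$a
      ifelse(t <= lam, lam * t,
             ifelse(t <= a * lam,
                    -(t^2 - 2 * a * lam * t + lam^2) / (2 * (a - 1)),
                    (a + 1) * lam^2 / 2))
    },
    mcp = {
      g <- spec$gamma
      ifelse(t <= g * lam, lam * t - t^2 / (2 * g), g * lam^2 / 2)
    }
  )
}

# Unit-curvature scalar objective used as the brute-force oracle for the
# thresholding operators.
scalar_objective <- function(t, z, spec, kappa = 1) {
  kappa / 2 * (t - z)^2 + pen_each(t, spec)
}

# Two-stage grid minimizer at 1e-5 resolution (coarse 1e-3 pass, then a
# fine pass around the coarse winner).
grid_threshold <- function(z, spec, kappa = 1, fine = 1e-5) {
  s <- sign(z)
  z <- abs(z)
  hi <- z + 1
  coarse <- seq(0, hi, by = 1e-3)
  oc <- scalar_objective(coarse, z, spec, kappa)
  t0 <- coarse[which.min(oc)]
  finegrid <- seq(max(0, t0 - 2e-3), min(hi, t0 + 2e-3), by = fine)
  of <- scalar_objective(finegrid, z, spec, kappa)
  s * finegrid[which.min(of)]
}
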