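toy_data <- function() {
  # interpolating 2-point design, used unstandardized
  lq_data(matrix(c(0, 1), 2, 1), c(0, 1), standardize = FALSE)
}

test_that("Lq-likelihood reduces to the normal log-likelihood at q = 1", {
  inst <- random_instance(n = 25, d = 3, seed = 2)
  th <- c(0.1, 1, -2, 0.5)
  r <- inst$data$y - (th[1] + drop(inst$data$x %*% th[-1]))
  expect_equal(lq_likelihood(th, inst$data, q = 1),
               -sum(r^2) / 2 - 25 / 2 * log(2 * pi))
  expect_equal(lq_likelihood(th, inst$data, q = 1),
               log_likelihood(th, inst$data, q = 1))
  expect_equal(lq_likelihood(c(0, 1), toy_data(), q = 1), -log(2 * pi))
})

test_that("Lq-likelihood is affine in the residual sum of squares with slope -Zq^(q-1)/(3-q)", {
  inst <- random_instance(n = 30, d = 4, seed = 3)
  thA <- c(0, 1, 1, 0, -1)
  thB <- c(0.3, -1, 2, 0.5, 0)
  rss <- function(th) sum((inst$data$y - th[1] - inst$data$x %*% th[-1])^2)
  for (q in c(13 / 11, 1.5, 2, 2.5)) {
    spec <- q_spec(q)
    slope <- (lq_likelihood(thA, inst$data, q) - lq_likelihood(thB, inst$data, q)) /
      (rss(thB) - rss(thA))
    expect_equal(slope, spec$Zq^(q - 1) / (3 - q), tolerance = 1e-10)
  }
})

test_that("log-likelihood matches the t/Cauchy density and is additive", {
  # two zero-residual observations under the Cauchy model
  d2 <- lq_data(matrix(c(0, 1), 2, 1), c(0.5, 1.5), standardize = FALSE)
  expect_equal(log_likelihood(c(0.5, 1), d2, q = 2), 2 * log(1 / pi))
  inst <- random_instance(n = 12, d = 2, seed = 4, q = 1.5)
  th <- c(0.2, 1, -1)
  half1 <- lq_data(inst$data$x[1:6, ], inst$data$y[1:6], standardize = FALSE)
  half2 <- lq_data(inst$data$x[7:12, ], inst$data$y[7:12], standardize = FALSE)
  expect_equal(log_likelihood(th, inst$data, 1.5),
               log_likelihood(th, half1, 1.5) + log_likelihood(th, half2, 1.5))
  # agrees with direct summation over the density
  expect_equal(log_likelihood(th, inst$data, 1.5),
               sum(log(dqnormal(inst$data$y - th[1] -
                                  drop(inst$data$x %*% th[-1]), q = 1.5))))
})

test_that("the MLqE is the OLS solution, independently of q", {
  expect_equal(unname(mlqe(toy_data(), q = 1)), c(0, 1))
  inst <- random_instance(n = 40, d = 5, seed = 5)
  ols <- unname(coef(lm(inst$data$y ~ inst$data$x)))
  for (q in c(1, 2, 2.9)) {
    expect_equal(unname(mlqe(inst$data, q)), ols, tolerance = 1e-10)
  }
  # rank-deficient designs are an error, not a silent pseudo-inverse
  xdup <- cbind(inst$x, inst$x[, 1])
  expect_error(mlqe(lq_data(xdup, inst$y, standardize = FALSE)),
               "rank deficient")
})

test_that("numerically maximizing the Lq-likelihood recovers OLS", {
  inst <- random_instance(n = 20, d = 3, seed = 6, q = 1.5)
  ols <- unname(mlqe(inst$data))
  for (q in c(1, 2)) {
    opt <- optim(rep(0, 4), function(th) -lq_likelihood(th, inst$data, q),
                 method = "BFGS", control = list(reltol = 1e-15, maxit = 1000))
    expect_equal(opt$par, ols, tolerance = 1e-6)
  }
})

test_that("submodel MLE: q = 1 is OLS, q > 1 dominates the OLS refit", {
  inst <- random_instance(n = 50, d = 4, seed = 7, q = 5 / 3,
                          theta = c(0, 3, -3, 0, 0))
  full <- submodel_mle(inst$data, 1:4, q = 1)
  expect_true(full$available)
  expect_equal(unname(full$coef), unname(mlqe(inst$data)), tolerance = 1e-12)

  for (q in c(3 / 2, 5 / 3)) {
    sub <- submodel_mle(inst$data, c(1, 2), q = q)
    expect_true(sub$available)
    # OLS refit on the same support
    ols_refit <- submodel_mle(inst$data, c(1, 2), q = 1)$coef
    expect_gte(sub$loglik, log_likelihood(ols_refit, inst$data, q) - 1e-10)
    expect_equal(sub$coef[c(4, 5)], c(0, 0))
  }
})

test_that("submodel MLE matches a generic optimizer on strong-signal data", {
  inst <- random_instance(n = 200, d = 3, seed = 8, q = 5 / 3,
                          theta = c(1, 5, -5, 0))
  fit <- submodel_mle(inst$data, c(1, 2), q = 5 / 3)
  expect_true(fit$available)
  opt <- optim(c(0, 0, 0),
               function(b) -log_likelihood(c(b[1], b[2], b[3], 0),
                                           inst$data, 5 / 3),
               method = "BFGS", control = list(reltol = 1e-15, maxit = 2000))
  expect_equal(unname(fit$coef[1:3]), opt$par, tolerance = 1e-5)
  # within 3 standard errors of the truth: unit-norm columns give slope
  # SE ~ sqrt((nu+3)/(nu+1)) = sqrt(5/3) ~ 1.29 for t(2) errors
  expect_lt(max(abs(fit$coef - inst$theta)), 3 * sqrt(5 / 3))
})

test_that("intercept-only t-location MLE sits near the sample median", {
  inst <- random_instance(n = 400, d = 2, seed = 9, q = 2,
                          theta = c(1.5, 0, 0))
  fit <- submodel_mle(inst$data, integer(0), q = 2)
  expect_true(fit$available)
  # 1-d grid-search oracle for the Cauchy location MLE
  grid <- seq(median(inst$data$y) - 1, median(inst$data$y) + 1, by = 1e-4)
  ll <- vapply(grid, function(m) sum(dcauchy(inst$data$y - m, log = TRUE)),
               numeric(1))
  expect_equal(fit$coef[1], grid[which.max(ll)], tolerance = 1e-3)
  expect_lt(abs(fit$coef[1] - median(inst$data$y)), 0.2)
})

test_that("support validation catches out-of-range indices", {
  inst <- random_instance(n = 20, d = 3, seed = 10)
  expect_error(submodel_mle(inst$data, 5, q = 1), "1..d")
})
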