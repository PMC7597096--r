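test_that("standardization centers and unit-norms columns and round-trips", {
  d <- lq_data(matrix(c(1, 2, 3), 3, 1), c(1, 0, 1))
  expect_equal(drop(d$x), c(-1, 0, 1) / sqrt(2))
  # idempotence
  d2 <- lq_data(d$x, d$y)
  expect_equal(d2$x, d$x, tolerance = 1e-12)
  # destandardized coefficients reproduce fitted values on the raw inputs
  withr::with_seed(12, {
    x <- matrix(rnorm(60, sd = 4) + 7, 20, 3)
    y <- rnorm(20)
  })
  fit <- lq_fit(x, y, "lasso", lambda = 0.05)
  d3 <- lq_data(x, y)
  fitted_std <- fit$coef[1] + drop(d3$x %*% fit$coef[-1])
  fitted_orig <- fit$coef_original[1] + drop(x %*% fit$coef_original[-1])
  expect_equal(fitted_std, fitted_orig, tolerance = 1e-10)
  # zero-variance column is a named degenerate-input error
  xz <- cbind(x, zcol = 5)
  expect_error(lq_data(xz, y), "zcol")
})

test_that("lambda grid is log-spaced and every family starts all-zero", {
  inst <- random_instance(n = 40, d = 6, seed = 13, theta = c(0, 2, -2, 0, 0, 0, 0))
  data <- lq_data(inst$x, inst$y)
  lam <- lambda_grid(data, nlambda = 57)
  expect_length(lam, 57)
  ratios <- lam[-1] / lam[-57]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  for (fam in c("lasso", "scad", "mcp")) {
    fit <- lq_fit(data, penalty = fam, lambda = lam[1])
    expect_equal(unname(fit$coef), c(mean(data$y), rep(0, 6)), tolerance = 1e-9)
  }
  # just above lambda_max nothing enters; just below, something does (lasso)
  p <- lq_path(data, penalty = "lasso", lambda = c(lam[1] * 1.01, lam[1] * 0.99))
  expect_true(all(p$coefs[-1, 1] == 0))
  expect_gt(sum(p$coefs[-1, 2] != 0), 0)
})

test_that("LASSO satisfies its KKT conditions at convergence", {
  inst <- random_instance(n = 50, d = 8, seed = 14,
                          theta = c(0.5, 3, -2, 1, rep(0, 5)))
  data <- lq_data(inst$x, inst$y)
  p <- lq_path(data, penalty = "lasso", nlambda = 30)
  xt <- data$x * sqrt(data$n) # solver-scale columns
  for (k in c(5, 15, 25)) {
    tb <- p$coefs[-1, k] / sqrt(data$n) # solver-scale coefficients
    r <- data$y - p$coefs[1, k] - drop(data$x %*% p$coefs[-1, k])
    g <- drop(crossprod(xt, r)) / data$n
    lam <- p$lambda[k]
    active <- tb != 0
    expect_true(all(abs(g[!active]) <= lam + 1e-6))
    expect_equal(g[active], lam * sign(tb[active]), tolerance = 1e-5)
  }
})

test_that("solver solutions are coordinate-wise stationary for all families", {
  inst <- random_instance(n = 60, d = 5, seed = 15, theta = c(0, 2, -1, 0, 0, 0))
  data <- lq_data(inst$x, inst$y)
  for (fam in c("lasso", "scad", "mcp")) {
    p <- lq_path(data, penalty = fam, nlambda = 20)
    k <- 10
    tb <- p$coefs[-1, k] / sqrt(data$n)
    xt <- data$x * sqrt(data$n)
    r <- data$y - p$coefs[1, k] - drop(xt %*% tb)
    spec <- penalty_spec(fam, p$lambda[k], a = p$a, gamma = p$gamma)
    for (j in 1:5) {
      z <- sum(xt[, j] * r) / data$n + tb[j]
      expect_equal(threshold(z, spec), tb[j], tolerance = 1e-5)
    }
  }
})

test_that("orthonormal designs reduce to coordinate-wise thresholding", {
  withr::with_seed(16, {
    n <- 32; d <- 4
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * d), n, d))))[, -1] # orthogonal to 1
    x <- sweep(Q, 2, sqrt(colSums(Q^2)), "/")
    y <- rnorm(n) + drop(x %*% c(6, -4, 0, 0))
  })
  data <- lq_data(x, y)
  for (fam in c("lasso", "scad", "mcp")) {
    lam <- 0.2
    fit <- lq_fit(data, penalty = fam, lambda = lam)
    z <- drop(crossprod(data$x * sqrt(data$n), y - mean(y))) / data$n
    want <- threshold(z, penalty_spec(fam, lam)) * sqrt(data$n)
    expect_equal(unname(fit$coef[-1]), unname(want), tolerance = 1e-6)
  }
})

test_that("lambda = 0 recovers OLS (the MLqE) and small lambda approaches it", {
  inst <- random_instance(n = 100, d = 4, seed = 17, theta = c(1, 2, -2, 1, 0))
  data <- lq_data(inst$x, inst$y)
  ols <- unname(mlqe(data))
  for (fam in c("lasso", "mcp")) {
    fit <- lq_fit(data, penalty = fam, lambda = 0)
    expect_equal(unname(fit$coef), ols, tolerance = 1e-6)
  }
  # end of the default path (min_ratio 1e-3, n >> d), nonconvex families
  # carry no shrinkage bias at small lambda
  for (fam in c("mcp", "scad")) {
    p <- lq_path(data, penalty = fam, nlambda = 100)
    expect_equal(unname(p$coefs[, 100]), ols, tolerance = 1e-3)
  }
})

test_that("LASSO beats a brute-force grid on a 2-predictor instance", {
  withr::with_seed(18, {
    x <- matrix(rnorm(40), 20, 2)
    y <- rnorm(20)
  })
  data <- lq_data(x, y)
  lam <- 0.15
  fit <- lq_fit(data, penalty = "lasso", lambda = lam)
  objective <- function(b0, b1, b2) {
    tb <- c(b1, b2) / sqrt(data$n)
    sum((data$y - b0 - data$x %*% c(b1, b2))^2) / (2 * data$n) +
      lam * sum(abs(tb))
  }
  grid <- seq(-3, 3, by = 0.01)
  best <- Inf
  for (b1 in grid) {
    vals <- vapply(grid, function(b2) objective(mean(data$y), b1, b2),
                   numeric(1))
    best <- min(best, min(vals))
  }
  expect_lte(objective(fit$coef[1], fit$coef[2], fit$coef[3]), best + 1e-10)
})

test_that("paths are warm-started, continuous for LASSO, and fully recorded", {
  inst <- random_instance(n = 80, d = 6, seed = 19,
                          theta = c(0, 3, 2, -2, 0, 0, 0))
  p <- lq_path(inst$x, inst$y, penalty = "lasso", nlambda = 50)
  expect_length(p$lambda, 50)
  expect_identical(ncol(p$coefs), 50L)
  expect_true(all(p$converged))
  jumps <- apply(abs(diff(t(p$coefs))), 1, max)
  expect_lt(max(jumps), 1.5) # no oscillation between adjacent lambdas
})

test_that("the Lq objective equals penalized least squares after the lambda map", {
  inst <- random_instance(n = 40, d = 5, seed = 20, q = 2,
                          theta = c(0, 2, -2, 1, 0, 0))
  data <- lq_data(inst$x, inst$y)
  for (q in c(1, 3 / 2, 2, 2.5)) {
    s <- lq_loss_scale(q)
    expect_equal(map_lambda(1, q), (3 - q) / (2 * q_spec(q)$Zq^(q - 1)))
    for (lam in c(0.05, 0.3, 1)) {
      f_lq <- lq_fit(data, penalty = "lasso", lambda = lam, q = q,
                     objective = "lq")
      f_ls <- lq_fit(data, penalty = "lasso", lambda = map_lambda(lam, q))
      expect_equal(f_lq$coef, f_ls$coef, tolerance = 1e-8)
      # MCP needs the companion gamma rescaling gamma' = gamma * s
      m_lq <- lq_fit(data, penalty = "mcp", lambda = lam, q = q,
                     objective = "lq", gamma = 3)
      m_ls <- lq_fit(data, penalty = "mcp", lambda = lam / s, gamma = 3 * s)
      expect_equal(m_lq$coef, m_ls$coef, tolerance = 1e-8)
    }
  }
})

test_that("the Lq objective is what the solver actually minimizes", {
  # the loss term of the solver objective differs from -(1/n) Lq only by a
  # theta-free constant, computed here through lq_likelihood itself
  inst <- random_instance(n = 30, d = 3, seed = 21, q = 3 / 2)
  data <- lq_data(inst$x, inst$y)
  q <- 3 / 2
  s <- lq_loss_scale(q)
  th <- c(0.2, 1, -1, 0.5)
  rss <- sum((data$y - th[1] - drop(data$x %*% th[-1]))^2)
  spec <- q_spec(q)
  const <- data$n * (spec$Zq^(q - 1) - 1) / (1 - q) / data$n
  expect_equal(-lq_likelihood(th, data, q) / data$n,
               s * rss / (2 * data$n) - const, tolerance = 1e-10)
})
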