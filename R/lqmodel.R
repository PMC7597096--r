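#' Assemble a regression dataset for q-normal linear modelling
#'
#' Builds the container used by the fitting, selection and simulation
#' functions: a design matrix whose non-intercept columns are (by default)
#' centered and scaled to unit Euclidean norm
#' (\eqn{\sum_a x_{ia} = 0}, \eqn{\lVert x_i \rVert = 1}), the response,
#' and the transform record needed to map coefficients back to the input
#' scale. The intercept is implicit (a leading all-ones column in the
#' model) and never penalized.
#'
#' @param x Predictors: numeric matrix or data frame, n rows by d columns.
#' @param y Numeric response vector of length n.
#' @param standardize Center and unit-norm-scale the columns (default
#'   `TRUE`). With `FALSE` the columns are used as supplied; the
#'   standardization invariants are then the caller's responsibility.
#' @return An object of class `lq_data`: list with elements `x`
#'   (standardized n-by-d matrix), `y`, `n`, `d`, `center`, `scale`
#'   (centering constants and post-centering norms per column, identity
#'   when `standardize = FALSE`) and `standardized`.
#' @examples
#' d <- lq_data(matrix(rnorm(40), 10, 4), rnorm(10))
#' colSums(d$x)          # ~ 0
#' colSums(d$x^2)        # ~ 1
#' @export
lq_data <- function(x, y, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  d <- ncol(x)
  if (length(y) != n) stop("`x` and `y` must have matching rows", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(d))
  if (standardize) {
    center <- colMeans(x)
    xc <- sweep(x, 2L, center)
    scale <- sqrt(colSums(xc^2))
    if (any(scale <= .Machine$double.eps * n)) {
      bad <- colnames(x)[scale <= .Machine$double.eps * n]
      stop("zero-variance column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    x <- sweep(xc, 2L, scale, "/")
  } else {
    center <- rep(0, d)
    scale <- rep(1, d)
  }
  structure(
    list(x = x, y = y, n = n, d = d, center = center, scale = scale,
         standardized = standardize),
    class = "lq_data"
  )
}

#' @export
print.lq_data <- function(x, ...) {
  cat(sprintf("<lq_data> n = %d, d = %d, standardized = %s\n",
              x$n, x$d, x$standardized))
  invisible(x)
}

residuals_of <- function(theta, data) {
  data$y - (theta[1L] + drop(data$x %*% theta[-1L]))
}

check_theta <- function(theta, data) {
  theta <- as.numeric(theta)
  if (length(theta) != data$d + 1L) {
    stop("`theta` must have length d + 1 (intercept first)", call. = FALSE)
  }
  theta
}

#' Lq-likelihood of the q-normal linear model
#'
#' The Lq-likelihood \eqn{L_q(\theta \mid y) = \sum_a \log_q f_q(y_a \mid
#' x_a\theta, \sigma = 1)}, computed by direct summation of q-logarithms of
#' the q-normal density (dispersion fixed at 1). It is an affine,
#' decreasing function of the residual sum of squares with slope
#' \eqn{-Z_q^{q-1}/(3-q)}; at q = 1 it is the ordinary normal
#' log-likelihood.
#'
#' @param theta Coefficient vector of length d + 1, intercept first.
#' @param data An [lq_data()] object.
#' @param q Deformation parameter or [q_spec()] object.
#' @return Scalar Lq-likelihood value.
#' @seealso [log_likelihood()], [mlqe()].
#' @export
lq_likelihood <- function(theta, data, q = 1) {
  spec <- q_spec(q)
  theta <- check_theta(theta, data)
  r <- residuals_of(theta, data)
  sum(log_q(dqnormal(r, 0, 1, spec), spec$q))
}

#' Log-likelihood of the q-normal linear model
#'
#' \eqn{\sum_a \log f_q(y_a \mid x_a\theta, \sigma = 1)}: the normal
#' log-likelihood at q = 1 and the Student-t (\eqn{\nu = (3-q)/(q-1)})
#' error log-likelihood for q > 1. Used by the AIC/BIC criteria.
#'
#' @inheritParams lq_likelihood
#' @return Scalar log-likelihood value.
#' @export
log_likelihood <- function(theta, data, q = 1) {
  spec <- q_spec(q)
  theta <- check_theta(theta, data)
  r <- residuals_of(theta, data)
  if (spec$q == 1) {
    -sum(r^2) / 2 - data$n * log(spec$Zq)
  } else {
    -(spec$nu + 1) / 2 * sum(log1p(r^2 / spec$nu)) - data$n * log(spec$Zq)
  }
}

#' Maximum Lq-likelihood estimator
#'
#' For the q-normal linear model with known dispersion the maximizer of the
#' Lq-likelihood is the ordinary least-squares solution, for every q in
#' \[1, 3): the Lq-likelihood is a decreasing affine function of the
#' residual sum of squares. The estimate therefore does not depend on `q`.
#'
#' @param data An [lq_data()] object.
#' @param q Deformation parameter (accepted for interface symmetry;
#'   validated, does not affect the estimate).
#' @return Named coefficient vector of length d + 1, intercept first.
#' @export
mlqe <- function(data, q = 1) {
  q_spec(q)
  X <- cbind(`(Intercept)` = 1, data$x)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    stop("design matrix is rank deficient; MLqE is not unique", call. = FALSE)
  }
  stats::setNames(qr.coef(qr_X, data$y), colnames(X))
}

#' Submodel maximum likelihood estimate
#'
#' Maximizes the q-normal [log_likelihood()] over coefficients restricted
#' to a support (a set of slope indices; the intercept is always free). At
#' q = 1 this is ordinary least squares on the selected columns. For q > 1
#' it is a Student-t regression MLE computed by iteratively reweighted
#' least squares with weights \eqn{(\nu+1)/(\nu + r_a^2)}, initialized at
#' the OLS refit; the Cauchy case (q = 2), whose likelihood can be
#' multimodal, adds random restarts around the OLS fit and keeps the best
#' local maximum. The MLE is declared unavailable when IRLS does not
#' converge or the Hessian at the solution is not negative definite.
#'
#' @param data An [lq_data()] object.
#' @param support Integer vector of slope indices in 1..d with nonzero
#'   coefficients (may be empty for the intercept-only model).
#' @param q Deformation parameter or [q_spec()] object.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per IRLS step.
#' @param max_iter Maximum IRLS iterations.
#' @param restarts Random restarts used for q = 2.
#' @return List with elements `coef` (full-length d + 1 vector, zeros off
#'   the support), `loglik`, `available` (logical: MLE exists),
#'   `converged`, `iterations`.
#' @export
submodel_mle <- function(data, support, q = 1, tol = 1e-8, max_iter = 500L,
                         restarts = 5L) {
  spec <- q_spec(q)
  support <- sort(unique(as.integer(support)))
  if (length(support) && (min(support) < 1L || max(support) > data$d)) {
    stop("`support` indices must lie in 1..d", call. = FALSE)
  }
  if (length(support) + 1L > data$n) {
    stop("support larger than the sample size", call. = FALSE)
  }
  X <- cbind(1, data$x[, support, drop = FALSE])
  ols <- tryCatch(qr.solve(qr(X), data$y), error = function(e) NULL)
  if (is.null(ols)) {
    return(list(coef = NULL, loglik = NA_real_, available = FALSE,
                converged = FALSE, iterations = 0L))
  }
  full <- function(beta) {
    out <- numeric(data$d + 1L)
    out[1L] <- beta[1L]
    if (length(support)) out[support + 1L] <- beta[-1L]
    out
  }
  if (spec$q == 1) {
    cf <- full(ols)
    return(list(coef = cf, loglik = log_likelihood(cf, data, spec),
                available = TRUE, converged = TRUE, iterations = 0L))
  }
  starts <- list(ols)
  if (abs(spec$q - 2) < 1e-12 && restarts > 0L) {
    scale <- pmax(abs(ols), 0.5)
    for (i in seq_len(restarts)) {
      starts[[i + 1L]] <- ols + stats::rnorm(length(ols)) * scale * 0.5
    }
  }
  best <- NULL
  for (beta0 in starts) {
    fit <- t_irls(X, data$y, spec$nu, beta0, tol, max_iter)
    if (is.null(best) || fit$loglik_kernel > best$loglik_kernel) best <- fit
  }
  cf <- full(best$beta)
  available <- best$converged && hessian_negdef(X, data$y - drop(X %*% best$beta), spec$nu)
  list(coef = cf, loglik = log_likelihood(cf, data, spec),
       available = available, converged = best$converged,
       iterations = best$iterations)
}

# IRLS for t-regression with known scale 1; maximizes
# -((nu+1)/2) sum log(1 + r^2/nu) over beta.
t_irls <- function(X, y, nu, beta, tol, max_iter) {
  kernel <- function(b) {
    r <- y - drop(X %*% b)
    -(nu + 1) / 2 * sum(log1p(r^2 / nu))
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    w <- (nu + 1) / (nu + r^2)
    Xw <- X * w
    new_beta <- tryCatch(solve(crossprod(Xw, X), crossprod(Xw, y)),
                         error = function(e) NULL)
    if (is.null(new_beta)) break
    new_beta <- drop(new_beta)
    # step-halve if the reweighted update decreases the likelihood kernel
    if (kernel(new_beta) < kernel(beta)) {
      step <- 1
      repeat {
        step <- step / 2
        cand <- beta + step * (new_beta - beta)
        if (kernel(cand) >= kernel(beta) || step < 1e-8) {
          new_beta <- cand
          break
        }
      }
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged, iterations = it,
       loglik_kernel = kernel(beta))
}

# Hessian of the t log-likelihood at beta:
#  -(nu+1) * sum_a x_a x_a' (nu - r_a^2) / (nu + r_a^2)^2
hessian_negdef <- function(X, r, nu) {
  w <- (nu - r^2) / (nu + r^2)^2
  H <- -(nu + 1) * crossprod(X * w, X)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  all(ev < -1e-10 * max(1, abs(ev[1L])))
}
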