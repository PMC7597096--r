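family_code <- function(family) {
  match(family, c("lasso", "scad", "mcp")) - 1L
}

#' Loss-scale constant linking the Lq-likelihood and least-squares objectives
#'
#' Dropping constants, \eqn{-(1/n) L_q(\theta \mid y)} equals
#' \eqn{s \cdot \frac{1}{2n}\lVert y - X\theta \rVert^2} with
#' \eqn{s = 2 Z_q^{q-1} / (3-q)}; `lq_loss_scale()` returns \eqn{s} and
#' [map_lambda()] returns the equivalent least-squares regularization
#' parameter \eqn{\lambda' = \lambda / s = \lambda (3-q)/(2 Z_q^{q-1})}.
#' For the LASSO the Lq-penalized problem at \eqn{\lambda} and the
#' penalized least-squares problem at \eqn{\lambda'} have identical
#' minimizers; for MCP the same holds with \eqn{\gamma' = \gamma s}; SCAD
#' requires solving the scaled objective directly (see the `objective`
#' argument of [lq_path()]).
#'
#' @param q Deformation parameter or [q_spec()] object.
#' @return Scalar, \eqn{2 Z_q^{q-1} / (3-q)}; equal to 1 at q = 1.
#' @export
lq_loss_scale <- function(q) {
  spec <- q_spec(q)
  2 * spec$Zq^(spec$q - 1) / (3 - spec$q)
}

#' @param lambda Regularization parameter(s) on the Lq-likelihood scale.
#' @rdname lq_loss_scale
#' @export
map_lambda <- function(lambda, q) {
  lambda / lq_loss_scale(q)
}

#' Regularization parameter grid
#'
#' Log-spaced decreasing grid from \eqn{\lambda_{\max}} — the smallest
#' \eqn{\lambda} at which every penalty family keeps all slopes at zero
#' under the solver's convention (see [lq_path()]), i.e.
#' \eqn{\max_i |x_i^\top (y - \bar y)| / \sqrt{n}} for unit-norm columns
#' — down to `lambda_max * min_ratio`.
#'
#' @param data An [lq_data()] object.
#' @param nlambda Grid length (default 100).
#' @param min_ratio Ratio of the smallest to the largest lambda; defaults
#'   to 0.001 when n > d and 0.05 otherwise.
#' @return Numeric vector of strictly decreasing lambda values.
#' @export
lambda_grid <- function(data, nlambda = 100L, min_ratio = NULL) {
  stopifnot(inherits(data, "lq_data"))
  if (is.null(min_ratio)) min_ratio <- if (data$n > data$d) 0.001 else 0.05
  lam_max <- max(abs(crossprod(data$x, data$y - mean(data$y)))) / sqrt(data$n)
  if (lam_max <= 0) lam_max <- .Machine$double.eps
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = nlambda))
}

as_lq_data <- function(x, y, standardize) {
  if (inherits(x, "lq_data")) x else lq_data(x, y, standardize = standardize)
}

#' Penalized least-squares path by cyclic coordinate descent
#'
#' Solves, along a decreasing lambda grid with warm starts, the penalized
#' least-squares problem in the reference convention for coordinate
#' descent with nonconvex penalties: with \eqn{\tilde X = \sqrt{n} X}
#' (columns of squared norm \eqn{n} when the input columns are unit-norm)
#' and \eqn{\tilde\theta = \theta/\sqrt{n}},
#' \deqn{\min_{\tilde\theta} \; s \cdot \frac{1}{2n}
#'   \lVert y - \tilde X\tilde\theta \rVert^2 +
#'   \rho_\lambda(\tilde\theta).}
#' Under this scaling every coordinate update is the exact unit-curvature
#' scalar minimizer ([threshold()]) — soft thresholding for the LASSO and
#' the firm/clipped rules for MCP/SCAD — and all three families keep every
#' slope at zero at \eqn{\lambda_{\max}} ([lambda_grid()]).
#'
#' The loss scale \eqn{s} is 1 for `objective = "ls"` (classical penalized
#' least squares) and \eqn{2 Z_q^{q-1}/(3-q)} for `objective = "lq"`,
#' which makes the loss equal to \eqn{-(1/n) L_q(\theta \mid y)} up to an
#' additive constant — the Lq-likelihood-based regularization problem.
#' Since the two losses differ only by the positive factor \eqn{s}, the Lq
#' problem is a penalized least-squares problem with a rescaled penalty
#' (see [map_lambda()]); both are solved by the same coordinate-descent
#' core. The intercept is unpenalized. Reported coefficients are mapped
#' back to the unit-norm standardized scale (`coefs`) and to the input
#' scale (`coefs_original`).
#'
#' @param x Predictor matrix or data frame (or an [lq_data()] object, in
#'   which case `y` and `standardize` are ignored).
#' @param y Numeric response.
#' @param penalty Penalty family: `"lasso"`, `"scad"` or `"mcp"`.
#' @param lambda Optional user lambda vector (sorted decreasing); by
#'   default [lambda_grid()] is used.
#' @param nlambda,min_ratio Grid controls passed to [lambda_grid()].
#' @param a,gamma SCAD / MCP tuning constants (defaults 3.7 and 3).
#' @param q Deformation parameter (used when `objective = "lq"`).
#' @param objective `"ls"` (default) or `"lq"`, see above.
#' @param standardize Standardize columns (center, unit norm); default TRUE.
#' @param tol Convergence tolerance: maximum absolute coefficient change in
#'   a full sweep (default 1e-7).
#' @param max_iter Maximum sweeps per lambda (default 1e4).
#' @return Object of class `lq_path`: list with `lambda`, `coefs`
#'   ((d+1)-by-nlambda matrix on the standardized scale, intercept first),
#'   `coefs_original` (input scale), `converged`, `iterations`,
#'   `objective_value`, the penalty settings, and the `lq_data` used.
#' @seealso [lq_fit()] for a single lambda, [evaluate_path()] and
#'   [select_model()] for criterion-based selection, [autoplot.lq_path()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- x[, 1] * 2 + rnorm(50)
#' fit <- lq_path(x, y, penalty = "mcp")
#' dplyr::filter(tidy(fit), estimate != 0)
#' @export
lq_path <- function(x, y = NULL, penalty = c("lasso", "scad", "mcp"),
                    lambda = NULL, nlambda = 100L, min_ratio = NULL,
                    a = 3.7, gamma = 3, q = 1,
                    objective = c("ls", "lq"), standardize = TRUE,
                    tol = 1e-7, max_iter = 10000L) {
  penalty <- match.arg(penalty)
  objective <- match.arg(objective)
  data <- as_lq_data(x, y, standardize)
  penalty_spec(penalty, lambda = 0, a = a, gamma = gamma) # validate constants
  if (is.null(lambda)) {
    lambda <- lambda_grid(data, nlambda = nlambda, min_ratio = min_ratio)
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  s <- if (objective == "lq") lq_loss_scale(q) else 1
  res <- cd_path(data$x * sqrt(data$n), data$y, family_code(penalty), lambda,
                 a, gamma, s, tol, as.integer(max_iter), numeric(0))
  coefs <- res$coefs
  coefs[-1L, ] <- coefs[-1L, , drop = FALSE] * sqrt(data$n)
  rownames(coefs) <- c("(Intercept)", colnames(data$x))
  structure(
    list(lambda = lambda, coefs = coefs,
         coefs_original = destandardize_coefs(coefs, data),
         converged = as.logical(res$converged),
         iterations = as.integer(res$iterations),
         objective_value = as.numeric(res$objective),
         penalty = penalty, a = a, gamma = gamma, q = q,
         objective = objective, loss_scale = s, data = data),
    class = "lq_path"
  )
}

# Map standardized-scale coefficients (intercept first) to the input scale.
destandardize_coefs <- function(coefs, data) {
  out <- coefs
  out[-1L, ] <- coefs[-1L, , drop = FALSE] / data$scale
  out[1L, ] <- coefs[1L, ] - colSums(coefs[-1L, , drop = FALSE] * data$center / data$scale)
  out
}

#' Penalized least-squares fit at a single lambda
#'
#' Single-lambda convenience wrapper around the coordinate-descent core;
#' see [lq_path()] for the objective. At `lambda = 0` the fit is the
#' ordinary least-squares solution, which is also the maximum
#' Lq-likelihood estimate for every q.
#'
#' @inheritParams lq_path
#' @param lambda Single nonnegative regularization parameter.
#' @return Object of class `lq_fit`: list with `coef` (standardized scale,
#'   intercept first), `coef_original`, `lambda`, penalty settings,
#'   `converged`, `objective_value`, and the `lq_data` used.
#' @export
lq_fit <- function(x, y = NULL, penalty = c("lasso", "scad", "mcp"),
                   lambda, a = 3.7, gamma = 3, q = 1,
                   objective = c("ls", "lq"), standardize = TRUE,
                   tol = 1e-7, max_iter = 10000L) {
  penalty <- match.arg(penalty)
  objective <- match.arg(objective)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  data <- as_lq_data(x, y, standardize)
  # warm-start through a short geometric ramp for the nonconvex families
  lam_seq <- if (lambda > 0 && penalty != "lasso") {
    lam_max <- max(lambda_grid(data, nlambda = 2L), lambda)
    unique(sort(c(exp(seq(log(lam_max), log(max(lambda, 1e-12)),
                          length.out = 20L)), lambda), decreasing = TRUE))
  } else {
    lambda
  }
  path <- lq_path(data, penalty = penalty, lambda = lam_seq, a = a,
                  gamma = gamma, q = q, objective = objective,
                  tol = tol, max_iter = max_iter)
  k <- which.min(abs(path$lambda - lambda))
  structure(
    list(coef = path$coefs[, k], coef_original = path$coefs_original[, k],
         lambda = lambda, penalty = penalty, a = a, gamma = gamma, q = q,
         objective = objective, loss_scale = path$loss_scale,
         converged = path$converged[k],
         objective_value = path$objective_value[k], data = data),
    class = "lq_fit"
  )
}

#' @export
coef.lq_fit <- function(object, original = TRUE, ...) {
  if (original) object$coef_original else object$coef
}

#' @export
coef.lq_path <- function(object, original = TRUE, ...) {
  if (original) object$coefs_original else object$coefs
}

#' @export
predict.lq_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  cf <- object$coef_original
  drop(cf[1L] + newx %*% cf[-1L])
}

#' @export
predict.lq_path <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  cf <- object$coefs_original
  sweep(newx %*% cf[-1L, , drop = FALSE], 2L, cf[1L, ], "+")
}

#' @export
print.lq_path <- function(x, ...) {
  cat(sprintf("<lq_path> %s path, %d lambdas in [%.4g, %.4g], n = %d, d = %d\n",
              x$penalty, length(x$lambda), min(x$lambda), max(x$lambda),
              x$data$n, x$data$d))
  if (x$objective == "lq") {
    cat(sprintf("  Lq objective, q = %g (loss scale %.4g)\n", x$q, x$loss_scale))
  }
  invisible(x)
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit> %s, lambda = %.4g, %d nonzero slope(s)\n",
              x$penalty, x$lambda, sum(x$coef[-1L] != 0)))
  invisible(x)
}

#' Nonzero-slope support of a coefficient vector
#'
#' @param coefs Coefficient vector (intercept first) or an `lq_fit`.
#' @return Sorted integer vector of slope indices with nonzero estimates.
#' @export
support_of <- function(coefs) {
  if (inherits(coefs, "lq_fit")) coefs <- coefs$coef
  which(coefs[-1L] != 0)
}
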