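#' Penalty specification
#'
#' Describes one of the three supported sparsity penalties together with its
#' regularization parameter and tuning constants:
#' \describe{
#'   \item{lasso}{\eqn{\rho_\lambda(\theta) = \lambda \sum_i |\theta_i|}.}
#'   \item{scad}{the smoothly clipped absolute deviation penalty:
#'     \eqn{\lambda|\theta_i|} for \eqn{|\theta_i| \le \lambda},
#'     \eqn{-(|\theta_i|^2 - 2a\lambda|\theta_i| + \lambda^2)/(2(a-1))}
#'     for \eqn{\lambda < |\theta_i| \le a\lambda}, and the constant
#'     \eqn{(a+1)\lambda^2/2} beyond.}
#'   \item{mcp}{the minimax concave penalty
#'     \eqn{\lambda \int_0^{|\theta_i|} (1 - u/(\gamma\lambda))_+ \, du},
#'     i.e. \eqn{\lambda|\theta_i| - \theta_i^2/(2\gamma)} up to
#'     \eqn{\gamma\lambda} and the constant \eqn{\gamma\lambda^2/2} beyond.}
#' }
#' The defaults a = 3.7 and gamma = 3 are the conventional choices. `a > 2`
#' and `gamma > 1` are required so the unit-curvature scalar thresholding
#' problem has a unique minimizer.
#'
#' @param family One of `"lasso"`, `"scad"`, `"mcp"`.
#' @param lambda Regularization parameter, \eqn{\lambda \ge 0}.
#' @param a SCAD tuning constant (> 2).
#' @param gamma MCP tuning constant (> 1).
#' @return Object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("lasso", "scad", "mcp"), lambda,
                         a = 3.7, gamma = 3) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single nonnegative number", call. = FALSE)
  }
  if (family == "scad" && a <= 2) {
    stop("SCAD requires `a` > 2", call. = FALSE)
  }
  if (family == "mcp" && gamma <= 1) {
    stop("MCP requires `gamma` > 1 for a unique scalar minimizer",
         call. = FALSE)
  }
  structure(list(family = family, lambda = lambda, a = a, gamma = gamma),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  extra <- switch(x$family, scad = sprintf(", a = %g", x$a),
                  mcp = sprintf(", gamma = %g", x$gamma), "")
  cat(sprintf("<penalty_spec> %s, lambda = %g%s\n", x$family, x$lambda, extra))
  invisible(x)
}

#' Penalty value on a slope vector
#'
#' Separable sum of the penalty over the slope coordinates (the intercept
#' is never penalized and is not part of the input).
#'
#' @param slopes Numeric vector of slope coefficients.
#' @param spec A [penalty_spec()].
#' @return Nonnegative scalar penalty value.
#' @examples
#' penalty_value(c(0.5, -2), penalty_spec("lasso", lambda = 1)) # 2.5
#' @export
penalty_value <- function(slopes, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  t <- abs(slopes)
  lam <- spec$lambda
  v <- switch(
    spec$family,
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
  sum(v)
}

#' Scalar thresholding (proximal) operator
#'
#' Exact minimizer over \eqn{\theta} of the unit-curvature scalar problem
#' \deqn{\tfrac12 (z - \theta)^2 + \rho_\lambda(\theta),}
#' the kernel of the coordinate-descent update under unit-norm design
#' columns: soft thresholding for the LASSO and the firm/clipped rules for
#' MCP and SCAD. Odd in `z`; never increases magnitude; identity at
#' \eqn{\lambda = 0}.
#'
#' @param z Numeric vector of inputs.
#' @param spec A [penalty_spec()].
#' @param kappa Curvature of the quadratic term: minimizes
#'   \eqn{(\kappa/2)(z-\theta)^2 + \rho_\lambda(\theta)}. The default 1 is
#'   the classical operator; the path solver uses \eqn{\kappa = s/n}. When
#'   the scalar problem is nonconvex (small `kappa` with SCAD/MCP) the
#'   exact global minimizer is still returned, with ties broken toward the
#'   smaller magnitude.
#' @return Numeric vector of thresholded values.
#' @examples
#' threshold(3, penalty_spec("lasso", 1))          # 2
#' threshold(3, penalty_spec("scad", 1, a = 3.7))  # 2.588...
#' threshold(2, penalty_spec("mcp", 1, gamma = 3)) # 1.5
#' @export
threshold <- function(z, spec, kappa = 1) {
  stopifnot(inherits(spec, "penalty_spec"), kappa > 0)
  vapply(z, threshold1, numeric(1L), spec = spec, kappa = kappa)
}

threshold1 <- function(z, spec, kappa) {
  s <- sign(z)
  z <- abs(z)
  lam <- spec$lambda
  if (lam == 0) return(s * z)
  obj <- function(t) kappa / 2 * (t - z)^2 + penalty_value(t, spec)
  cand <- switch(
    spec$family,
    lasso = max(0, z - lam / kappa),
    scad = {
      a <- spec$a
      cs <- c(0, min(max(z - lam / kappa, 0), lam), lam, a * lam)
      k2 <- kappa - 1 / (a - 1) # curvature of the middle branch
      if (k2 > 0) {
        cs <- c(cs, min(max((kappa * z - a * lam / (a - 1)) / k2, lam), a * lam))
      }
      if (z > a * lam) cs <- c(cs, z)
      cs
    },
    mcp = {
      g <- spec$gamma
      cs <- c(0, g * lam)
      k1 <- kappa - 1 / g
      if (k1 > 0) cs <- c(cs, min(max((kappa * z - lam) / k1, 0), g * lam))
      if (z > g * lam) cs <- c(cs, z)
      cs
    }
  )
  vals <- vapply(cand, obj, numeric(1L))
  best <- min(vals)
  # ties (within numerical noise) resolve to the sparser, smaller-|theta| root
  s * min(cand[vals <= best + 1e-12 * max(1, best)])
}
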