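#' q-deformed logarithm
#'
#' The q-logarithm \eqn{\log_q(u) = (u^{1-q} - 1)/(1-q)} for \eqn{q \ne 1},
#' reducing to the natural logarithm at \eqn{q = 1}. It is the deformation of
#' the logarithm underlying both the Lq-likelihood and the q-normal
#' distribution family.
#'
#' @param u Positive numeric vector.
#' @param q Deformation parameter, \eqn{1 \le q < 3}.
#' @return Numeric vector, `log_q(u)`.
#' @seealso [exp_q()] for the inverse, [lq_likelihood()].
#' @examples
#' log_q(2, q = 2)      # 0.5
#' log_q(exp(1), q = 1) # 1
#' @export
log_q <- function(u, q) {
  check_q(q)
  if (any(!is.finite(u)) || any(u <= 0)) {
    stop("`u` must be positive and finite", call. = FALSE)
  }
  if (abs(q - 1) < 1e-10) {
    log(u)
  } else {
    (u^(1 - q) - 1) / (1 - q)
  }
}

#' q-deformed exponential
#'
#' The q-exponential \eqn{\exp_q(u) = \{1 + (1-q)u\}^{1/(1-q)}}, the inverse
#' of [log_q()] on its domain; the ordinary exponential at \eqn{q = 1}. For
#' \eqn{q > 1} the argument must satisfy \eqn{1 + (1-q)u > 0}, i.e.
#' \eqn{u < 1/(q-1)}.
#'
#' @inheritParams log_q
#' @param u Numeric vector inside the q-exponential domain.
#' @return Numeric vector, `exp_q(u)`.
#' @examples
#' exp_q(0, q = 2)                 # 1
#' exp_q(log_q(5, q = 1.5), 1.5)   # 5
#' @export
exp_q <- function(u, q) {
  check_q(q)
  if (abs(q - 1) < 1e-10) {
    return(exp(u))
  }
  base <- 1 + (1 - q) * u
  if (any(base <= 0)) {
    stop("argument outside the q-exponential domain (needs 1 + (1-q)u > 0)",
         call. = FALSE)
  }
  base^(1 / (1 - q))
}

#' Degrees of freedom of the Student-t representation of a q-normal law
#'
#' For \eqn{1 < q < 3} the unit-dispersion q-normal distribution is the
#' Student-t distribution with \eqn{\nu = (3-q)/(q-1)} degrees of freedom;
#' equivalently \eqn{q = 1 + 2/(\nu+1)}. `q = 2` gives the Cauchy
#' distribution (\eqn{\nu = 1}).
#'
#' @param q Numeric vector with \eqn{1 < q < 3}.
#' @return Degrees of freedom \eqn{\nu > 0}.
#' @examples
#' nu_of_q(13 / 11) # 10
#' nu_of_q(3 / 2)   # 3
#' nu_of_q(2)       # 1 (Cauchy)
#' @export
nu_of_q <- function(q) {
  if (any(q <= 1) || any(q >= 3)) {
    stop("`q` must satisfy 1 < q < 3", call. = FALSE)
  }
  (3 - q) / (q - 1)
}

#' q-normal distribution specification
#'
#' Bundles the deformation parameter `q` with its derived quantities: the
#' Student-t degrees of freedom `nu` (`Inf` at q = 1) and the normalizing
#' constant `Zq` of the unit-dispersion q-normal density,
#' \eqn{Z_q = \sqrt{2\pi}} at q = 1 and
#' \eqn{Z_q = \sqrt{\nu}\,B(\nu/2, 1/2)} for \eqn{1 < q < 3}.
#'
#' @param q Deformation parameter, \eqn{1 \le q < 3}. q = 1 is the normal
#'   distribution, q = 2 the Cauchy; generally \eqn{q = 1 + 2/(\nu+1)} is
#'   Student-t with \eqn{\nu} degrees of freedom.
#' @return An object of class `q_spec`: list with elements `q`, `nu`, `Zq`.
#' @examples
#' q_spec(2)$Zq # pi (Cauchy normalizer)
#' @export
q_spec <- function(q) {
  if (inherits(q, "q_spec")) return(q)
  check_q(q)
  if (abs(q - 1) < 1e-10) {
    spec <- list(q = 1, nu = Inf, Zq = sqrt(2 * pi))
  } else {
    nu <- nu_of_q(q)
    spec <- list(q = q, nu = nu, Zq = sqrt(nu) * beta(nu / 2, 1 / 2))
  }
  structure(spec, class = "q_spec")
}

#' @export
print.q_spec <- function(x, ...) {
  cat(sprintf("q-normal spec: q = %g, nu = %g, Zq = %g\n", x$q, x$nu, x$Zq))
  invisible(x)
}

check_q <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 1 || q >= 3) {
    stop("`q` must be a single number in [1, 3)", call. = FALSE)
  }
  invisible(q)
}

#' q-normal density
#'
#' Density of the q-normal distribution with location `xi` and dispersion
#' `sigma`,
#' \deqn{f_q(y \mid \xi, \sigma) = \frac{1}{\sigma Z_q}
#'   \exp_q\!\left(-\frac{1}{3-q}\Big(\frac{y-\xi}{\sigma}\Big)^2\right),}
#' the normal density at q = 1 and the Student-t density with
#' \eqn{\nu = (3-q)/(q-1)} degrees of freedom (scaled by `sigma`) for
#' \eqn{1 < q < 3}.
#'
#' @param y Numeric vector of evaluation points.
#' @param xi Location parameter.
#' @param sigma Dispersion parameter, positive.
#' @param q Deformation parameter or a [q_spec()] object.
#' @return Numeric vector of density values.
#' @examples
#' dqnormal(0, q = 2) # 1/pi, the standard Cauchy density at 0
#' @export
dqnormal <- function(y, xi = 0, sigma = 1, q = 1) {
  spec <- q_spec(q)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  u <- (y - xi) / sigma
  if (spec$q == 1) {
    exp(-u^2 / 2) / (sigma * spec$Zq)
  } else {
    # exp_q(-u^2/(3-q)) = (1 + u^2/nu)^(-(nu+1)/2), always in-domain for q>1
    (1 + u^2 / spec$nu)^(-(spec$nu + 1) / 2) / (sigma * spec$Zq)
  }
}

#' Sample from a q-normal distribution
#'
#' Draws i.i.d. variates as \eqn{\xi + \sigma T}, with \eqn{T} standard
#' normal at q = 1 and Student-t with \eqn{\nu = (3-q)/(q-1)} degrees of
#' freedom for q > 1 — the exact distributional equivalence, not an
#' approximate generalized Box-Muller scheme.
#'
#' @inheritParams dqnormal
#' @param n Number of draws.
#' @param seed Optional integer seed applied locally (the caller's RNG
#'   state is restored on exit).
#' @return Numeric vector of length `n`.
#' @export
rqnormal <- function(n, xi = 0, sigma = 1, q = 1, seed = NULL) {
  spec <- q_spec(q)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  t <- if (spec$q == 1) stats::rnorm(n) else stats::rt(n, df = spec$nu)
  xi + sigma * t
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
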