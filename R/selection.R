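#' Information criteria
#'
#' Deviance-form criteria: \eqn{\mathrm{AIC} = -2\log p(y\mid\hat\theta) +
#' 2d'}, \eqn{\mathrm{BIC} = -2\log p(y\mid\hat\theta) + d'\log n}, and
#' their Lq-likelihood analogues \eqn{L_q\mathrm{-AIC} = -2 L_q + 2d'},
#' \eqn{L_q\mathrm{-BIC} = -2 L_q + d'\log n}. `d_prime` is the dimension
#' of the submodel: nonzero slopes plus the intercept (dispersion is
#' known). Smaller is better. At q = 1 the Lq criteria coincide with the
#' ordinary ones.
#'
#' @param loglik Log-likelihood at the evaluated estimate.
#' @param lqlik Lq-likelihood at the evaluated estimate.
#' @param d_prime Number of free parameters of the submodel.
#' @param n Sample size.
#' @return Scalar criterion value.
#' @name information-criteria
NULL

#' @rdname information-criteria
#' @export
aic <- function(loglik, d_prime) -2 * loglik + 2 * d_prime

#' @rdname information-criteria
#' @export
bic <- function(loglik, d_prime, n) -2 * loglik + d_prime * log(n)

#' @rdname information-criteria
#' @export
lq_aic <- function(lqlik, d_prime) -2 * lqlik + 2 * d_prime

#' @rdname information-criteria
#' @export
lq_bic <- function(lqlik, d_prime, n) -2 * lqlik + d_prime * log(n)

lq_criteria <- c("AIC1", "AIC2", "BIC1", "BIC2",
                 "LqAIC1", "LqAIC2", "LqBIC1", "LqBIC2")

# Likelihood pieces for all path points at once. q-normal, sigma = 1.
path_likelihoods <- function(coefs, data, spec) {
  resid <- data$y - sweep(data$x %*% coefs[-1L, , drop = FALSE], 2L,
                          -coefs[1L, ])
  rss <- colSums(resid^2)
  if (spec$q == 1) {
    loglik <- -rss / 2 - data$n * log(spec$Zq)
    lqlik <- loglik
  } else {
    loglik <- -(spec$nu + 1) / 2 * colSums(log1p(resid^2 / spec$nu)) -
      data$n * log(spec$Zq)
    # Lq-likelihood is affine in the RSS (Eq.-6 summation in closed form)
    zpow <- spec$Zq^(spec$q - 1)
    lqlik <- -zpow / (3 - spec$q) * rss + data$n * (zpow - 1) / (1 - spec$q)
  }
  list(loglik = loglik, lqlik = lqlik)
}

#' Evaluate information criteria along a regularization path
#'
#' For every path point \eqn{\hat\theta^{(k)}} the support
#' \eqn{I(k) = \{i : \hat\theta^{(k)}_i \ne 0\}} is extracted and each
#' requested criterion is computed in two variants: the "2" variants plug
#' in the path estimate itself; the "1" variants plug in the maximum
#' likelihood refit of the submodel with that support
#' ([submodel_mle()]), and are marked unavailable when that MLE does not
#' exist. Duplicate supports along the path are refit once.
#'
#' @param path An [lq_path()] fit.
#' @param q Deformation parameter of the assumed q-normal error law used
#'   in the likelihoods (defaults to the path's `q`).
#' @param criteria Character vector among `"AIC1"`, `"AIC2"`, `"BIC1"`,
#'   `"BIC2"`, `"LqAIC1"`, `"LqAIC2"`, `"LqBIC1"`, `"LqBIC2"`.
#' @return Tibble with columns `index`, `lambda`, `criterion`, `value`,
#'   `d_prime`, `available`.
#' @seealso [select_model()]
#' @export
evaluate_path <- function(path, q = path$q, criteria = lq_criteria) {
  stopifnot(inherits(path, "lq_path"))
  criteria <- match.arg(criteria, lq_criteria, several.ok = TRUE)
  spec <- q_spec(q)
  data <- path$data
  nlam <- length(path$lambda)
  supports <- lapply(seq_len(nlam), function(k) unname(which(path$coefs[-1L, k] != 0)))
  d_prime <- lengths(supports) + 1L
  need1 <- any(grepl("1$", criteria))
  need2 <- any(grepl("2$", criteria))

  lik2 <- if (need2) path_likelihoods(path$coefs, data, spec)
  refit <- NULL
  if (need1) {
    keys <- vapply(supports, function(s) paste0("s", paste(s, collapse = ",")),
                   character(1L))
    uniq <- !duplicated(keys)
    cache <- new.env(parent = emptyenv())
    for (k in which(uniq)) {
      fit <- submodel_mle(data, supports[[k]], spec)
      lq <- if (fit$available) lq_likelihood(fit$coef, data, spec) else NA_real_
      assign(keys[k], list(loglik = fit$loglik, lqlik = lq,
                           available = fit$available), envir = cache)
    }
    refit <- lapply(keys, get, envir = cache)
  }

  rows <- lapply(criteria, function(cr) {
    ic1 <- grepl("1$", cr)
    uses_lq <- grepl("^Lq", cr)
    is_aic <- grepl("AIC", cr)
    if (ic1) {
      lik <- vapply(refit, function(f) if (uses_lq) f$lqlik else f$loglik,
                    numeric(1L))
      avail <- vapply(refit, `[[`, logical(1L), "available")
    } else {
      lik <- if (uses_lq) lik2$lqlik else lik2$loglik
      avail <- rep(TRUE, nlam)
    }
    value <- if (is_aic) -2 * lik + 2 * d_prime
             else -2 * lik + d_prime * log(data$n)
    tibble::tibble(index = seq_len(nlam), lambda = path$lambda,
                   criterion = cr, value = value, d_prime = d_prime,
                   available = avail)
  })
  dplyr::bind_rows(rows)
}

#' Select a model from a criterion table
#'
#' Picks the path index minimizing the chosen criterion over its available
#' entries; ties are broken toward the larger lambda (sparser model).
#'
#' @param values Criterion table from [evaluate_path()].
#' @param criterion Single criterion name present in `values`.
#' @param path Optional [lq_path()]; when supplied the selected support
#'   and coefficients are attached.
#' @return List with `index`, `lambda`, `value`, `d_prime`, and (given
#'   `path`) `support` and `coef`.
#' @export
select_model <- function(values, criterion, path = NULL) {
  tab <- values[values$criterion == criterion & values$available, ]
  if (nrow(tab) == 0L) {
    stop("criterion '", criterion, "' has no available entries", call. = FALSE)
  }
  # lambda grid is decreasing in index, so the first minimum is the sparser one
  tab <- tab[order(tab$index), ]
  k <- tab$index[which.min(tab$value)]
  out <- list(index = k, lambda = values$lambda[match(k, values$index)],
              value = min(tab$value),
              d_prime = tab$d_prime[match(k, tab$index)])
  if (!is.null(path)) {
    out$support <- unname(which(path$coefs[-1L, k] != 0))
    out$coef <- path$coefs[, k]
    out$coef_original <- path$coefs_original[, k]
  }
  out
}

#' K-fold cross-validation for the penalized fit
#'
#' Splits the sample into K contiguous blocks after a seeded random
#' permutation, fits the path on each training set over a common lambda
#' grid (computed on the full data), and scores held-out squared
#' prediction error. The reported curve is the mean over folds of the
#' per-fold mean squared error; the chosen lambda is its minimizer. Note
#' that squared-error CV has unstable means under very heavy tails
#' (q at or above 2, infinite error variance).
#'
#' @inheritParams lq_path
#' @param K Number of folds (default 10).
#' @param seed Optional integer seed for the fold permutation (applied
#'   locally).
#' @return Object of class `lq_cv`: list with `table` (tibble: `lambda`,
#'   `cv_error`, `cv_se`, `nfolds_used`), `lambda_min`, `index_min`, and
#'   the settings.
#' @export
cv_lq <- function(x, y = NULL, penalty = c("lasso", "scad", "mcp"), K = 10L,
                  seed = NULL, lambda = NULL, nlambda = 100L,
                  min_ratio = NULL, a = 3.7, gamma = 3,
                  standardize = TRUE) {
  penalty <- match.arg(penalty)
  if (inherits(x, "lq_data")) {
    y <- x$y
    x <- x$x
    standardize <- TRUE
  }
  x <- as.matrix(x)
  n <- nrow(x)
  K <- as.integer(K)
  if (K < 2L || K > n) stop("need 2 <= K <= n folds", call. = FALSE)
  full <- lq_data(x, y, standardize = standardize)
  if (is.null(lambda)) {
    lambda <- lambda_grid(full, nlambda = nlambda, min_ratio = min_ratio)
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  perm <- sample.int(n)
  fold_id <- rep(seq_len(K), length.out = n)[order(perm)]
  errs <- matrix(NA_real_, K, length(lambda))
  for (f in seq_len(K)) {
    test <- fold_id == f
    fit <- tryCatch(
      lq_path(x[!test, , drop = FALSE], y[!test], penalty = penalty,
              lambda = lambda, a = a, gamma = gamma,
              standardize = standardize),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning("fold ", f, " skipped (degenerate design)", call. = FALSE)
      next
    }
    pred <- predict(fit, x[test, , drop = FALSE])
    errs[f, ] <- colMeans((y[test] - pred)^2)
  }
  used <- !is.na(errs[, 1L])
  if (!any(used)) stop("all folds degenerate", call. = FALSE)
  cv_err <- colMeans(errs[used, , drop = FALSE])
  cv_se <- apply(errs[used, , drop = FALSE], 2L, stats::sd) / sqrt(sum(used))
  k <- which.min(cv_err)
  structure(
    list(table = tibble::tibble(lambda = lambda, cv_error = cv_err,
                                cv_se = cv_se, nfolds_used = sum(used)),
         lambda_min = lambda[k], index_min = k, cv_min = cv_err[k],
         penalty = penalty, K = K, a = a, gamma = gamma),
    class = "lq_cv"
  )
}

#' @export
print.lq_cv <- function(x, ...) {
  cat(sprintf("<lq_cv> %s, %d-fold: lambda_min = %.4g (cv error %.4g)\n",
              x$penalty, x$K, x$lambda_min, x$cv_min))
  invisible(x)
}
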