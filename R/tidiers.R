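#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a single-lambda fit
#'
#' @param x An [lq_fit()] object.
#' @param original Report coefficients on the input scale (default) or the
#'   standardized scale.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.lq_fit <- function(x, original = TRUE, ...) {
  cf <- if (original) x$coef_original else x$coef
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' @export
glance.lq_fit <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, lambda = x$lambda,
                 n_nonzero = sum(x$coef[-1L] != 0),
                 objective = x$objective_value, converged = x$converged,
                 n = x$data$n, d = x$data$d)
}

#' Tidy a regularization path
#'
#' @param x An [lq_path()] object.
#' @param original Report coefficients on the input scale (default).
#' @param ... Unused.
#' @return Tibble with columns `index`, `lambda`, `term`, `estimate`.
#' @export
tidy.lq_path <- function(x, original = TRUE, ...) {
  cf <- if (original) x$coefs_original else x$coefs
  tibble::tibble(
    index = rep(seq_along(x$lambda), each = nrow(cf)),
    lambda = rep(x$lambda, each = nrow(cf)),
    term = rep(rownames(cf), times = length(x$lambda)),
    estimate = as.vector(cf)
  )
}

#' @export
glance.lq_path <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, nlambda = length(x$lambda),
                 lambda_max = max(x$lambda), lambda_min = min(x$lambda),
                 all_converged = all(x$converged), n = x$data$n, d = x$data$d)
}

#' @export
tidy.lq_cv <- function(x, ...) x$table

#' @export
glance.lq_cv <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, K = x$K, lambda_min = x$lambda_min,
                 cv_min = x$cv_min)
}

#' @export
tidy.lq_experiment <- function(x, ...) x$summary

#' @export
glance.lq_experiment <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(q = cfg$q, n = cfg$n, d = cfg$d, rnz = cfg$rnz,
                 theta_star = cfg$theta_star, m = cfg$m,
                 best_recovery = max(x$summary$recovery_count))
}

#' Coefficient-path plot
#'
#' One line per slope against log10(lambda); the intercept is omitted.
#'
#' @param object An [lq_path()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lq_path <- function(object, ...) {
  df <- tidy(object, original = FALSE)
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$lambda),
                                   y = .data$estimate,
                                   group = .data$term,
                                   colour = .data$term)) +
    ggplot2::geom_line(show.legend = object$data$d <= 12) +
    ggplot2::labs(x = expression(log[10](lambda)), y = "coefficient",
                  title = sprintf("%s path", object$penalty)) +
    ggplot2::theme_minimal()
}

#' Cross-validation curve plot
#'
#' @param object An [cv_lq()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lq_cv <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$lambda),
                                   y = .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = log10(object$lambda_min),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log[10](lambda)), y = "CV squared error",
                  title = sprintf("%d-fold CV, %s", object$K,
                                  object$penalty)) +
    ggplot2::theme_minimal()
}

#' Experiment summary plot
#'
#' Bar chart of exact-recovery counts (or generalization error) per
#' penalty and criterion, mirroring the style of the study's figures.
#'
#' @param object An [run_experiment()] result.
#' @param metric `"recovery_count"`, `"mean_mse"`, or any summary column.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lq_experiment <- function(object, metric = "recovery_count", ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion,
                                   y = .data[[metric]],
                                   fill = .data$penalty)) +
    ggplot2::geom_col(position = "dodge", colour = "black") +
    ggplot2::scale_fill_manual(values = c(lasso = "white", scad = "grey70",
                                          mcp = "black")) +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("q = %g, n = %d, d = %d, rnz = %g, theta* = %g",
                                  object$config$q, object$config$n,
                                  object$config$d, object$config$rnz,
                                  object$config$theta_star)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib lqreg, .registration = TRUE
NULL
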