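#' Generate a standardized Gaussian design matrix
#'
#' Entries are i.i.d. standard normal, then each column is centered and
#' scaled to unit Euclidean norm — the standing standardization of the
#' model (\eqn{\sum_a x_{ia} = 0}, \eqn{\lVert x_i \rVert = 1}).
#'
#' @param n Sample size.
#' @param d Number of explanatory variables.
#' @param seed Optional integer seed (applied locally).
#' @return An n-by-d standardized matrix.
#' @export
gen_design <- function(n, d, seed = NULL) {
  if (n <= d) warning("n <= d: design columns cannot be linearly independent",
                      call. = FALSE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  x <- matrix(stats::rnorm(n * d), n, d)
  xc <- sweep(x, 2L, colMeans(x))
  sweep(xc, 2L, sqrt(colSums(xc^2)), "/")
}

#' True sparse coefficient vector
#'
#' The first `d * rnz` slopes equal `theta_star`, the rest are zero, and
#' the intercept is zero. With an exchangeable standardized Gaussian
#' design the position of the nonzeros is immaterial.
#'
#' @param d Number of slopes.
#' @param rnz Ratio of nonzero slopes; `d * rnz` must be whole.
#' @param theta_star Common magnitude of the nonzero slopes.
#' @return Coefficient vector of length d + 1, intercept first.
#' @examples
#' gen_true_theta(10, 0.2, 10) # intercept 0, slopes 10,10,0,...,0
#' @export
gen_true_theta <- function(d, rnz, theta_star) {
  k <- d * rnz
  if (abs(k - round(k)) > 1e-8) stop("d * rnz must be a whole number",
                                     call. = FALSE)
  k <- as.integer(round(k))
  c(0, rep(theta_star, k), rep(0, d - k))
}

#' Generate responses under the q-normal linear model
#'
#' \eqn{y_a = \theta_0 + x_a\theta + \varepsilon_a} with i.i.d. q-normal
#' errors of unit dispersion (normal at q = 1, Student-t with
#' \eqn{\nu = (3-q)/(q-1)} otherwise).
#'
#' @param x Design matrix (n by d).
#' @param theta True coefficient vector, length d + 1, intercept first.
#' @param q Deformation parameter or [q_spec()].
#' @param seed Optional integer seed (applied locally).
#' @return Numeric response vector of length n.
#' @export
gen_response <- function(x, theta, q = 1, seed = NULL) {
  x <- as.matrix(x)
  stopifnot(length(theta) == ncol(x) + 1L)
  eps <- rqnormal(nrow(x), 0, 1, q, seed = seed)
  theta[1L] + drop(x %*% theta[-1L]) + eps
}

#' Simulation experiment configuration
#'
#' Bundles one cell of the simulation design: the error deformation `q`,
#' sample size `n`, dimension `d`, nonzero ratio `rnz`, nonzero magnitude
#' `theta_star`, number of trials `m`, the penalty families and selection
#' criteria to compare, and the master seed. Per-trial seeds are derived
#' from the master seed by a counter scheme so that individual trials can
#' be re-run in isolation.
#'
#' @param q Deformation parameter of the error law.
#' @param n Sample size per trial.
#' @param d Number of explanatory variables.
#' @param rnz Nonzero ratio of the true slopes (`d * rnz` whole).
#' @param theta_star Magnitude of the nonzero slopes.
#' @param m Number of Monte Carlo trials (default 100; the full-scale
#'   study uses 1000).
#' @param penalties Penalty families to compare.
#' @param criteria Selection criteria: any of the eight information
#'   criteria (see [evaluate_path()]) and/or `"CV"`.
#' @param seed Master seed.
#' @param nlambda Path length per fit.
#' @param cv_folds Folds used when `"CV"` is among the criteria.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(q = 1, n = 100L, d = 10L, rnz = 0.2,
                              theta_star = 1, m = 100L,
                              penalties = c("lasso", "scad", "mcp"),
                              criteria = c("AIC1", "AIC2", "BIC1", "BIC2",
                                           "LqAIC1", "LqAIC2", "LqBIC1",
                                           "LqBIC2"),
                              seed = 1L, nlambda = 100L, cv_folds = 10L) {
  check_q(q)
  penalties <- match.arg(penalties, c("lasso", "scad", "mcp"),
                         several.ok = TRUE)
  criteria <- match.arg(criteria, c(lq_criteria, "CV"), several.ok = TRUE)
  gen_true_theta(d, rnz, theta_star) # validates d * rnz
  structure(
    list(q = q, n = as.integer(n), d = as.integer(d), rnz = rnz,
         theta_star = theta_star, m = as.integer(m), penalties = penalties,
         criteria = criteria, seed = as.integer(seed),
         nlambda = as.integer(nlambda), cv_folds = as.integer(cv_folds)),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> q = %g, n = %d, d = %d, rnz = %g, theta* = %g, m = %d\n",
    x$q, x$n, x$d, x$rnz, x$theta_star, x$m))
  cat("  penalties:", paste(x$penalties, collapse = ", "), "\n")
  cat("  criteria: ", paste(x$criteria, collapse = ", "), "\n")
  invisible(x)
}

trial_seed <- function(master, trial, stream = 0L) {
  (as.integer(master) + 104729L * as.integer(trial) + 15485863L * stream) %%
    2147483629L
}

#' Run one simulation trial
#'
#' Draws a fresh standardized Gaussian design and q-normal responses,
#' fits the path for every configured penalty, selects a model per
#' criterion, and evaluates exact support recovery and out-of-sample
#' prediction error on an independent test set of the same size (fresh
#' design from the same law, same true coefficients, fresh q-normal
#' errors). The prediction error is reported per observation both as mean
#' squared error and mean absolute error.
#'
#' @param config An [experiment_config()].
#' @param trial Trial index (1-based); combined with the master seed to
#'   give the trial its own reproducible seed.
#' @return Tibble with one row per penalty-criterion pair: columns
#'   `trial`, `penalty`, `criterion`, `selected` (list of slope indices),
#'   `exact_recovery`, `mse`, `mae`, `available`.
#' @export
run_trial <- function(config, trial = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  theta <- gen_true_theta(config$d, config$rnz, config$theta_star)
  true_support <- which(theta[-1L] != 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(trial_seed(config$seed, trial))
  X <- gen_design(config$n, config$d)
  y <- gen_response(X, theta, config$q)
  X_test <- gen_design(config$n, config$d)
  y_test <- gen_response(X_test, theta, config$q)

  ic <- setdiff(config$criteria, "CV")
  rows <- list()
  for (pen in config$penalties) {
    path <- lq_path(X, y, penalty = pen, nlambda = config$nlambda,
                    q = config$q)
    sel <- list()
    if (length(ic)) {
      vals <- evaluate_path(path, q = config$q, criteria = ic)
      for (cr in ic) {
        sel[[cr]] <- tryCatch(select_model(vals, cr, path),
                              error = function(e) NULL)
      }
    }
    if ("CV" %in% config$criteria) {
      cv <- cv_lq(X, y, penalty = pen, K = config$cv_folds,
                  seed = trial_seed(config$seed, trial, stream = 1L),
                  lambda = path$lambda)
      k <- cv$index_min
      sel[["CV"]] <- list(index = k, lambda = path$lambda[k],
                          support = unname(which(path$coefs[-1L, k] != 0)),
                          coef_original = path$coefs_original[, k])
    }
    for (cr in names(sel)) {
      s <- sel[[cr]]
      if (is.null(s)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          trial = trial, penalty = pen, criterion = cr,
          selected = list(integer(0)), exact_recovery = NA,
          mse = NA_real_, mae = NA_real_, available = FALSE)
        next
      }
      cf <- s$coef_original
      pred <- cf[1L] + drop(X_test %*% cf[-1L])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial = trial, penalty = pen, criterion = cr,
        selected = list(s$support),
        exact_recovery = identical(sort(s$support), true_support),
        mse = mean((y_test - pred)^2), mae = mean(abs(y_test - pred)),
        available = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run a simulation experiment
#'
#' Repeats [run_trial()] `m` times and aggregates per penalty-criterion
#' pair: the exact support-recovery count and the mean and median of the
#' per-trial prediction errors (the median is reported as a robustness
#' diagnostic — under q at or above 2 the squared error has no finite
#' variance and trial means can be erratic).
#'
#' @param config An [experiment_config()].
#' @param keep_trials Also return the trial-level table (default FALSE).
#' @return Object of class `lq_experiment`: list with `summary` (tibble:
#'   `penalty`, `criterion`, `m`, `n_available`, `recovery_count`,
#'   `recovery_rate`, `mean_mse`, `median_mse`, `mean_mae`,
#'   `median_mae`), the `config`, and optionally `trials`.
#' @export
run_experiment <- function(config, keep_trials = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  trials <- dplyr::bind_rows(
    lapply(seq_len(config$m), function(t) run_trial(config, t))
  )
  summary <- trials |>
    dplyr::group_by(.data$penalty, .data$criterion) |>
    dplyr::summarise(
      m = dplyr::n(),
      n_available = sum(.data$available),
      recovery_count = sum(.data$exact_recovery, na.rm = TRUE),
      recovery_rate = .data$recovery_count / .data$m,
      mean_mse = mean(.data$mse, na.rm = TRUE),
      median_mse = stats::median(.data$mse, na.rm = TRUE),
      mean_mae = mean(.data$mae, na.rm = TRUE),
      median_mae = stats::median(.data$mae, na.rm = TRUE),
      .groups = "drop"
    )
  out <- list(summary = summary, config = config)
  if (keep_trials) out$trials <- trials
  structure(out, class = "lq_experiment")
}

#' @export
print.lq_experiment <- function(x, ...) {
  print(x$config)
  print(x$summary, n = Inf)
  invisible(x)
}

#' Enumerate the full simulation design grid
#'
#' The 32-cell factorial over dimension d in \{10, 100\}, nonzero ratio
#' rnz in \{0.2, 0.4, 0.6, 0.8\} and nonzero magnitude theta_star in
#' \{1, 10, 100, 1000\}; each cell is additionally run for every (q, n)
#' pair in the full-scale study. Cases are numbered with theta_star
#' varying fastest, then d, then rnz.
#'
#' @return Tibble with columns `case`, `d`, `rnz`, `theta_star`.
#' @export
enumerate_cases <- function() {
  grid <- expand.grid(theta_star = 10^(0:3), d = c(10L, 100L),
                      rnz = c(0.2, 0.4, 0.6, 0.8))
  tibble::tibble(case = seq_len(nrow(grid)), d = grid$d, rnz = grid$rnz,
                 theta_star = grid$theta_star)
}
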