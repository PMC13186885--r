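## Naive inference: bounded nonlinear least squares, Jacobian-based
## confidence intervals, goodness of fit, Gaussian negative log-likelihood
## and kernel density summaries. "Naive" means the recorded (protocol) times
## are taken at face value; timing error is not modelled here.

default_lower <- function(model_id, free) {
  lo <- switch(model_id,
    linear   = c(beta0 = -Inf, beta_x = -Inf),
    cosine   = c(a = 0, b = 0),
    parasite = c(V0 = 0, g = 0, B0 = 0, k = 0),
    gompertz = c(y0 = 1e-8, r = 1e-8, K = 1e-8),
    glut4    = c(P0 = 0, k = 1e-8, M = 0)
  )
  lo[free]
}

default_init <- function(model_id, free, data) {
  y <- data$response
  init <- switch(model_id,
    linear   = c(beta0 = 0, beta_x = 0),
    cosine   = c(a = max(abs(y)), b = 1),
    parasite = c(V0 = 0.01, g = 0.3, B0 = 0.01, k = 0.5),
    gompertz = c(y0 = max(min(y), 1), r = 0.1, K = max(y) * 1.5),
    glut4    = c(P0 = max(min(y), 1e-3), k = 0.1, M = max(y))
  )
  init[free]
}

fit_time_values <- function(data, time) {
  tt <- switch(time, protocol = data$protocol_time, true = data$true_time)
  if (time == "true" && (is.null(tt) || anyNA(tt))) {
    abort("`time = \"true\"` requires the hidden true_time column (synthetic data only)")
  }
  tt
}

## central-difference Jacobian of model predictions w.r.t. the free params
prediction_jacobian <- function(model_id, theta, fixed, tt) {
  p <- length(theta)
  J <- matrix(0, length(tt), p)
  for (j in seq_len(p)) {
    h <- max(1e-7, 1e-7 * abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (evaluate_model(c(as.list(up), as.list(fixed)), tt,
                              model_id = model_id) -
               evaluate_model(c(as.list(dn), as.list(fixed)), tt,
                              model_id = model_id)) / (2 * h)
  }
  colnames(J) <- names(theta)
  J
}

#' Naive least-squares fit of a timecourse dataset
#'
#' Minimises the sum of squared residuals between the observed responses and
#' the model evaluated at the recorded protocol times (`time = "protocol"`)
#' or, for synthetic data, at the hidden true times (`time = "true"`), using
#' bounded Levenberg-Marquardt nonlinear least squares. Fitting is pooled: a
#' single shared parameter vector with residuals stacked across all
#' subjects. Parameters named in `fixed` are held constant; lower bounds
#' enforce non-negativity constraints where the model requires them.
#'
#' The estimated covariance of the free parameters is `(J'J)^-1 s^2`, with
#' `J` the Jacobian of the fitted values with respect to the parameters and
#' `s^2` the mean squared error; confidence bounds are
#' `estimate +/- t_{dof} * sqrt(diag(cov))` with the Student-t quantile at
#' the fit's error degrees of freedom.
#'
#' @param data A timecourse tibble (see [as_timecourse()]).
#' @param model_id Model identifier; defaults to the generator's model
#'   recorded in the dataset metadata.
#' @param time `"protocol"` (naive) or `"true"` (oracle fit to the hidden
#'   truth).
#' @param free Names of parameters to estimate (default: all parameters not
#'   in `fixed`).
#' @param fixed Named numeric vector of parameters held constant.
#' @param init Named numeric starting values for the free parameters;
#'   model-specific defaults are used when omitted.
#' @param lower Named numeric lower bounds; defaults enforce the model's
#'   sign constraints.
#' @param level Confidence level (default 0.95).
#' @return A `timerr_fit` object with elements `theta_hat`, `fixed`, `cov`,
#'   `ci`, `residuals`, `fitted`, `dof`, `s2`, `r2`, `adj_r2`, `converged`,
#'   `n_evals`. Non-convergence is flagged, not thrown.
#' @examples
#' set.seed(1)
#' d <- generate_parasite_dataset(sigma_U = 0, sigma_eps = 0)
#' fit_least_squares(d)
#' @export
fit_least_squares <- function(data, model_id = NULL,
                              time = c("protocol", "true"),
                              free = NULL, fixed = NULL, init = NULL,
                              lower = NULL, level = 0.95) {
  time <- match.arg(time)
  if (nrow(data) == 0) abort("`data` is empty")
  model_id <- model_id %||% timecourse_meta(data)$meta$model_id
  if (is.null(model_id)) abort("`model_id` must be supplied for external data")
  model_id <- match.arg(model_id, model_ids())
  all_par <- model_par_names(model_id)
  fixed <- unlist(fixed) %||% numeric(0)
  free <- free %||% setdiff(all_par, names(fixed))
  if (!all(free %in% all_par) || anyDuplicated(free)) {
    abort("`free` must name distinct parameters of the model")
  }
  missing_par <- setdiff(all_par, c(free, names(fixed)))
  if (length(missing_par)) {
    abort(paste("parameters not free and not fixed:",
                paste(missing_par, collapse = ", ")))
  }
  tt <- fit_time_values(data, time)
  y <- data$response
  th0 <- unlist(init) %||% default_init(model_id, free, data)
  th0 <- th0[free]
  lo <- unlist(lower) %||% default_lower(model_id, free)
  lo <- lo[free]
  if (any(th0 < lo)) abort("starting values must respect the lower bounds")

  resid_fn <- function(th) {
    th <- setNames(th, free)
    y - evaluate_model(c(as.list(th), as.list(fixed)), tt, model_id = model_id)
  }
  # multi-start guard against local minima: the supplied start plus the
  # model's default start (when different); keep the lowest SSR
  starts <- list(th0)
  def0 <- pmax(default_init(model_id, free, data)[free], lo)
  if (any(abs(def0 - th0) > 1e-12)) starts <- c(starts, list(def0))
  fit <- NULL
  best_ssr <- Inf
  for (st in starts) {
    cand <- minpack.lm::nls.lm(
      par = st, fn = resid_fn, lower = lo,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    )
    ssr_c <- sum(resid_fn(coef(cand))^2)
    if (ssr_c < best_ssr) {
      fit <- cand
      best_ssr <- ssr_c
    }
    if (best_ssr <= 1e-18 * max(1, sum(y^2))) break
  }
  theta <- setNames(coef(fit), free)
  res <- resid_fn(theta)
  ssr <- sum(res^2)
  # Gauss-Newton polish: LM's relative-change stopping rule leaves ~1e-9
  # parameter error; a few Newton steps sharpen the optimum (exact for
  # models linear in the parameters)
  for (pol in 1:3) {
    J <- prediction_jacobian(model_id, theta, fixed, tt)
    step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- pmax(theta + drop(step), lo)
    res_c <- resid_fn(cand)
    if (sum(res_c^2) <= ssr) {
      theta <- cand; res <- res_c; ssr <- sum(res_c^2)
    } else break
    if (max(abs(drop(step))) < 1e-13 * max(1, max(abs(theta)))) break
  }
  n <- length(y); p <- length(theta)
  dof <- n - p
  s2 <- if (dof >= 1) ssr / dof else NA_real_
  converged <- fit$info %in% 1:4

  covm <- matrix(NA_real_, p, p, dimnames = list(free, free))
  singular <- FALSE
  if (dof >= 1) {
    J <- prediction_jacobian(model_id, theta, fixed, tt)
    jtj <- crossprod(J)
    covm <- tryCatch(solve(jtj) * s2, error = function(e) {
      singular <<- TRUE
      matrix(NA_real_, p, p, dimnames = list(free, free))
    })
    if (!singular && any(!is.finite(diag(covm)))) singular <- TRUE
  }

  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  adj_r2 <- if (sst > 0 && dof >= 1) 1 - (1 - r2) * (n - 1) / dof else NA_real_

  out <- structure(
    list(
      model_id = model_id, theta_hat = theta, fixed = fixed, cov = covm,
      residuals = res, fitted = y - res, dof = dof, s2 = s2,
      r2 = r2, adj_r2 = adj_r2, converged = converged,
      singular = singular, n = n, n_evals = fit$niter, level = level,
      time = time, data = tibble::tibble(t = tt, y = y)
    ),
    class = "timerr_fit"
  )
  out$ci <- confidence_intervals(out, level)
  out
}

#' Fit each subject separately
#'
#' Convenience wrapper: runs [fit_least_squares()] within each
#' `subject_id` and row-binds the tidy coefficient tables.
#'
#' @inheritParams fit_least_squares
#' @param ... Passed on to [fit_least_squares()].
#' @return A tibble with columns `subject_id`, `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `converged`.
#' @export
fit_subjects <- function(data, ...) {
  purrr::map_dfr(split(data, data$subject_id), function(d) {
    f <- fit_least_squares(tibble::as_tibble(d), ...)
    dplyr::mutate(tidy(f), subject_id = d$subject_id[1], converged = f$converged,
                  .before = 1)
  })
}

#' Student-t confidence intervals from the Jacobian covariance
#'
#' Implements `C = b +/- t * sqrt(S)`: per-parameter bounds from the
#' diagonal of the estimated covariance `(J'J)^-1 s^2` and the Student-t
#' quantile with the fit's error degrees of freedom. A singular `J'J`
#' (non-identifiable parameters) yields `NA` bounds, flagged in the fit.
#'
#' @param fit A `timerr_fit`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "timerr_fit"))
  se <- sqrt(diag(fit$cov))
  tq <- if (fit$dof >= 1) qt((1 + level) / 2, fit$dof) else NA_real_
  tibble::tibble(
    term = names(fit$theta_hat),
    estimate = unname(fit$theta_hat),
    std.error = unname(se),
    conf.low = unname(fit$theta_hat - tq * se),
    conf.high = unname(fit$theta_hat + tq * se)
  )
}

#' Goodness of fit
#'
#' `R^2 = 1 - SSR/SST` (total sum of squares about the mean response) and
#' the adjusted `R^2 = 1 - (1 - R^2)(n - 1)/(n - p)`. Undefined (NA) when
#' the responses are constant.
#'
#' @param fit A `timerr_fit`.
#' @return A tibble with `r2` and `adj_r2`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "timerr_fit"))
  tibble::tibble(r2 = fit$r2, adj_r2 = fit$adj_r2)
}

#' @export
print.timerr_fit <- function(x, ...) {
  cat("<timerr_fit: ", x$model_id, " model, ", x$time, " times, n = ", x$n,
      ">\n", sep = "")
  print(x$ci)
  cat(sprintf("R^2 = %.4f, adj R^2 = %.4f, converged: %s\n",
              x$r2, x$adj_r2, x$converged))
  if (x$singular) cat("note: singular J'J, intervals unavailable\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a least-squares fit
#' @param x A `timerr_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy timerr_fit
#' @export
tidy.timerr_fit <- function(x, ...) x$ci

#' One-row fit summary
#' @param x A `timerr_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`, `nobs`, `converged`.
#' @method glance timerr_fit
#' @export
glance.timerr_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, adj.r.squared = x$adj_r2,
    sigma = sqrt(x$s2), df.residual = x$dof, nobs = x$n,
    converged = x$converged
  )
}

#' Gaussian negative log-likelihood
#'
#' The negative log-likelihood of additive, iid normal equation error with
#' constant variance `sigma2`:
#' `sum((y_i - y(theta, x_i))^2 / (2 sigma2) + log(2 pi sigma2) / 2)`.
#' With constant variance its minimiser over `theta` coincides with the
#' least-squares estimate.
#'
#' @param theta Named parameter values (all parameters of the model).
#' @param data A timecourse tibble.
#' @param sigma2 Equation-error variance (> 0).
#' @param model_id Model identifier (default from metadata).
#' @param time `"protocol"` or `"true"`.
#' @return The scalar negative log-likelihood.
#' @export
gaussian_nll <- function(theta, data, sigma2, model_id = NULL,
                         time = c("protocol", "true")) {
  time <- match.arg(time)
  if (sigma2 <= 0) abort("`sigma2` must be positive")
  model_id <- model_id %||% timecourse_meta(data)$meta$model_id
  tt <- fit_time_values(data, time)
  res <- data$response - evaluate_model(as.list(theta), tt, model_id = model_id)
  sum(res^2 / (2 * sigma2) + 0.5 * log(2 * pi * sigma2))
}

#' Gaussian-kernel density estimate
#'
#' Density of a sample with a Gaussian kernel and the normal-reference
#' bandwidth rule (the default of the usual built-in density estimators).
#'
#' @param samples Numeric vector (length >= 2).
#' @param grid Optional evaluation grid; by default 512 points spanning the
#'   sample range extended by three bandwidths.
#' @return A tibble with `x` and `density`; a constant sample is degenerate
#'   and yields a warning with `NA` densities.
#' @export
kde <- function(samples, grid = NULL) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) abort("`samples` must hold at least two finite values")
  if (sd(samples) == 0) {
    warn("constant sample: density estimate is degenerate")
    grid <- grid %||% rep(samples[1], 2L)
    return(tibble::tibble(x = grid, density = NA_real_))
  }
  bw <- bw.nrd(samples)
  if (is.null(grid)) {
    grid <- seq(min(samples) - 3 * bw, max(samples) + 3 * bw,
                length.out = 512)
  }
  dens <- vapply(grid, function(g) mean(dnorm(g, samples, bw)), numeric(1))
  tibble::tibble(x = grid, density = dens)
}
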