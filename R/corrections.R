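## Correction methods for independent-variable measurement error:
## reliability ratio, Fuller's method of moments, regression calibration,
## orthogonal (Deming) regression, SIMEX, and classical/Berkson
## measurement-error likelihoods, plus a rule-based method selector.

#' Reliability ratio and attenuation correction
#'
#' Under classical error `w = x + u` the naive linear slope converges to
#' `lambda * beta_x` with reliability ratio
#' `lambda = sigma_x^2 / (sigma_x^2 + sigma_u^2) <= 1`. When the error
#' variance is known, dividing the naive slope by `lambda` undoes the
#' attenuation exactly (linear models only).
#'
#' @param sigma_x2 Variance of the true independent variable (> 0).
#' @param sigma_u2 Variance of the measurement error (>= 0).
#' @return `reliability_ratio()`: lambda in (0, 1].
#' @examples
#' reliability_ratio(1, 0.25)
#' correct_slope(0.8431, reliability_ratio(1, 0.25))
#' @export
reliability_ratio <- function(sigma_x2, sigma_u2) {
  sigma_x2 <- check_finite(sigma_x2, "sigma_x2")
  sigma_u2 <- check_finite(sigma_u2, "sigma_u2")
  if (sigma_x2 <= 0) abort("`sigma_x2` must be positive")
  if (sigma_u2 < 0) abort("`sigma_u2` must be non-negative")
  sigma_x2 / (sigma_x2 + sigma_u2)
}

#' @rdname reliability_ratio
#' @param naive_beta Naive (attenuated) slope estimate.
#' @param lambda Reliability ratio.
#' @return `correct_slope()`: the corrected slope `naive_beta / lambda`.
#' @export
correct_slope <- function(naive_beta, lambda) {
  if (lambda <= 0 || lambda > 1) abort("`lambda` must lie in (0, 1]")
  naive_beta / lambda
}

#' Does classical error shrink the naive slope's asymptotic variance?
#'
#' The naive estimator from observed `w` is asymptotically less variable
#' than the true-data estimator iff
#' `beta_x^2 sigma_x^2 / (sigma_x^2 + sigma_u^2) < sigma_eps^2 / sigma_x^2`:
#' small equation error, large measurement error or a shallow slope make
#' the biased estimate deceptively precise.
#'
#' @param beta_x True slope.
#' @param sigma_x2 Variance of the true X (> 0).
#' @param sigma_u2 Measurement-error variance (>= 0).
#' @param sigma_eps2 Equation-error variance (>= 0).
#' @return Logical.
#' @export
variance_inequality_holds <- function(beta_x, sigma_x2, sigma_u2, sigma_eps2) {
  if (sigma_x2 <= 0) abort("`sigma_x2` must be positive")
  if (sigma_u2 < 0 || sigma_eps2 < 0) abort("variances must be non-negative")
  beta_x^2 * sigma_x2 / (sigma_x2 + sigma_u2) < sigma_eps2 / sigma_x2
}

#' Fuller's method-of-moments slope correction
#'
#' For a linear model with additive classical error of known variance
#' `sigma_u^2`, the moment-corrected estimator replaces the naive
#' denominator by the estimated variance of the true X:
#' `slope = S_wy / (S_ww - sigma_u^2)`,
#' `intercept = mean(y) - slope * mean(w)`. With `sigma_u2 = 0` this is
#' exactly ordinary least squares.
#'
#' @param w Observed independent values.
#' @param y Responses.
#' @param sigma_u2 Known measurement-error variance.
#' @return A tibble with `term` (`beta0`, `beta_x`) and `estimate`.
#' @export
fuller_moment_fit <- function(w, y, sigma_u2) {
  stopifnot(length(w) == length(y), length(w) >= 3)
  if (sigma_u2 < 0) abort("`sigma_u2` must be non-negative")
  s_ww <- var(w)
  if (s_ww <= sigma_u2) {
    abort("sample variance of `w` does not exceed `sigma_u2`: estimator degenerate")
  }
  slope <- stats::cov(w, y) / (s_ww - sigma_u2)
  tibble::tibble(term = c("beta0", "beta_x"),
                 estimate = c(mean(y) - slope * mean(w), slope))
}

#' Regression-calibration imputation
#'
#' Replaces the mismeasured `w` by the best linear approximation to
#' `E[X | W]`: `x_hat = mu_x + lambda * (w - mu_x)`. Downstream fitting
#' then proceeds as if `x_hat` were observed. For unbiased Berkson error
#' `E[X | W] = W`, so the imputation is the identity and no extra
#' information is gained (`lambda = 1`).
#'
#' @param w Observed values.
#' @param lambda Reliability ratio in `[0, 1]`.
#' @param mu_x Mean of the true X (default: `mean(w)`, its natural
#'   estimate under zero-mean error).
#' @return Numeric vector of imputed values.
#' @export
regression_calibration <- function(w, lambda, mu_x = mean(w)) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must lie in [0, 1]")
  mu_x + lambda * (w - mu_x)
}

#' Orthogonal (Deming) regression for any model
#'
#' Jointly minimises
#' `sum((y_i - y(theta, x_i))^2 + eta * (w_i - x_i)^2)` over the model
#' parameters and the latent true abscissae `x_1..x_N`, with weight
#' `eta = sigma_eps^2 / sigma_u^2`. As `eta` grows the latent `x` are
#' pinned to `w` and the fit approaches ordinary least squares.
#'
#' Note the caution surfaced by the measurement-error literature: with
#' `eta = 1` the implied correction depends on the measurement scale of the
#' data (rescaling the axes changes the answer), and the method ignores
#' error in the equation, which tends to overcorrect; a warning points this
#' out when `eta = 1` is used.
#'
#' @param data A timecourse tibble (observed `protocol_time` is `w`).
#' @param eta Positive weight on the horizontal distances.
#' @param model_id,free,fixed,init,lower As in [fit_least_squares()].
#' @return A list of class `timerr_orth_fit`: `theta_hat`, `x_hat`,
#'   `objective`, `converged`.
#' @export
orthogonal_regression_fit <- function(data, eta, model_id = NULL,
                                      free = NULL, fixed = NULL,
                                      init = NULL, lower = NULL) {
  if (eta <= 0) abort("`eta` must be positive")
  if (isTRUE(all.equal(eta, 1))) {
    warn(paste("eta = 1 orthogonal regression is scale-dependent and ignores",
               "equation error; the correction can overcorrect"))
  }
  model_id <- model_id %||% timecourse_meta(data)$meta$model_id
  model_id <- match.arg(model_id, model_ids())
  all_par <- model_par_names(model_id)
  fixed <- unlist(fixed) %||% numeric(0)
  free <- free %||% setdiff(all_par, names(fixed))
  w <- data$protocol_time
  y <- data$response
  n <- length(w)
  th0 <- unlist(init) %||% default_init(model_id, free, data)
  th0 <- th0[free]
  lo_th <- (unlist(lower) %||% default_lower(model_id, free))[free]
  p <- length(th0)

  resid_fn <- function(par) {
    th <- setNames(par[seq_len(p)], free)
    x <- par[-seq_len(p)]
    c(y - evaluate_model(c(as.list(th), as.list(fixed)), x,
                         model_id = model_id),
      sqrt(eta) * (w - x))
  }
  par <- c(th0, w)
  obj <- Inf
  # warm restarts sharpen the optimum past LM's relative-change stop rule
  for (round in 1:6) {
    fit <- minpack.lm::nls.lm(
      par = par, fn = resid_fn,
      lower = c(lo_th, rep(-Inf, n)),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    par <- coef(fit)
    obj_new <- sum(resid_fn(par)^2)
    if (obj - obj_new < 1e-14 * max(1, obj_new)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  structure(
    list(theta_hat = setNames(par[seq_len(p)], free),
         x_hat = unname(par[-seq_len(p)]),
         objective = sum(resid_fn(par)^2),
         converged = fit$info %in% 1:4,
         eta = eta, model_id = model_id),
    class = "timerr_orth_fit"
  )
}

#' @export
print.timerr_orth_fit <- function(x, ...) {
  cat("<orthogonal regression fit: ", x$model_id, ", eta = ", x$eta, ">\n",
      sep = "")
  print(x$theta_hat)
  invisible(x)
}

#' Simulation extrapolation (SIMEX)
#'
#' Learns how an estimator degrades as the (classical, normal) measurement
#' error variance is artificially inflated and extrapolates the trajectory
#' back to the no-error case. For each `zeta` in the grid and each of `B`
#' pseudo-datasets, `w` is perturbed to `w + sqrt(zeta) * N(0, sigma_u2)`,
#' the naive estimator is refit, and estimates are averaged per `zeta`; the
#' extrapolant is fit to the trajectory (including the naive point at
#' `zeta = 0`) and evaluated at `zeta = -1`.
#'
#' The rational-linear extrapolant `a + b / (c + zeta)` matches the exact
#' attenuation curve of the linear-classical problem; the quadratic is the
#' generic default. A failed rational-linear fit falls back to the
#' quadratic with a warning.
#'
#' @param w Observed independent values.
#' @param y Responses.
#' @param fitter Function `(w, y) -> named numeric vector` of estimates
#'   (the naive estimator to be corrected).
#' @param sigma_u2 Known measurement-error variance (>= 0); zero returns
#'   the naive estimate unchanged.
#' @param zeta Positive inflation grid (default `c(0.5, 1, 1.5, 2)`).
#' @param B Pseudo-datasets per `zeta` (default 100).
#' @param extrapolant `"quadratic"` or `"rational_linear"`.
#' @return A list of class `timerr_simex`: `estimates` (named, at
#'   `zeta = -1`), `naive`, `trajectory` (tibble of per-`zeta` means),
#'   `extrapolant`.
#' @export
simex <- function(w, y, fitter, sigma_u2,
                  zeta = c(0.5, 1, 1.5, 2), B = 100,
                  extrapolant = c("quadratic", "rational_linear")) {
  extrapolant <- match.arg(extrapolant)
  if (sigma_u2 < 0) abort("`sigma_u2` must be non-negative")
  if (any(zeta <= 0)) abort("`zeta` values must be positive")
  if (B < 2) abort("`B` must be at least 2")
  naive <- fitter(w, y)
  if (is.null(names(naive))) {
    names(naive) <- paste0("par", seq_along(naive))
  }
  if (sigma_u2 == 0) {
    traj <- tibble::tibble(zeta = 0, term = names(naive),
                           estimate = unname(naive))
    return(structure(list(estimates = naive, naive = naive,
                          trajectory = traj, extrapolant = extrapolant),
                     class = "timerr_simex"))
  }
  sd_u <- sqrt(sigma_u2)
  per_zeta <- purrr::map(zeta, function(z) {
    est <- replicate(B, fitter(w + sqrt(z) * rnorm(length(w), 0, sd_u), y))
    if (is.null(dim(est))) est <- matrix(est, 1, dimnames = list(names(naive)))
    rowMeans(est)
  })
  traj <- dplyr::bind_rows(
    tibble::tibble(zeta = 0, term = names(naive), estimate = unname(naive)),
    purrr::map2_dfr(zeta, per_zeta, function(z, e) {
      tibble::tibble(zeta = z, term = names(e), estimate = unname(e))
    })
  )
  zs <- c(0, zeta)
  est_out <- purrr::imap_dbl(naive, function(val, nm) {
    path <- traj$estimate[traj$term == nm][order(zs)]
    extrapolate_simex(sort(zs), path, extrapolant)
  })
  structure(list(estimates = est_out, naive = naive, trajectory = traj,
                 extrapolant = extrapolant),
            class = "timerr_simex")
}

## evaluate the chosen extrapolant at zeta = -1
extrapolate_simex <- function(zs, est, extrapolant) {
  quad <- function() {
    fitq <- lm(est ~ zs + I(zs^2))
    unname(predict(fitq, data.frame(zs = -1)))
  }
  if (extrapolant == "quadratic") return(quad())
  # rational linear a + b / (c + zeta): profile out (a, b) and line-search c
  ssr_c <- function(cc) {
    xr <- 1 / (cc + zs)
    sum(lm(est ~ xr)$residuals^2)
  }
  opt <- tryCatch(
    optimize(function(lc) ssr_c(exp(lc)), c(log(1.001), log(1e4))),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    warn("rational-linear extrapolant failed; falling back to quadratic")
    return(quad())
  }
  cc <- exp(opt$minimum)
  cf <- coef(lm(est ~ I(1 / (cc + zs))))
  unname(cf[1] + cf[2] / (cc - 1))
}

#' @export
print.timerr_simex <- function(x, ...) {
  cat("<SIMEX correction (", x$extrapolant, " extrapolant)>\n", sep = "")
  print(rbind(naive = x$naive, corrected = x$estimates))
  invisible(x)
}

## Measurement-error likelihoods --------------------------------------------

#' Measurement-error-aware log-likelihood
#'
#' Marginalises the latent true independent value out of the observation
#' density. For classical error the observed-data density is
#' `phi_{Y|W}(y | w) = integral phi_{Y|X}(y; y(theta, x))
#' phi_{W|X}(w; x) phi_X(x) dx`, which requires a density for the true X;
#' for Berkson error it is
#' `integral phi_{Y|X}(y; y(theta, x)) phi_{X|W}(x; w) dx`, which does not
#' (the distribution of the predetermined `w` carries no information about
#' `theta`). The observation density `phi_{Y|X}` is normal about the model
#' with variance `sigma_eps2`.
#'
#' Integrals are evaluated by Gauss-Hermite quadrature for normal latent
#' errors and Gauss-Legendre quadrature on the support for uniform Berkson
#' errors. A zero error variance degenerates to the naive likelihood.
#'
#' @param theta Named vector with all model parameters.
#' @param data A timecourse tibble (`protocol_time` is `w`).
#' @param error An [error_spec()] describing the timing error.
#' @param sigma_eps2 Equation-error variance (> 0).
#' @param model_id Model identifier (default from metadata).
#' @param x_density For classical error only: `list(mean =, var =)` of the
#'   normal density of the true X.
#' @param order Quadrature order (default 21).
#' @return Scalar log-likelihood (`-Inf` if any observation has zero
#'   density).
#' @export
me_likelihood <- function(theta, data, error, sigma_eps2, model_id = NULL,
                          x_density = NULL, order = 21) {
  stopifnot(inherits(error, "error_spec"))
  if (sigma_eps2 <= 0) abort("`sigma_eps2` must be positive")
  model_id <- model_id %||% timecourse_meta(data)$meta$model_id
  model_id <- match.arg(model_id, model_ids())
  w <- data$protocol_time
  y <- data$response
  theta <- as.list(theta)
  sd_eps <- sqrt(sigma_eps2)
  obs_dens <- function(x, yi) {
    dnorm(yi, evaluate_model(theta, x, model_id = model_id), sd_eps)
  }

  if (error$kind == "classical" && is.null(x_density)) {
    abort("classical error requires `x_density` (mean and var of the true X)")
  }
  if (error$kind == "berkson" && !is.null(x_density)) {
    abort("Berkson error must not specify `x_density`; X | W is fully specified")
  }

  if (error$var_u == 0) {
    # degenerate integrand: the naive likelihood (classical keeps the
    # theta-free phi_X factor so the var_u -> 0 limit is continuous)
    dens <- obs_dens(w, y)
    if (error$kind == "classical") {
      dens <- dens * dnorm(w, x_density$mean, sqrt(x_density$var))
    }
    return(if (any(dens <= 0)) -Inf else sum(log(dens)))
  }

  if (error$kind == "berkson") {
    if (error$distribution == "normal") {
      gh <- pracma::gaussHermite(order)
      sd_u <- sqrt(error$var_u)
      dens <- vapply(seq_along(w), function(i) {
        x <- w[i] + sqrt(2) * sd_u * gh$x
        sum(gh$w * obs_dens(x, y[i])) / sqrt(pi)
      }, numeric(1))
    } else {
      lo <- if (error$biased) 0 else -error$delta / 2
      gl <- pracma::gaussLegendre(order, 0, 1)
      dens <- vapply(seq_along(w), function(i) {
        x <- w[i] + lo + error$delta * gl$x
        sum(gl$w * obs_dens(x, y[i]))  # density 1/delta times delta Jacobian
      }, numeric(1))
    }
  } else {
    if (error$distribution != "normal") {
      abort("classical error is supported for normal error distributions")
    }
    mx <- x_density$mean; vx <- x_density$var
    if (is.null(mx) || is.null(vx) || vx <= 0) {
      abort("`x_density` must supply `mean` and positive `var`")
    }
    vu <- error$var_u
    # N(x; m_post, v_post) * N(w; mx, vx + vu) factorisation of
    # phi_{W|X} phi_X; quadrature over the conditional of X given W
    v_post <- vx * vu / (vx + vu)
    gh <- pracma::gaussHermite(order)
    dens <- vapply(seq_along(w), function(i) {
      m_post <- (w[i] * vx + mx * vu) / (vx + vu)
      x <- m_post + sqrt(2 * v_post) * gh$x
      marg_w <- dnorm(w[i], mx, sqrt(vx + vu))
      marg_w * sum(gh$w * obs_dens(x, y[i])) / sqrt(pi)
    }, numeric(1))
  }
  if (any(!is.finite(dens))) {
    warn("non-finite quadrature value in measurement-error likelihood")
    return(-Inf)
  }
  if (any(dens <= 0)) return(-Inf)
  sum(log(dens))
}

#' Maximise a measurement-error likelihood over free parameters
#'
#' One-dimensional problems use golden-section search on the given
#' interval; higher-dimensional problems use Nelder-Mead from `init`.
#'
#' @param data A timecourse tibble.
#' @param free Names of the parameters to maximise over.
#' @param fixed Named vector of fixed parameters.
#' @param error,sigma_eps2,model_id,x_density,order As in
#'   [me_likelihood()].
#' @param interval Search interval for a single free parameter.
#' @param init Starting values when several parameters are free.
#' @return Named vector of maximising parameter values.
#' @export
maximise_me_likelihood <- function(data, free, fixed, error, sigma_eps2,
                                   model_id = NULL, x_density = NULL,
                                   order = 21, interval = NULL, init = NULL) {
  model_id <- model_id %||% timecourse_meta(data)$meta$model_id
  obj <- function(vals) {
    th <- c(setNames(as.list(vals), free), as.list(fixed))
    me_likelihood(th, data, error, sigma_eps2, model_id = model_id,
                  x_density = x_density, order = order)
  }
  if (length(free) == 1) {
    if (is.null(interval)) abort("supply `interval` for a single free parameter")
    opt <- optimize(obj, interval, maximum = TRUE)
    setNames(opt$maximum, free)
  } else {
    if (is.null(init)) abort("supply `init` for several free parameters")
    opt <- optim(unlist(init)[free], function(v) -obj(v))
    setNames(opt$par, free)
  }
}

## Method selector ----------------------------------------------------------

#' Rule-based correction-method selector
#'
#' Deterministic recommendations mirroring the structure of the correction
#' toolbox: specialised exact corrections for linear models with known
#' error variance, calibration methods when replicate or validation data
#' exist, simulation-based and latent-variable corrections when only the
#' variance is known, and fully specified likelihood/Bayesian treatments
#' when the error distribution is known.
#'
#' @param model_class `"linear"`, `"glm"` or `"nonlinear"`.
#' @param extra_data `"none"`, `"replicates"` or `"validation"`.
#' @param variance_known Is the measurement-error variance known?
#' @param error_model `"classical"` or `"berkson"`.
#' @param distribution_fully_specified Is the full error distribution
#'   known?
#' @return A tibble with `rank`, `method`, `note`, `reference`, best first.
#' @examples
#' select_correction_method("linear", "none", TRUE, "classical", FALSE)
#' @export
select_correction_method <- function(model_class = c("linear", "glm",
                                                     "nonlinear"),
                                     extra_data = c("none", "replicates",
                                                    "validation"),
                                     variance_known,
                                     error_model = c("classical", "berkson"),
                                     distribution_fully_specified) {
  model_class <- match.arg(model_class)
  extra_data <- match.arg(extra_data)
  error_model <- match.arg(error_model)
  stopifnot(is.logical(variance_known), is.logical(distribution_fully_specified))
  rec <- list()
  add <- function(method, note, reference) {
    rec[[length(rec) + 1]] <<- tibble::tibble(method = method, note = note,
                                              reference = reference)
  }
  if (extra_data == "validation") {
    add("validation-data methods",
        "true X observed for a subset; no error assumptions needed (reference only, not implemented here)",
        "Sepanski & Carroll (1993)")
  }
  if (model_class == "linear" && variance_known && error_model == "classical") {
    add("reliability ratio",
        "exact attenuation correction for the linear slope",
        "Carroll et al. (2006)")
    add("Fuller's method of moments",
        "moment-corrected linear estimator with known error variance",
        "Fuller (1987)")
  }
  if (extra_data == "replicates") {
    add("regression calibration",
        "impute E[X | W] from replicates; most useful for generalised linear models",
        "Carroll & Stefanski (1990); Prentice (1982)")
  }
  if (variance_known) {
    add("SIMEX",
        "model-agnostic simulation extrapolation for additive classical error",
        "Cook & Stefanski (1994)")
    add("orthogonal regression",
        "joint latent-x minimisation with eta = sigma_eps^2 / sigma_u^2; scale caution applies",
        "Fuller (1987); Casella & Berger (2002)")
  }
  if (distribution_fully_specified) {
    if (error_model == "berkson") {
      add("Berkson measurement-error likelihood",
          "marginalise X | W out of the likelihood; no density for X needed",
          "Carroll et al. (2006)")
    } else {
      add("classical measurement-error likelihood",
          "marginalise over phi_{W|X} and phi_X; requires a density for the true X",
          "Carroll et al. (2006)")
    }
    add("Bayesian latent-variable model",
        "same likelihood inside a posterior sampler; priors regularise the extra error parameters",
        "Gustafson (2004)")
  }
  if (!length(rec)) {
    add("collect additional data",
        "no correction applies without variance knowledge, extra data or a specified error distribution",
        "Buonaccorsi (2010)")
  }
  out <- dplyr::distinct(dplyr::bind_rows(rec), .data$method, .keep_all = TRUE)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}
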