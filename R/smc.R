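## Bayesian inference for the GLUT4 study: lognormal likelihood, adaptive
## likelihood-tempered sequential Monte Carlo, and posterior summary metrics
## (MAP absolute error, credibility-interval width, distance from the true
## value to the interval).

#' Independent uniform priors
#'
#' @param lower,upper Named numeric vectors (same names) with
#'   `lower < upper` elementwise.
#' @return A `prior_spec` object.
#' @examples
#' prior_spec(c(P0 = 0, k = 0, M = 0), c(P0 = 0.5, k = 0.5, M = 58))
#' @export
prior_spec <- function(lower, upper) {
  if (is.null(names(lower)) || !identical(names(lower), names(upper))) {
    abort("`lower` and `upper` must share the same parameter names")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    abort("priors require finite bounds with lower < upper")
  }
  structure(list(lower = lower, upper = upper, names = names(lower)),
            class = "prior_spec")
}

sample_prior <- function(priors, n) {
  d <- length(priors$names)
  m <- matrix(runif(n * d), n, d)
  m <- sweep(sweep(m, 2, priors$upper - priors$lower, `*`), 2, priors$lower, `+`)
  colnames(m) <- priors$names
  m
}

log_prior_density <- function(priors, particles) {
  inside <- rep(TRUE, nrow(particles))
  for (j in seq_along(priors$names)) {
    inside <- inside & particles[, j] >= priors$lower[j] &
      particles[, j] <= priors$upper[j]
  }
  ifelse(inside, -sum(log(priors$upper - priors$lower)), -Inf)
}

#' Default GLUT4 priors
#'
#' Independent uniforms over twice the span of the true-parameter grid used
#' in the synthetic study: `P0, k` on `[0, 0.5]` and `M` on `[0, 58]`. A
#' package choice (the study itself does not prescribe priors), exposed so
#' it can be overridden.
#'
#' @return A [prior_spec()].
#' @export
glut4_default_priors <- function() {
  prior_spec(c(P0 = 0, k = 0, M = 0), c(P0 = 0.5, k = 0.5, M = 58))
}

#' Lognormal log-likelihood of a GLUT4 dataset
#'
#' The response at protocol time `w` is modelled as lognormal with
#' original-scale mean `P(theta, w)` and variance `sigma_Y^2`
#' (moment-matched log-scale parameters, see [lognormal_from_moments()]).
#' The likelihood is evaluated at the *recorded* protocol times: timing
#' error is deliberately not modelled (that is the point of the naive
#' Bayesian study). Parameter sets with a non-positive model mean get
#' `-Inf`.
#'
#' @param theta Named vector `(P0, k, M)`, or a matrix with those columns
#'   (one row per particle; a length-`nrow` vector is returned).
#' @param data A GLUT4 timecourse tibble.
#' @param sigma_Y Target response standard deviation (> 0).
#' @return Scalar (or vector) log-likelihood.
#' @export
lognormal_loglik <- function(theta, data, sigma_Y) {
  if (sigma_Y <= 0) abort("`sigma_Y` must be positive")
  w <- data$protocol_time
  y <- data$response
  if (!is.matrix(theta)) {
    theta <- matrix(unlist(theta[c("P0", "k", "M")]), 1,
                    dimnames = list(NULL, c("P0", "k", "M")))
    scalar <- TRUE
  } else scalar <- FALSE
  P0 <- theta[, "P0"]; k <- theta[, "k"]; M <- theta[, "M"]
  # N x n matrix of model means
  Pm <- (P0 - M) * exp(-outer(k, w)) + M
  ll <- rep(-Inf, nrow(theta))
  ok <- rowSums(Pm <= 0) == 0 & k > 0
  if (any(ok)) {
    P2 <- Pm[ok, , drop = FALSE]^2
    mu <- log(P2 / sqrt(P2 + sigma_Y^2))
    sig <- sqrt(log1p(sigma_Y^2 / P2))
    ymat <- matrix(y, sum(ok), length(y), byrow = TRUE)
    ll[ok] <- rowSums(dlnorm(ymat, mu, sig, log = TRUE))
  }
  if (scalar) ll[1] else ll
}

systematic_resample <- function(weights, n = length(weights)) {
  u <- (runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(weights)) + 1L
}

ess_of <- function(logw) {
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  1 / sum(w^2)
}

#' Adaptive likelihood-tempered sequential Monte Carlo
#'
#' Approximates the posterior `prior x likelihood` by moving a particle
#' population through the tempered sequence `prior x likelihood^gamma`,
#' `gamma: 0 -> 1`. Each temperature increment is chosen by bisection so
#' that the effective sample size (ESS) of the reweighted population is
#' `ess_target * n_particles`; when the ESS falls below
#' `resample_threshold * n_particles` the population is resampled
#' systematically and rejuvenated with `n_moves` Metropolis-Hastings
#' random-walk sweeps whose proposal covariance is adapted from the current
#' weighted particle cloud.
#'
#' @param loglik Function taking a matrix of particles (one row per
#'   particle, named columns) and returning a vector of log-likelihoods.
#'   Wrap a scalar function with [rowwise_loglik()].
#' @param priors A [prior_spec()].
#' @param n_particles Number of particles (>= 100).
#' @param ess_target Fraction of `n_particles` targeted by each temperature
#'   step (default 0.5).
#' @param resample_threshold ESS fraction below which the population is
#'   resampled (default 0.5).
#' @param n_moves MH sweeps per resampling (default 5).
#' @param max_steps Safety cap on the number of temperature steps.
#' @return A `particle_set`: `particles` (matrix), `weights` (normalised),
#'   `loglik`, `schedule` (temperature trace), `ess_trace`, `accept_rates`,
#'   `priors`.
#' @export
run_smc <- function(loglik, priors, n_particles = 1000,
                    ess_target = 0.5, resample_threshold = 0.5,
                    n_moves = 5, max_steps = 200) {
  stopifnot(inherits(priors, "prior_spec"), n_particles >= 100)
  d <- length(priors$names)
  particles <- sample_prior(priors, n_particles)
  ll <- loglik(particles)
  if (all(!is.finite(ll))) {
    abort("all particles have zero likelihood under the prior; check the model/data")
  }
  logw <- rep(0, n_particles)
  temp <- 0
  schedule <- 0
  ess_trace <- n_particles
  acc <- numeric(0)

  for (step in seq_len(max_steps)) {
    if (temp >= 1) break
    ll_f <- ifelse(is.finite(ll), ll, -1e300)
    target_ess <- ess_target * n_particles
    f <- function(dt) ess_of(logw + dt * ll_f)
    dt_max <- 1 - temp
    if (f(dt_max) >= target_ess) {
      dt <- dt_max
    } else {
      lo <- 0; hi <- dt_max
      for (i in 1:50) {
        mid <- (lo + hi) / 2
        if (f(mid) >= target_ess) lo <- mid else hi <- mid
      }
      dt <- (lo + hi) / 2
      dt <- max(dt, dt_max * 1e-6)
    }
    temp <- temp + dt
    logw <- logw + dt * ll_f
    w <- exp(logw - max(logw)); w <- w / sum(w)
    ess <- 1 / sum(w^2)
    schedule <- c(schedule, temp)

    if (ess < resample_threshold * n_particles || temp >= 1) {
      # adapted RW proposal from the weighted cloud
      mu <- colSums(particles * w)
      ctr <- sweep(particles, 2, mu)
      Sigma <- crossprod(ctr * sqrt(w), ctr * sqrt(w))
      Sigma <- Sigma * (2.38^2 / d) + diag(1e-12, d)
      L <- tryCatch(chol(Sigma), error = function(e) {
        diag(sqrt(pmax(diag(Sigma), 1e-12)), d)
      })
      idx <- systematic_resample(w)
      particles <- particles[idx, , drop = FALSE]
      ll <- ll[idx]
      logw <- rep(0, n_particles)
      n_acc <- 0
      lp <- log_prior_density(priors, particles)
      for (m in seq_len(n_moves)) {
        prop <- particles + matrix(rnorm(n_particles * d), n_particles, d) %*% L
        colnames(prop) <- priors$names
        lp_prop <- log_prior_density(priors, prop)
        ll_prop <- rep(-Inf, n_particles)
        okp <- is.finite(lp_prop)
        if (any(okp)) ll_prop[okp] <- loglik(prop[okp, , drop = FALSE])
        log_alpha <- temp * (ll_prop - ll) + lp_prop - lp
        accept <- log(runif(n_particles)) < log_alpha
        accept[!is.finite(log_alpha)] <- FALSE
        particles[accept, ] <- prop[accept, ]
        ll[accept] <- ll_prop[accept]
        lp[accept] <- lp_prop[accept]
        n_acc <- n_acc + sum(accept)
      }
      acc <- c(acc, n_acc / (n_moves * n_particles))
      ess <- n_particles
    }
    ess_trace <- c(ess_trace, ess)
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  structure(
    list(particles = particles, weights = w, loglik = ll,
         schedule = schedule, ess_trace = ess_trace, accept_rates = acc,
         priors = priors),
    class = "particle_set"
  )
}

#' Adapt a scalar log-likelihood for [run_smc()]
#' @param f Function of one named parameter vector returning a scalar.
#' @return A function over particle matrices.
#' @export
rowwise_loglik <- function(f) {
  function(particles) {
    vapply(seq_len(nrow(particles)),
           function(i) f(particles[i, ]), numeric(1))
  }
}

#' @export
print.particle_set <- function(x, ...) {
  cat("<particle_set: ", nrow(x$particles), " particles, ",
      length(x$schedule) - 1, " temperature steps>\n", sep = "")
  print(utils::head(posterior_summary(x)))
  invisible(x)
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Marginal posterior summaries
#'
#' @param particles A `particle_set`.
#' @param level Credibility level for equal-tailed intervals (default 0.95).
#' @return A tibble with `parameter`, `mean`, `map`, `ci_lower`,
#'   `ci_upper`. The MAP is the particle maximising prior x likelihood
#'   (deterministic given the particles).
#' @export
posterior_summary <- function(particles, level = 0.95) {
  stopifnot(inherits(particles, "particle_set"))
  lp <- log_prior_density(particles$priors, particles$particles)
  map_idx <- which.max(particles$loglik + lp)
  a <- (1 - level) / 2
  purrr::map_dfr(colnames(particles$particles), function(nm) {
    x <- particles$particles[, nm]
    q <- weighted_quantile(x, particles$weights, c(a, 1 - a))
    tibble::tibble(
      parameter = nm,
      mean = sum(x * particles$weights),
      map = x[map_idx],
      ci_lower = q[1], ci_upper = q[2]
    )
  })
}

#' Posterior accuracy metrics against known truth
#'
#' For each parameter: the absolute error of the MAP estimate, the width of
#' the equal-tailed 95% credibility interval, and the distance from the true
#' value to the interval (zero when the interval contains the truth).
#'
#' @param particles A `particle_set`.
#' @param theta_true Named vector of true parameter values.
#' @param level Credibility level (default 0.95).
#' @return A tibble with `parameter`, `truth`, `map`, `map_abs_error`,
#'   `ci_lower`, `ci_upper`, `ci_width`, `ci_distance`.
#' @export
posterior_metrics <- function(particles, theta_true, level = 0.95) {
  s <- posterior_summary(particles, level)
  s$truth <- unname(unlist(theta_true)[s$parameter])
  dplyr::transmute(s,
    parameter = .data$parameter, truth = .data$truth, map = .data$map,
    map_abs_error = abs(.data$map - .data$truth),
    ci_lower = .data$ci_lower, ci_upper = .data$ci_upper,
    ci_width = .data$ci_upper - .data$ci_lower,
    ci_distance = pmax(0, .data$ci_lower - .data$truth,
                       .data$truth - .data$ci_upper)
  )
}

#' Posterior for a GLUT4 dataset
#'
#' Convenience wrapper: runs the tempered SMC sampler on the naive
#' lognormal likelihood of a GLUT4 timecourse.
#'
#' @param data A GLUT4 timecourse tibble.
#' @param sigma_Y Response standard deviation used in the likelihood
#'   (default: the generator value recorded in the metadata).
#' @param priors A [prior_spec()] (default [glut4_default_priors()]).
#' @param ... Passed to [run_smc()].
#' @return A `particle_set`.
#' @export
glut4_posterior <- function(data, sigma_Y = NULL,
                            priors = glut4_default_priors(), ...) {
  sigma_Y <- sigma_Y %||% timecourse_meta(data)$meta$sigma_Y
  if (is.null(sigma_Y) || sigma_Y <= 0) {
    abort("`sigma_Y` must be positive (a zero-noise dataset has a degenerate likelihood)")
  }
  run_smc(function(p) lognormal_loglik(p, data, sigma_Y), priors, ...)
}
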