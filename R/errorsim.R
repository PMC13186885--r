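## Error-model primitives and the five synthetic timecourse generators.
##
## Conventions, fixed across the package:
##  * normal timing errors are parameterised by their VARIANCE `var_u`;
##  * uniform timing errors by the support width `delta`, either biased
##    (support [0, delta], mean delta/2) or unbiased ([-delta/2, delta/2]);
##  * the response is always generated from the hidden true time, never from
##    the recorded protocol time.

#' Declare a timing-error mechanism
#'
#' An error spec describes how the observed independent variable `w` relates
#' to the true value `x`: classical error observes `w = x + u` (observations
#' scattered about the truth), Berkson error realises `x = w + u` (truth
#' scattered about the recorded/assigned value, typical of protocol times in
#' controlled experiments).
#'
#' @param kind `"classical"` or `"berkson"`.
#' @param distribution `"normal"` (specify `var_u`, the error variance) or
#'   `"uniform"` (specify `delta`, the support width).
#' @param var_u Variance of a normal error (>= 0).
#' @param delta Width of a uniform error's support (>= 0).
#' @param biased For uniform errors: if `TRUE` the support is `[0, delta]`
#'   (mean `delta/2`); if `FALSE`, `[-delta/2, delta/2]` (mean 0). Normal
#'   errors are always zero-mean here.
#' @return An `error_spec` object with a derived `bias` field (the error
#'   mean).
#' @examples
#' error_spec("classical", var_u = 0.25)
#' error_spec("berkson", "uniform", delta = 0.5, biased = TRUE)
#' @export
error_spec <- function(kind = c("classical", "berkson"),
                       distribution = c("normal", "uniform"),
                       var_u = NULL, delta = NULL, biased = FALSE) {
  kind <- match.arg(kind)
  distribution <- match.arg(distribution)
  if (distribution == "normal") {
    if (is.null(var_u)) abort("normal errors require `var_u` (a variance)")
    var_u <- check_finite(var_u, "var_u")
    if (var_u < 0) abort("`var_u` must be non-negative")
    delta <- NULL
    bias <- 0
  } else {
    if (is.null(delta)) abort("uniform errors require `delta` (support width)")
    delta <- check_finite(delta, "delta")
    if (delta < 0) abort("`delta` must be non-negative")
    var_u <- delta^2 / 12
    bias <- if (biased) delta / 2 else 0
  }
  structure(
    list(kind = kind, distribution = distribution, var_u = var_u,
         delta = delta, biased = isTRUE(biased), bias = bias),
    class = "error_spec"
  )
}

#' @export
print.error_spec <- function(x, ...) {
  cat("<error_spec: ", x$kind, ", ", x$distribution, sep = "")
  if (x$distribution == "normal") cat(", var_u = ", x$var_u, sep = "")
  else cat(", delta = ", x$delta, if (x$biased) " (biased)" else "", sep = "")
  cat(">\n")
  invisible(x)
}

draw_error <- function(spec, n) {
  if (spec$distribution == "normal") {
    rnorm(n, 0, sqrt(spec$var_u))
  } else if (spec$biased) {
    runif(n, 0, spec$delta)
  } else {
    runif(n, -spec$delta / 2, spec$delta / 2)
  }
}

#' Apply classical or Berkson timing error
#'
#' `draw_classical_observations()` contaminates true values `x` with iid
#' error to produce the observed `w = x + u`. `draw_berkson_truth()` realises
#' the hidden truth `x = w + u` around recorded protocol values `w` (which
#' stay the recorded values). Each draws from the ambient RNG stream; seed
#' with `set.seed()` (or `withr::with_seed()`) for reproducibility.
#'
#' @param x True values (classical case).
#' @param w Recorded protocol values (Berkson case).
#' @param spec An [error_spec()] of the matching kind; passing the wrong
#'   kind is an error, since the two mechanisms have opposite conditioning.
#' @return Numeric vector: observed values `w` (classical) or true values
#'   `x` (Berkson), same length as the input.
#' @export
draw_classical_observations <- function(x, spec) {
  stopifnot(inherits(spec, "error_spec"))
  if (spec$kind != "classical") {
    abort("`spec` is a Berkson spec; classical error observes w = x + u")
  }
  x + draw_error(spec, length(x))
}

#' @rdname draw_classical_observations
#' @export
draw_berkson_truth <- function(w, spec) {
  stopifnot(inherits(spec, "error_spec"))
  if (spec$kind != "berkson") {
    abort("`spec` is a classical spec; Berkson error realises x = w + u")
  }
  w + draw_error(spec, length(w))
}

## Sequential (correlated) delays -------------------------------------------

#' Cumulative measurement delays for sequentially measured subjects
#'
#' Models a lone experimentalist measuring `n_subjects` specimens one after
#' another on each protocol day: the duration of each measurement is iid
#' lognormal with original-scale mean `mean_duration` and standard deviation
#' `sd_duration` (days), and a subject's timing error is the cumulative sum
#' of the durations of all measurements up to and including its own. With
#' `ordering = "fixed"` the subjects are measured in index order every day;
#' `"random_per_day"` reshuffles the order independently each day.
#'
#' @param n_subjects,n_days Positive integers.
#' @param mean_duration Mean measurement duration, days (> 0).
#' @param sd_duration Standard deviation of the duration, days (>= 0); zero
#'   gives the degenerate constant duration.
#' @param ordering `"fixed"` or `"random_per_day"`.
#' @return An `n_subjects` x `n_days` matrix of delays `U[subject, day]`.
#' @examples
#' set.seed(1)
#' sequential_timing_errors(6, 3, 1 / 6, 0.1)
#' @export
sequential_timing_errors <- function(n_subjects, n_days,
                                     mean_duration = 1 / 6,
                                     sd_duration = 0.1,
                                     ordering = c("fixed", "random_per_day")) {
  ordering <- match.arg(ordering)
  stopifnot(n_subjects >= 1, n_days >= 1)
  if (mean_duration <= 0) abort("`mean_duration` must be positive")
  if (sd_duration < 0) abort("`sd_duration` must be non-negative")
  lp <- lognormal_from_moments(mean_duration, sd_duration^2)
  U <- matrix(0, n_subjects, n_days)
  for (j in seq_len(n_days)) {
    m <- rlnorm(n_subjects, lp$mu, sqrt(lp$sigma2))
    ord <- if (ordering == "fixed") seq_len(n_subjects) else sample.int(n_subjects)
    U[ord, j] <- cumsum(m)
  }
  U
}

## Timecourse container -----------------------------------------------------

new_timecourse <- function(df, design, meta = list()) {
  tib <- tibble::as_tibble(df)
  attr(tib, "timerr_design") <- design
  attr(tib, "timerr_meta") <- meta
  class(tib) <- unique(c("timecourse", class(tib)))
  tib
}

#' Coerce a tidy table to a timecourse dataset
#'
#' External datasets are accepted as tidy tables with columns `subject_id`,
#' `protocol_time` and `response`; a `true_time` column (hidden truth) is
#' present only for synthetic data and is filled with `NA` otherwise.
#'
#' @param df A data frame.
#' @param design Label describing the experimental design.
#' @return A tibble with class `timecourse`.
#' @export
as_timecourse <- function(df, design = "external") {
  need <- c("subject_id", "protocol_time", "response")
  if (!all(need %in% names(df))) {
    abort(paste("a timecourse needs columns", paste(need, collapse = ", ")))
  }
  if (!"true_time" %in% names(df)) df$true_time <- NA_real_
  if (anyNA(df$response) || any(!is.finite(df$protocol_time))) {
    abort("`response` must be complete and `protocol_time` finite")
  }
  new_timecourse(
    df[, c("subject_id", "protocol_time", "true_time", "response")],
    design
  )
}

#' Design metadata of a timecourse dataset
#'
#' @param data A timecourse tibble.
#' @return A list with elements `design` and `meta` (generator parameters).
#' @export
timecourse_meta <- function(data) {
  list(design = attr(data, "timerr_design"),
       meta = attr(data, "timerr_meta"))
}

## Generators ---------------------------------------------------------------

#' Simulate the linear-model designs
#'
#' Generates one synthetic dataset of the straight-line study
#' `y = beta0 + beta_x * x + eps`. Three designs are available:
#' non-controlled with classical error (`x ~ N(0, 1)` sampled, `w = x + u`),
#' non-controlled with Berkson error (`w ~ N(0, 1)` recorded, `x = w + u`),
#' and controlled with Berkson error (`w` at 5 equally spaced protocol
#' points on `[-2, 2]` with `n / 5` replicates each). Both the timing error
#' `u` and the error in the equation `eps` are zero-mean normal with the
#' given variances; the response is always computed from the hidden true
#' `x`.
#'
#' @param design One of `"noncontrolled_classical"`,
#'   `"noncontrolled_berkson"`, `"controlled_berkson"`.
#' @param n Number of observations (controlled design: divisible by 5).
#' @param params [linear_params()]; default slope 1, intercept 0.
#' @param var_u Timing-error variance (default 0.25).
#' @param var_eps Equation-error variance (default 0.25).
#' @return A `timecourse` tibble with hidden `true_time`.
#' @examples
#' set.seed(1)
#' generate_linear_dataset("noncontrolled_classical")
#' @export
generate_linear_dataset <- function(design = c("noncontrolled_classical",
                                               "noncontrolled_berkson",
                                               "controlled_berkson"),
                                    n = 50,
                                    params = linear_params(0, 1),
                                    var_u = 0.25, var_eps = 0.25) {
  design <- match.arg(design)
  stopifnot(n >= 2)
  if (design == "noncontrolled_classical") {
    x <- rnorm(n, 0, 1)
    w <- draw_classical_observations(x, error_spec("classical", var_u = var_u))
  } else {
    if (design == "controlled_berkson") {
      if (n %% 5 != 0) abort("controlled design needs `n` divisible by 5")
      w <- rep(seq(-2, 2, length.out = 5), each = n / 5)
    } else {
      w <- rnorm(n, 0, 1)
    }
    x <- draw_berkson_truth(w, error_spec("berkson", var_u = var_u))
  }
  y <- evaluate_model(params, x) + rnorm(n, 0, sqrt(var_eps))
  new_timecourse(
    tibble::tibble(subject_id = seq_len(n), protocol_time = w,
                   true_time = x, response = y),
    design,
    meta = list(model_id = "linear", params = params,
                var_u = var_u, var_eps = var_eps)
  )
}

#' Simulate the oscillator designs
#'
#' Generates one dataset of the cosine study `y = a * cos(b * x) + eps`,
#' true amplitude 3 and frequency 4 by default. Designs: non-controlled
#' classical (`x ~ U(-2, 2)`, `w = x + u`), non-controlled Berkson
#' (`w ~ U(-2, 2)`, `x = w + u`), controlled Case 1 (5 protocol points
#' equally spaced on `[-2, 2]`, 10 replicates each, Berkson error) and
#' controlled Case 2 (5 points equally spaced on `[-pi/2, pi/2]`, spacing
#' `pi/4`, which aligns every protocol point with a turning point of
#' `cos(4x)` so the amplitude is observed directly).
#'
#' @param design One of `"noncontrolled_classical"`,
#'   `"noncontrolled_berkson"`, `"controlled_case1"`, `"controlled_case2"`.
#' @param params [cosine_params()]; default `a = 3`, `b = 4`.
#' @param var_u,var_eps Timing and equation error variances (default 0.05
#'   each).
#' @param n Number of observations (default 50).
#' @return A `timecourse` tibble.
#' @export
generate_oscillation_dataset <- function(design = c("noncontrolled_classical",
                                                    "noncontrolled_berkson",
                                                    "controlled_case1",
                                                    "controlled_case2"),
                                         params = cosine_params(3, 4),
                                         var_u = 0.05, var_eps = 0.05,
                                         n = 50) {
  design <- match.arg(design)
  if (design == "noncontrolled_classical") {
    x <- runif(n, -2, 2)
    w <- draw_classical_observations(x, error_spec("classical", var_u = var_u))
  } else {
    w <- switch(design,
      noncontrolled_berkson = runif(n, -2, 2),
      controlled_case1 = rep(seq(-2, 2, length.out = 5), each = n / 5),
      controlled_case2 = rep(seq(-pi / 2, pi / 2, length.out = 5), each = n / 5)
    )
    x <- draw_berkson_truth(w, error_spec("berkson", var_u = var_u))
  }
  y <- evaluate_model(params, x) + rnorm(n, 0, sqrt(var_eps))
  new_timecourse(
    tibble::tibble(subject_id = seq_len(n), protocol_time = w,
                   true_time = x, response = y),
    design,
    meta = list(model_id = "cosine", params = params,
                var_u = var_u, var_eps = var_eps)
  )
}

#' Simulate the parasite-growth study
#'
#' One culture observed every second day until day 24 (protocol days
#' `{0, 2, ..., 24}`, 13 observations, a single observation per day). The
#' measurement is taken at a random time during the day but only the
#' protocol day is recorded (Berkson day-timing error
#' `t = w + u`, `u ~ N(0, sigma_U^2)`), and the response carries an
#' unbiased multiplicative equation error: `y = (1 + eps) * P(t)` with
#' `eps ~ N(0, sigma_eps^2)`. Negative responses at large `sigma_eps` are
#' kept (no censoring).
#'
#' @param params [parasite_params()]; defaults `V0 = 0.002`, `g = 0.531`,
#'   `B0 = 0.02`, `k = 0.323`.
#' @param sigma_U Standard deviation of the timing error, days (default
#'   0.25).
#' @param sigma_eps Standard deviation of the multiplicative factor
#'   (default 0).
#' @return A `timecourse` tibble with 13 rows.
#' @export
generate_parasite_dataset <- function(params = parasite_params(0.002, 0.531,
                                                               0.02, 0.323),
                                      sigma_U = 0.25, sigma_eps = 0) {
  if (sigma_U < 0 || sigma_eps < 0) abort("error SDs must be non-negative")
  w <- seq(0, 24, by = 2)
  t <- w + rnorm(length(w), 0, sigma_U)
  y <- (1 + rnorm(length(w), 0, sigma_eps)) * evaluate_model(params, t)
  new_timecourse(
    tibble::tibble(subject_id = 1L, protocol_time = w,
                   true_time = t, response = y),
    "parasite",
    meta = list(model_id = "parasite", params = params,
                sigma_U = sigma_U, sigma_eps = sigma_eps)
  )
}

#' Simulate a six-tumour Gompertz cohort
#'
#' Each tumour gets its own parameters (`y0 ~ U(100, 120)` mm^3,
#' `r ~ N(0.08, 0.02^2)` per day, `K = 4000` mm^3) and is measured every
#' second day for 60 days (protocol days `{0, 2, ..., 60}`, 31 per tumour).
#' Tumour volume is measured exactly (no equation error); all scatter comes
#' from between-tumour heterogeneity and, in the error scenarios, from
#' sequential measurement delays: tumours are measured one after another
#' each day and only the protocol day is recorded, so tumour `T`'s hidden
#' measurement time is the protocol day plus the cumulative lognormal
#' measurement durations of tumours up to and including `T`
#' (see [sequential_timing_errors()]). `"ordered"` uses the same measurement
#' sequence every day, `"random_order"` reshuffles it daily, `"perfect"`
#' has no delay (`t = w`).
#'
#' @param scenario `"perfect"`, `"ordered"` or `"random_order"`.
#' @param n_tumours Number of tumours (default 6).
#' @param mean_duration,sd_duration Lognormal measurement-duration moments,
#'   days (defaults 1/6 and 0.1).
#' @param K Carrying capacity, mm^3 (default 4000).
#' @return A `timecourse` tibble (`n_tumours * 31` rows) whose metadata
#'   records the per-tumour true parameters.
#' @export
generate_tumour_dataset <- function(scenario = c("perfect", "ordered",
                                                 "random_order"),
                                    n_tumours = 6,
                                    mean_duration = 1 / 6, sd_duration = 0.1,
                                    K = 4000) {
  scenario <- match.arg(scenario)
  w <- seq(0, 60, by = 2)
  y0 <- runif(n_tumours, 100, 120)
  r <- rnorm(n_tumours, 0.08, 0.02)
  U <- switch(scenario,
    perfect = matrix(0, n_tumours, length(w)),
    ordered = sequential_timing_errors(n_tumours, length(w), mean_duration,
                                       sd_duration, "fixed"),
    random_order = sequential_timing_errors(n_tumours, length(w),
                                            mean_duration, sd_duration,
                                            "random_per_day")
  )
  rows <- purrr::map_dfr(seq_len(n_tumours), function(i) {
    t <- w + U[i, ]
    tibble::tibble(
      subject_id = i, protocol_time = w, true_time = t,
      response = evaluate_model(gompertz_params(y0[i], r[i], K), t)
    )
  })
  new_timecourse(
    rows, paste0("tumour_", scenario),
    meta = list(
      model_id = "gompertz", scenario = scenario, K = K,
      mean_duration = mean_duration, sd_duration = sd_duration,
      true_params = tibble::tibble(subject_id = seq_len(n_tumours),
                                   y0 = y0, r = r, K = K)
    )
  )
}

#' Simulate the GLUT4 translocation study
#'
#' Replicated observations of plasma-membrane GLUT4 at the protocol times
#' `{0, 0.5, 1, 2, 5, 10, 15, 20, 25, 30, 45, 60}` minutes. Each replicate
#' at each protocol time has a hidden true time `t = w + u` with biased
#' uniform timing error `u ~ U(0, Delta)` (the stimulus is applied late,
#' never early), and the response is drawn from a lognormal distribution
#' moment-matched to mean `P(theta, t)` and variance `sigma_Y^2` (see
#' [lognormal_from_moments()]). `sigma_Y = 0` gives the noise-free response
#' exactly.
#'
#' @param params [glut4_params()]; defaults `P0 = 0.1`, `k = 0.1`, `M = 1`.
#' @param Delta Width of the uniform timing error, minutes (default 0).
#' @param sigma_Y Target standard deviation of the response (default 0).
#' @param n_rep Replicates per protocol time (default 1000).
#' @return A `timecourse` tibble with `12 * n_rep` rows; `subject_id` is
#'   the replicate index.
#' @export
generate_glut4_dataset <- function(params = glut4_params(0.1, 0.1, 1),
                                   Delta = 0, sigma_Y = 0, n_rep = 1000) {
  if (Delta < 0 || sigma_Y < 0) abort("`Delta` and `sigma_Y` must be non-negative")
  stopifnot(n_rep >= 1)
  w <- glut4_protocol_times()
  grid <- tidyr::expand_grid(subject_id = seq_len(n_rep), protocol_time = w)
  u <- if (Delta > 0) runif(nrow(grid), 0, Delta) else rep(0, nrow(grid))
  t <- grid$protocol_time + u
  mu_t <- evaluate_model(params, t)
  if (any(mu_t <= 0)) {
    abort("model mean must be positive for the lognormal parameterisation")
  }
  if (sigma_Y == 0) {
    y <- mu_t
  } else {
    lp <- lognormal_from_moments_vec(mu_t, sigma_Y^2)
    y <- rlnorm(nrow(grid), lp$mu, sqrt(lp$sigma2))
  }
  new_timecourse(
    tibble::tibble(subject_id = grid$subject_id,
                   protocol_time = grid$protocol_time,
                   true_time = t, response = y),
    "glut4",
    meta = list(model_id = "glut4", params = params,
                Delta = Delta, sigma_Y = sigma_Y, n_rep = n_rep)
  )
}

#' Protocol times of the GLUT4 study
#' @return Numeric vector of the 12 protocol times (minutes).
#' @export
glut4_protocol_times <- function() {
  c(0, 0.5, 1, 2, 5, 10, 15, 20, 25, 30, 45, 60)
}

## vectorised over the mean (scalar variance); used by the GLUT4 generator
## and likelihood, where every observation has its own model mean
lognormal_from_moments_vec <- function(target_mean, target_var) {
  m2 <- target_mean^2
  list(mu = log(m2 / sqrt(m2 + target_var)),
       sigma2 = log1p(target_var / m2))
}

## CSV + JSON sidecar -------------------------------------------------------

#' Write / read a timecourse dataset as CSV with a JSON sidecar
#'
#' The CSV holds the tidy columns (`subject_id`, `protocol_time`,
#' `true_time`, `response`); design label and generator parameters go to
#' `<path>.json`. Requires the jsonlite package.
#'
#' @param data A timecourse tibble.
#' @param path CSV file path.
#' @return `write_timecourse()` returns `path` invisibly;
#'   `read_timecourse()` returns a timecourse tibble.
#' @export
write_timecourse <- function(data, path) {
  rlang::check_installed("jsonlite")
  utils::write.csv(as.data.frame(data)[, c("subject_id", "protocol_time",
                                           "true_time", "response")],
                   path, row.names = FALSE)
  meta <- timecourse_meta(data)
  meta$meta$params <- if (!is.null(meta$meta$params)) {
    params_config(meta$meta$params)
  }
  meta$meta$true_params <- if (!is.null(meta$meta$true_params)) {
    as.data.frame(meta$meta$true_params)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  rlang::check_installed("jsonlite")
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  design <- "external"
  meta <- list()
  if (file.exists(sidecar)) {
    info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    design <- info$design %||% "external"
    meta <- info$meta %||% list()
    if (!is.null(meta$params)) meta$params <- params_from_config(meta$params)
  }
  new_timecourse(df, design, meta)
}
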