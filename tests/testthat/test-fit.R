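test_that("two exact points pin down the line exactly", {
  d <- as_timecourse(data.frame(subject_id = 1:2, protocol_time = c(0, 1),
                                response = c(0, 1)))
  f <- fit_least_squares(d, model_id = "linear")
  expect_equal(unname(f$theta_hat), c(0, 1), tolerance = 1e-10)
})

test_that("nonlinear least squares agrees with the closed-form OLS oracle", {
  set.seed(201)
  for (i in 1:5) {
    n <- 30
    x <- rnorm(n); y <- 0.5 + 2 * x + rnorm(n, 0, 0.7)
    d <- as_timecourse(data.frame(subject_id = seq_len(n), protocol_time = x,
                                  response = y))
    f <- fit_least_squares(d, model_id = "linear")
    o <- ols_oracle(x, y)
    expect_equal(f$theta_hat[["beta0"]], o$beta0, tolerance = 1e-8)
    expect_equal(f$theta_hat[["beta_x"]], o$beta_x, tolerance = 1e-8)
    ci <- f$ci
    expect_equal(ci$conf.low[ci$term == "beta_x"],
                 unname(o$ci["beta_x", 1]), tolerance = 1e-6)
    expect_equal(ci$conf.high[ci$term == "beta_x"],
                 unname(o$ci["beta_x", 2]), tolerance = 1e-6)
  }
})

test_that("noise-free data returns the generating parameters", {
  # parasite: all four parameters from starts at 1.5x truth
  d <- withr::with_seed(202, generate_parasite_dataset(sigma_U = 0, sigma_eps = 0))
  truth <- c(V0 = 0.002, g = 0.531, B0 = 0.02, k = 0.323)
  f <- fit_least_squares(d, init = truth * 1.5)
  expect_equal(f$theta_hat, truth, tolerance = 1e-4)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  # zero residuals give zero-width intervals
  expect_true(all(f$ci$conf.high - f$ci$conf.low < 1e-6))

  # gompertz: single noise-free trajectory
  tt <- seq(0, 60, 2)
  gp <- gompertz_params(110, 0.08, 4000)
  dg <- as_timecourse(data.frame(subject_id = 1, protocol_time = tt,
                                 response = evaluate_model(gp, tt)))
  fg <- fit_least_squares(dg, model_id = "gompertz",
                          init = c(y0 = 80, r = 0.12, K = 3000))
  expect_equal(fg$theta_hat[["r"]], 0.08, tolerance = 1e-5)
  expect_equal(fg$theta_hat[["K"]], 4000, tolerance = 1e-4)

  # glut4: noise-free protocol data
  dgl <- generate_glut4_dataset(Delta = 0, sigma_Y = 0, n_rep = 1)
  fgl <- fit_least_squares(dgl, init = c(P0 = 0.3, k = 0.2, M = 2))
  expect_equal(fgl$theta_hat, c(P0 = 0.1, k = 0.1, M = 1), tolerance = 1e-5)
})

test_that("confidence intervals achieve nominal coverage on the controlled design", {
  set.seed(203)
  hits <- replicate(400, {
    d <- generate_linear_dataset("controlled_berkson")
    ci <- fit_least_squares(d, time = "true")$ci
    ci$conf.low[2] <= 1 && 1 <= ci$conf.high[2]
  })
  cover <- mean(hits)
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / 400))
})

test_that("classical error attenuates the naive slope by the reliability ratio", {
  set.seed(204)
  slopes <- replicate(600, {
    d <- generate_linear_dataset("noncontrolled_classical")
    fit_least_squares(d)$theta_hat[["beta_x"]]
  })
  lambda <- reliability_ratio(1, 0.25)
  expect_equal(lambda, 0.8)
  expect_lt(abs(mean(slopes) - lambda * 1), 3 * sd(slopes) / sqrt(600))
})

test_that("timing error attenuates the fitted amplitude as exp(-b^2 var_u / 2)", {
  set.seed(205)
  ah <- replicate(400, {
    d <- generate_oscillation_dataset("controlled_case2")
    fit_least_squares(d, free = "a", fixed = c(b = 4),
                      init = c(a = 1))$theta_hat[["a"]]
  })
  oracle <- 3 * exp(-8 * 0.05)  # E[cos(4U)] = exp(-16 var_u / 2)
  expect_lt(abs(mean(ah) - oracle), 3 * sd(ah) / sqrt(400))
  expect_lt(mean(ah), 3)
})

test_that("gaussian_nll implements the closed-form negative log-likelihood", {
  d <- as_timecourse(data.frame(subject_id = 1, protocol_time = 1,
                                response = 2))
  # single observation, zero residual, unit variance
  expect_equal(gaussian_nll(c(beta0 = 0, beta_x = 2), d, 1,
                            model_id = "linear"),
               0.9189385332, tolerance = 1e-9)

  set.seed(206)
  dl <- generate_linear_dataset("noncontrolled_classical")
  th <- c(beta0 = 0.1, beta_x = 0.9)
  base <- gaussian_nll(th, dl, 0.25)
  n <- nrow(dl)
  # doubling residuals quadruples the quadratic term
  dl2 <- dl
  res <- dl$response - evaluate_model(th, dl$protocol_time, model_id = "linear")
  dl2$response <- dl$response + res
  quad <- function(nll) nll - n * 0.5 * log(2 * pi * 0.25)
  expect_equal(quad(gaussian_nll(th, dl2, 0.25)), 4 * quad(base),
               tolerance = 1e-10)

  # the constant-variance argmin coincides with least squares
  f <- fit_least_squares(dl)
  at <- function(b) gaussian_nll(c(beta0 = f$theta_hat[["beta0"]], beta_x = b),
                                 dl, 0.25)
  b_hat <- f$theta_hat[["beta_x"]]
  expect_lt(at(b_hat), at(b_hat + 0.01))
  expect_lt(at(b_hat), at(b_hat - 0.01))
  expect_error(gaussian_nll(th, dl, 0), "positive")
})

test_that("kde integrates to one and tracks the true density", {
  set.seed(207)
  x <- rnorm(1e5)
  dens <- kde(x, grid = seq(-6, 6, length.out = 601))
  dx <- diff(dens$x[1:2])
  integral <- sum((dens$density[-1] + dens$density[-601]) / 2 * dx)
  expect_lt(abs(integral - 1), 1e-3)
  expect_lt(abs(sum(dens$x * dens$density * dx) - mean(x)), 0.01)
  expect_lt(max(abs(dens$density - dnorm(dens$x))), 0.02)
  expect_warning(kde(rep(1, 10)), "degenerate")
  expect_error(kde(1), "at least two")
})

test_that("goodness of fit spans the perfect and mean-only extremes", {
  d <- withr::with_seed(208,
    generate_parasite_dataset(sigma_U = 0, sigma_eps = 0))
  f <- fit_least_squares(d)
  expect_equal(round(goodness_of_fit(f)$r2, 4), 1)

  dl <- withr::with_seed(209, generate_linear_dataset("noncontrolled_classical"))
  fm <- fit_least_squares(dl, free = "beta0", fixed = c(beta_x = 0))
  expect_equal(goodness_of_fit(fm)$r2, 0, tolerance = 1e-8)
})

test_that("tidy and glance expose broom-style summaries", {
  d <- withr::with_seed(210, generate_parasite_dataset())
  f <- fit_least_squares(d, free = c("V0", "g"),
                         fixed = c(B0 = 0.02, k = 0.323))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$term, c("V0", "g"))
  gl <- glance(f)
  expect_equal(gl$nobs, 13)
  expect_true(gl$converged)
})

test_that("per-subject fitting returns one block per subject", {
  d <- withr::with_seed(211, generate_tumour_dataset("perfect", n_tumours = 3))
  res <- fit_subjects(d, free = c("y0", "r", "K"))
  expect_equal(nrow(res), 9)
  expect_setequal(unique(res$subject_id), 1:3)
  truth <- timecourse_meta(d)$meta$true_params
  r1 <- res$estimate[res$subject_id == 1 & res$term == "r"]
  expect_equal(r1, truth$r[1], tolerance = 1e-5)
})
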