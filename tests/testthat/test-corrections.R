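test_that("reliability ratio corrects the attenuated linear slope", {
  expect_equal(reliability_ratio(1, 0.25), 0.8)
  expect_equal(reliability_ratio(2, 0), 1)
  expect_equal(correct_slope(0.8431, 0.8), 1.053875)
  expect_equal(correct_slope(1.3, 1), 1.3)
  expect_error(reliability_ratio(0, 0.1), "positive")
  expect_error(correct_slope(1, 1.2), "lie in")
})

test_that("the variance inequality flips only in the predicted direction", {
  # the linear-study configuration does not satisfy it
  expect_false(variance_inequality_holds(1, 1, 0.25, 0.25))
  # a flat slope with any equation error does
  expect_true(variance_inequality_holds(0, 1, 0.25, 0.25))
  # increasing sigma_u2 can only switch false -> true, never back
  for (i in 1:20) {
    set.seed(400 + i)
    b <- runif(1, -2, 2); sx <- runif(1, 0.5, 2); se <- runif(1, 0, 1)
    vals <- vapply(seq(0, 3, length.out = 10), function(su) {
      variance_inequality_holds(b, sx, su, se)
    }, logical(1))
    expect_true(all(diff(as.integer(vals)) >= 0))
  }
})

test_that("Fuller's estimator reduces to OLS and obeys its algebraic identity", {
  set.seed(401)
  w <- rnorm(100); y <- 1 + 2 * w + rnorm(100, 0, 0.5)
  f0 <- fuller_moment_fit(w, y, 0)
  o <- ols_oracle(w, y)
  expect_equal(f0$estimate[f0$term == "beta_x"], o$beta_x, tolerance = 1e-12)
  expect_equal(f0$estimate[f0$term == "beta0"], o$beta0, tolerance = 1e-12)

  for (i in 1:5) {
    set.seed(402 + i)
    w <- rnorm(60, 1, 1.3); y <- 0.3 * w + rnorm(60, 0, 0.4)
    su2 <- runif(1, 0, 0.5 * var(w))
    ff <- fuller_moment_fit(w, y, su2)
    naive <- ols_oracle(w, y)$beta_x
    expect_equal(ff$estimate[ff$term == "beta_x"],
                 naive * var(w) / (var(w) - su2), tolerance = 1e-12)
  }
  expect_error(fuller_moment_fit(rnorm(20), rnorm(20), 100), "degenerate")
})

test_that("Fuller's estimator is consistent on the classical linear design", {
  set.seed(403)
  est <- replicate(50, {
    x <- rnorm(2000); u <- rnorm(2000, 0, 0.5)
    y <- x + rnorm(2000, 0, 0.5)
    f <- fuller_moment_fit(x + u, y, 0.25)
    f$estimate[f$term == "beta_x"]
  })
  expect_lt(abs(mean(est) - 1), 3 * sd(est) / sqrt(50))
})

test_that("regression calibration shrinks towards the mean, identity for Berkson", {
  w <- c(-1, 0, 2, 5)
  expect_equal(regression_calibration(w, 1), w)           # unbiased Berkson
  expect_equal(regression_calibration(w, 0.5, mu_x = 0), w / 2)
  expect_equal(regression_calibration(rep(3, 4), 0.2, mu_x = 3), rep(3, 4))
  expect_error(regression_calibration(w, 1.5), "lie in")
})

test_that("orthogonal regression matches the closed-form Deming solution", {
  set.seed(404)
  x <- rnorm(50); w <- x + rnorm(50, 0, 0.4)
  y <- 1 + 2 * x + rnorm(50, 0, 0.4)
  d <- as_timecourse(data.frame(subject_id = 1:50, protocol_time = w,
                                response = y))
  of <- orthogonal_regression_fit(d, eta = 2, model_id = "linear")
  dm <- deming_oracle(w, y, 2)
  expect_equal(of$theta_hat[["beta_x"]], dm[["beta_x"]], tolerance = 1e-8)
  expect_equal(of$theta_hat[["beta0"]], dm[["beta0"]], tolerance = 1e-8)

  # objective never exceeds the naive SSR evaluated at x = w
  naive <- fit_least_squares(d, model_id = "linear")
  expect_lte(of$objective, sum(naive$residuals^2) + 1e-8)

  # eta -> infinity pins x to w and recovers OLS
  of_big <- orthogonal_regression_fit(d, eta = 1e12, model_id = "linear")
  expect_equal(of_big$theta_hat[["beta_x"]], naive$theta_hat[["beta_x"]],
               tolerance = 1e-5)
  expect_lt(max(abs(of_big$x_hat - w)), 1e-6)

  # noise-free data: exact parameters, x = w
  d0 <- as_timecourse(data.frame(subject_id = 1:10, protocol_time = 1:10,
                                 response = 2 * (1:10) + 1))
  of0 <- orthogonal_regression_fit(d0, eta = 3, model_id = "linear")
  expect_equal(unname(of0$theta_hat), c(1, 2), tolerance = 1e-8)
  expect_equal(of0$x_hat, as.numeric(1:10), tolerance = 1e-8)

  # eta = 1 carries the documented scale-dependence warning
  expect_warning(orthogonal_regression_fit(d, eta = 1, model_id = "linear"),
                 "scale")
})

test_that("eta = 1 orthogonal regression is scale-dependent", {
  set.seed(405)
  x <- rnorm(80); w <- x + rnorm(80, 0, 0.5)
  y <- x + rnorm(80, 0, 0.5)
  d1 <- as_timecourse(data.frame(subject_id = 1:80, protocol_time = w,
                                 response = y))
  d10 <- as_timecourse(data.frame(subject_id = 1:80, protocol_time = w,
                                  response = 10 * y))
  s1 <- suppressWarnings(
    orthogonal_regression_fit(d1, 1, model_id = "linear")
  )$theta_hat[["beta_x"]]
  s10 <- suppressWarnings(
    orthogonal_regression_fit(d10, 1, model_id = "linear")
  )$theta_hat[["beta_x"]] / 10
  expect_gt(abs(s1 - s10), 0.01)  # rescaling the response changes the answer
})

test_that("SIMEX degenerates to the naive fit at zero error variance", {
  set.seed(406)
  w <- rnorm(200); y <- 2 * w + rnorm(200, 0.2)
  sx <- simex(w, y, ols_estimator, 0)
  expect_identical(sx$estimates, ols_estimator(w, y))
})

test_that("the SIMEX trajectory attenuates monotonically and extrapolates back", {
  set.seed(407)
  x <- rnorm(4000); w <- x + rnorm(4000, 0, 0.5)
  y <- x + rnorm(4000, 0, 0.5)
  sx <- simex(w, y, ols_estimator, 0.25, B = 40,
              extrapolant = "rational_linear")
  path <- sx$trajectory$estimate[sx$trajectory$term == "beta_x"]
  expect_true(all(diff(path) < 0))  # increasing zeta shrinks a positive slope
  naive <- sx$naive[["beta_x"]]
  expect_lt(abs(sx$estimates[["beta_x"]] - 1), abs(naive - 1))
  expect_lt(abs(sx$estimates[["beta_x"]] - 1), 0.06)
})

test_that("the measurement-error likelihood collapses to the naive one", {
  set.seed(408)
  d <- generate_oscillation_dataset("controlled_case2")
  th <- c(a = 2.5, b = 4)
  naive <- -gaussian_nll(th, d, 0.05)
  expect_equal(me_likelihood(th, d, error_spec("berkson", var_u = 0), 0.05),
               naive, tolerance = 1e-8)
  # continuity of the classical joint form as var_u -> 0
  xd <- list(mean = 0, var = 1)
  at0 <- me_likelihood(th, d, error_spec("classical", var_u = 0), 0.05,
                       x_density = xd)
  near0 <- me_likelihood(th, d, error_spec("classical", var_u = 1e-12), 0.05,
                         x_density = xd)
  expect_equal(near0, at0, tolerance = 1e-6)
})

test_that("quadrature agrees with adaptive integration on random configurations", {
  set.seed(409)
  for (i in 1:10) {
    b0 <- runif(1, -1, 1); bx <- runif(1, 0.5, 2)
    w <- runif(1, -2, 2); yv <- runif(1, -2, 2)
    vu <- runif(1, 0.05, 0.3); ve <- runif(1, 0.2, 1)
    d <- as_timecourse(data.frame(subject_id = 1, protocol_time = w,
                                  response = yv))
    th <- c(beta0 = b0, beta_x = bx)
    got <- me_likelihood(th, d, error_spec("berkson", var_u = vu), ve,
                         model_id = "linear")
    oracle <- log(stats::integrate(function(x) {
      dnorm(yv, b0 + bx * x, sqrt(ve)) * dnorm(x, w, sqrt(vu))
    }, -Inf, Inf, rel.tol = 1e-12)$value)
    expect_lt(abs(got - oracle), 1e-6)

    # classical joint density against the same oracle
    xd <- list(mean = 0.3, var = 1.2)
    gotc <- me_likelihood(th, d, error_spec("classical", var_u = vu), ve,
                          model_id = "linear", x_density = xd)
    oraclec <- log(stats::integrate(function(x) {
      dnorm(yv, b0 + bx * x, sqrt(ve)) * dnorm(w, x, sqrt(vu)) *
        dnorm(x, xd$mean, sqrt(xd$var))
    }, -Inf, Inf, rel.tol = 1e-12)$value)
    expect_lt(abs(gotc - oraclec), 1e-6)
  }
})

test_that("the Berkson likelihood ignores the location of the design points", {
  # linear model: shifting w (and compensating the intercept) leaves the
  # per-point observed-data density unchanged for a location-family error
  set.seed(410)
  d <- generate_linear_dataset("controlled_berkson")
  th <- c(beta0 = 0.2, beta_x = 0.9)
  base <- me_likelihood(th, d, error_spec("berkson", var_u = 0.25), 0.25)
  shift <- 5
  d2 <- d
  d2$protocol_time <- d$protocol_time + shift
  th2 <- c(beta0 = 0.2 - 0.9 * shift, beta_x = 0.9)
  expect_equal(me_likelihood(th2, d2, error_spec("berkson", var_u = 0.25),
                             0.25),
               base, tolerance = 1e-8)
})

test_that("misuse of the likelihood specs is rejected", {
  d <- withr::with_seed(411, generate_oscillation_dataset("controlled_case2"))
  th <- c(a = 3, b = 4)
  expect_error(
    me_likelihood(th, d, error_spec("classical", var_u = 0.05), 0.05),
    "x_density"
  )
  expect_error(
    me_likelihood(th, d, error_spec("berkson", var_u = 0.05), 0.05,
                  x_density = list(mean = 0, var = 1)),
    "must not"
  )
  expect_error(
    me_likelihood(th, d, error_spec("berkson", var_u = 0.05), 0),
    "positive"
  )
})

test_that("the method selector ranks corrections by scenario", {
  r1 <- select_correction_method("linear", "none", TRUE, "classical", FALSE)
  expect_equal(r1$method[1:3],
               c("reliability ratio", "Fuller's method of moments", "SIMEX"))
  r2 <- select_correction_method("nonlinear", "none", FALSE, "berkson", TRUE)
  expect_equal(r2$method[1], "Berkson measurement-error likelihood")
  r3 <- select_correction_method("glm", "replicates", FALSE, "classical", FALSE)
  expect_equal(r3$method[1], "regression calibration")
  r4 <- select_correction_method("nonlinear", "none", FALSE, "classical", FALSE)
  expect_equal(r4$method[1], "collect additional data")
  expect_equal(r1$rank, seq_len(nrow(r1)))
})
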