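test_that("classical and Berkson draws respect their conditioning", {
  x <- 1:10 / 2
  expect_identical(draw_classical_observations(x, error_spec("classical", var_u = 0)), x)
  expect_identical(draw_berkson_truth(x, error_spec("berkson", var_u = 0)), x)
  expect_error(
    draw_classical_observations(x, error_spec("berkson", var_u = 0.1)),
    "Berkson"
  )
  expect_error(
    draw_berkson_truth(x, error_spec("classical", var_u = 0.1)),
    "classical"
  )
})

test_that("error draws match their specified moments", {
  set.seed(101)
  n <- 1e5
  x <- rnorm(n)
  w <- draw_classical_observations(x, error_spec("classical", var_u = 0.25))
  u <- w - x
  expect_lt(abs(mean(u)), 3 * 0.5 / sqrt(n))
  expect_lt(abs(var(u) - 0.25), 3 * 0.25 * sqrt(2 / (n - 1)))

  xb <- draw_berkson_truth(rep(2, n), error_spec("berkson", var_u = 0.09))
  expect_lt(abs(var(xb - 2) - 0.09), 3 * 0.09 * sqrt(2 / (n - 1)))

  xu <- draw_berkson_truth(rep(0, n),
                           error_spec("berkson", "uniform", delta = 0.7,
                                      biased = TRUE))
  expect_true(all(xu >= 0 & xu <= 0.7))
  expect_lt(abs(mean(xu) - 0.35), 3 * 0.7 / sqrt(12 * n))
})

test_that("sequential delays cumulate measurement durations", {
  # degenerate durations: subject T is delayed exactly T * mu
  U <- sequential_timing_errors(6, 4, mean_duration = 1 / 6, sd_duration = 0)
  expect_equal(U, outer(1:6, rep(1, 4)) / 6)
  expect_equal(U[6, 1], 1)

  set.seed(102)
  U <- sequential_timing_errors(6, 31, 1 / 6, 0.1, "fixed")
  expect_true(all(apply(U, 2, diff) > 0))

  # first-measured subject's delay is one lognormal duration
  set.seed(103)
  m1 <- replicate(2e4, sequential_timing_errors(1, 1, 1 / 6, 0.1)[1, 1])
  expect_lt(abs(mean(m1) - 1 / 6), 3 * 0.1 / sqrt(2e4))

  # random ordering breaks the fixed subject-order monotonicity on some day
  set.seed(104)
  Ur <- sequential_timing_errors(6, 30, 1 / 6, 0.1, "random_per_day")
  expect_false(all(apply(Ur, 2, function(col) all(diff(col) > 0))))
})

test_that("linear designs have the stated structure", {
  set.seed(105)
  d0 <- generate_linear_dataset("noncontrolled_classical", var_u = 0,
                                var_eps = 0)
  f <- ols_oracle(d0$protocol_time, d0$response)
  expect_equal(f$beta_x, 1, tolerance = 1e-12)
  expect_equal(f$beta0, 0, tolerance = 1e-12)

  d <- generate_linear_dataset("controlled_berkson")
  expect_setequal(unique(d$protocol_time), c(-2, -1, 0, 1, 2))
  expect_true(all(table(d$protocol_time) == 10))
  expect_equal(length(unique(d$true_time)), 50)
  expect_error(generate_linear_dataset("controlled_berkson", n = 48),
               "divisible")
})

test_that("oscillator case 2 observes the amplitude directly without error", {
  set.seed(106)
  d <- generate_oscillation_dataset("controlled_case2", var_u = 0, var_eps = 0)
  expect_true(all(abs(abs(d$response) - 3) < 1e-12))
  # protocol points spaced pi/4 on [-pi/2, pi/2]
  expect_equal(sort(unique(d$protocol_time)),
               seq(-pi / 2, pi / 2, by = pi / 4))
})

test_that("parasite datasets record only the protocol day", {
  set.seed(107)
  d <- generate_parasite_dataset(sigma_U = 0.4, sigma_eps = 0.1)
  expect_equal(d$protocol_time, seq(0, 24, by = 2))
  expect_equal(nrow(d), 13)

  d0 <- generate_parasite_dataset(sigma_U = 0, sigma_eps = 0)
  p <- parasite_params(0.002, 0.531, 0.02, 0.323)
  expect_equal(d0$response, evaluate_model(p, d0$protocol_time))

  # multiplicative-error scale recovered from relative residuals
  set.seed(108)
  rel <- unlist(replicate(300, {
    dd <- generate_parasite_dataset(sigma_U = 0, sigma_eps = 0.1)
    dd$response / evaluate_model(p, dd$protocol_time) - 1
  }, simplify = FALSE))
  expect_lt(abs(sd(rel) - 0.1), 3 * 0.1 / sqrt(2 * length(rel)))
})

test_that("tumour cohorts carry their hidden truth consistently", {
  set.seed(109)
  d <- generate_tumour_dataset("perfect")
  expect_equal(nrow(d), 186)
  expect_equal(d$true_time, d$protocol_time)

  set.seed(110)
  d <- generate_tumour_dataset("ordered")
  delays <- matrix(d$true_time - d$protocol_time, nrow = 31)
  expect_true(all(apply(delays, 1, diff) > 0))  # increasing in tumour index

  # response is an exact function of the hidden truth (no equation error)
  truth <- timecourse_meta(d)$meta$true_params
  for (i in 1:6) {
    rows <- d[d$subject_id == i, ]
    expect_identical(
      rows$response,
      evaluate_model(gompertz_params(truth$y0[i], truth$r[i], truth$K[i]),
                     rows$true_time)
    )
  }
})

test_that("GLUT4 datasets follow the biased uniform timing model", {
  d0 <- generate_glut4_dataset(Delta = 0, sigma_Y = 0, n_rep = 3)
  expect_equal(nrow(d0), 36)
  p <- glut4_params(0.1, 0.1, 1)
  expect_equal(d0$response, evaluate_model(p, d0$protocol_time))

  set.seed(111)
  d <- generate_glut4_dataset(Delta = 0.8, sigma_Y = 0.05, n_rep = 20)
  u <- d$true_time - d$protocol_time
  expect_true(all(u >= 0 & u <= 0.8))

  # lognormal mean construction: sample mean converges to the model mean
  set.seed(112)
  d2 <- generate_glut4_dataset(Delta = 0, sigma_Y = 0.2, n_rep = 5000)
  y60 <- d2$response[d2$protocol_time == 60]
  expect_lt(abs(mean(y60) - evaluate_model(p, 60)), 3 * 0.2 / sqrt(5000))
})

test_that("generators are deterministic under a fixed seed", {
  gens <- list(
    function() generate_linear_dataset("noncontrolled_classical"),
    function() generate_oscillation_dataset("controlled_case2"),
    function() generate_parasite_dataset(),
    function() generate_tumour_dataset("random_order"),
    function() generate_glut4_dataset(Delta = 0.5, sigma_Y = 0.1, n_rep = 5)
  )
  for (g in gens) {
    a <- withr::with_seed(31, g())
    b <- withr::with_seed(31, g())
    expect_identical(a, b)
  }
})

test_that("external tables coerce to timecourses with hidden truth optional", {
  ext <- data.frame(subject_id = 1:3, protocol_time = c(0, 1, 2),
                    response = c(1, 2, 3))
  d <- as_timecourse(ext)
  expect_true(all(is.na(d$true_time)))
  expect_error(fit_least_squares(d, model_id = "linear", time = "true"),
               "true_time")
  expect_error(as_timecourse(data.frame(protocol_time = 1, response = 2)),
               "subject_id")
})

test_that("timecourses round-trip through CSV with a JSON sidecar", {
  skip_if_not_installed("jsonlite")
  set.seed(113)
  d <- generate_parasite_dataset()
  path <- file.path(withr::local_tempdir(), "parasite.csv")
  write_timecourse(d, path)
  d2 <- read_timecourse(path)
  expect_equal(tibble::as_tibble(d2)[, 1:4], tibble::as_tibble(d)[, 1:4])
  expect_equal(timecourse_meta(d2)$design, "parasite")
  expect_equal(timecourse_meta(d2)$meta$params$g, 0.531)
})
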