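# Independent oracles used across the tests.

# closed-form simple linear regression with textbook t-intervals
ols_oracle <- function(x, y, level = 0.95) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  se1 <- sqrt(s2 / sxx)
  se0 <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  tq <- qt((1 + level) / 2, n - 2)
  list(beta0 = b0, beta_x = b1, se = c(beta0 = se0, beta_x = se1),
       ci = rbind(beta0 = c(b0 - tq * se0, b0 + tq * se0),
                  beta_x = c(b1 - tq * se1, b1 + tq * se1)))
}

# fast OLS estimator used as the SIMEX "naive fitter" on large designs
ols_estimator <- function(w, y) {
  cf <- stats::coef(stats::lm.fit(cbind(1, w), y))
  c(beta0 = cf[[1]], beta_x = cf[[2]])
}

# closed-form Deming slope for the objective
# sum((y - b0 - b1 x)^2 + delta (w - x)^2)
deming_oracle <- function(w, y, delta) {
  sxx <- var(w); syy <- var(y); sxy <- cov(w, y)
  b1 <- (syy - delta * sxx +
           sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) / (2 * sxy)
  c(beta0 = mean(y) - b1 * mean(w), beta_x = b1)
}

# amplitude estimate in closed form when only `a` is free (linear in a)
amplitude_oracle <- function(t, y, b = 4) {
  cc <- cos(b * t)
  sum(y * cc) / sum(cc^2)
}

# the reference pooled tumour fit configuration:
# shared (r, K), y0 fixed to the mean day-0 response
fit_tumour_pooled_for_test <- function(d) {
  y0 <- mean(d$response[d$protocol_time == 0])
  fit_least_squares(d, free = c("r", "K"), fixed = c(y0 = y0),
                    init = c(r = 0.1, K = max(d$response) * 1.5))
}
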