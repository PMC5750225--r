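conc12 <- c(10, 20, 40, 80, 150, 300, 600, 1000, 1500, 2000, 2500, 3000)

test_that("a noiseless binding curve recovers the dissociation constant exactly", {
  cur <- simulate_binding_curve(curve_config(300, conc12, 0.05, 0.25, noise_sd = 0))
  fit <- fit_kd(cur$conc, cur$anisotropy)
  expect_true(fit$converged)
  expect_lt(abs(fit$param - 300) / 300, 1e-6)
  expect_lt(abs(fit$floor - 0.05), 1e-6)
  expect_lt(abs(fit$ceiling - 0.25), 1e-6)
  ## model identity: fitted value at P = Kd is the floor/ceiling midpoint
  expect_equal(predict(fit, fit$param), (fit$floor + fit$ceiling) / 2)
  expect_equal(unname(coef(fit)["Kd"]), fit$param)
})

test_that("Kd estimates are invariant to affine rescaling of the signal", {
  cur <- simulate_binding_curve(curve_config(250, conc12, 0.05, 0.25,
                                             noise_sd = 0.003, seed = 8L))
  f1 <- fit_kd(cur$conc, cur$anisotropy)
  f2 <- fit_kd(cur$conc, 40 * cur$anisotropy + 7)
  expect_lt(abs(f1$param - f2$param) / f1$param, 1e-5)
})

test_that("noisy curves recover the dissociation constant within tolerance", {
  err <- vapply(1:20, function(s) {
    cur <- simulate_binding_curve(curve_config(300, conc12, 0.05, 0.25,
                                               noise_sd = 0.02 * 0.2, seed = s))
    abs(fit_kd(cur$conc, cur$anisotropy)$param - 300) / 300
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("the quadratic depletion model matches its own generating form", {
  R <- 50  # deliberately non-negligible probe
  kd <- 200
  P <- conc12
  frac <- ((kd + P + R) - sqrt((kd + P + R)^2 - 4 * P * R)) / (2 * R)
  y <- 0.05 + 0.2 * frac
  fit <- fit_kd(P, y, probe_conc = R, model = "quadratic")
  expect_lt(abs(fit$param - kd) / kd, 1e-4)
})

test_that("bootstrap standard errors shrink with the noise level", {
  se <- vapply(c(0.01, 0.002), function(ns) {
    cur <- simulate_binding_curve(curve_config(300, conc12, 0.05, 0.25,
                                               noise_sd = ns, seed = 5L))
    fit_kd(cur$conc, cur$anisotropy, n_boot = 60L, seed = 6L)$stderr
  }, numeric(1))
  expect_lt(se[2], se[1])
})

test_that("percent remaining normalises to the time-zero intensity", {
  pr <- percent_remaining(c(0, 1, 2), c(80, 40, 20))
  expect_equal(pr$percent_remaining, c(100, 50, 25))
  expect_equal(percent_remaining(c(0, 1), c(5, 5))$percent_remaining, c(100, 100))
  ## halving intensities halves nothing after normalisation
  expect_equal(percent_remaining(c(0, 1, 2), c(40, 20, 10))$percent_remaining,
               pr$percent_remaining)
  expect_error(percent_remaining(c(0, 1), c(0, 1)), "positive")
  expect_error(percent_remaining(c(1, 2), c(5, 3)), "time point must be 0")
})

test_that("an exact decay series recovers its half-life", {
  tt <- c(0, 0.5, 1, 2, 3, 6, 24)
  cur <- simulate_decay(curve_config(18, tt[-1], y_ceiling = 100, noise_sd = 0))
  fit <- fit_half_life(c(0, cur$time), c(100, cur$intensity))
  expect_false(fit$censored)
  expect_lt(abs(fit$param - 18) / 18, 1e-6)
  expect_equal(unname(coef(fit)["t_half"]), fit$param)
})

test_that("the nonlinear decay fit never does worse than its log-linear seed", {
  set.seed(51)
  tt <- c(0, 0.5, 1, 2, 3, 6, 24)
  y <- 100 * 2^(-tt / 18) + rnorm(7, 0, 5)
  y <- pmax(y, 1)
  fit <- fit_half_life(tt, y)
  lmfit <- lm(log(y) ~ tt)
  ## the seed solution as documented: th0 = -log(2)/slope, y0 = exp(intercept)
  th0 <- -log(2) / coef(lmfit)[2]
  seed_ss <- sum((y - exp(coef(lmfit)[1]) * 2^(-tt / th0))^2)
  expect_lte(fit$residual_ss, seed_ss + 1e-9)
})

test_that("the relative error model recovers half-lives under constant-CV noise", {
  grid <- c(0, 0.5, 1, 2, 3, 6, 24)
  cur <- simulate_decay(curve_config(18, grid, y_ceiling = 100, noise_sd = 0,
                                     n_replicates = 2L))
  o <- order(cur$time)
  fit <- fit_half_life(cur$time[o], cur$intensity[o], error_model = "relative")
  expect_lt(abs(fit$param - 18) / 18, 1e-6)
  err <- vapply(1:20, function(s) {
    cur <- simulate_decay(curve_config(18, grid, y_ceiling = 100,
                                       noise_sd = 0.05,
                                       noise_type = "proportional",
                                       n_replicates = 3L, seed = s))
    o <- order(cur$time)
    abs(fit_half_life(cur$time[o], cur$intensity[o],
                      error_model = "relative")$param - 18) / 18
  }, numeric(1))
  expect_lt(median(err), 0.06)
})

test_that("flat or rising series yield a censored lower bound, not an estimate", {
  fit <- fit_half_life(c(0, 1, 3, 6, 24), c(100, 101, 99, 100, 98))
  expect_true(fit$censored)
  expect_true(is.na(fit$param))
  expect_equal(fit$lower_bound, 24)
  rising <- fit_half_life(c(0, 2, 4, 8), c(100, 110, 120, 130))
  expect_true(rising$censored)
  expect_error(fit_half_life(c(0, 1, 2), c(3, 2, 1)), "4 time points")
})
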