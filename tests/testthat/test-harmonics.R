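test_that("noiseless signals in the model class are recovered exactly", {
  T <- 10
  tt <- seq(0, T - T / 600, length.out = 600)
  y <- 0.5 + 0.1 * sin(2 * pi * (tt - 0.25 * T) / T)
  fit <- fit_harmonics(tt, y, T)
  expect_equal(fit$A0, 0.5, tolerance = 1e-10)
  expect_equal(fit$A[1], 0.1, tolerance = 1e-10)
  expect_equal(fit$tau_frac[1], 0.25, tolerance = 1e-10)
  expect_lt(max(fit$A[2:4]), 1e-12)
  expect_lt(fit$residual_rms, 1e-12)

  # constant signal
  fitc <- fit_harmonics(tt, rep(0.42, 600), T)
  expect_equal(fitc$A0, 0.42)
  expect_lt(max(fitc$A), 1e-12)

  # full four-harmonic signal
  A <- c(0.08, 0.03, 0.015, 0.006)
  tau <- c(0.12, 0.4, 0.77, 0.05)
  y4 <- 0.3
  for (k in 1:4) y4 <- y4 + A[k] * sin(k * 2 * pi * (tt - tau[k] * T) / T)
  fit4 <- fit_harmonics(tt, y4, T)
  expect_equal(fit4$A, A, tolerance = 1e-10)
  # each tau_k is identified modulo 1/k of the period
  for (k in 1:4) {
    dphi <- (fit4$tau_frac[k] - tau[k]) * k
    expect_lt(min(abs(dphi - round(dphi))), 1e-9)
  }
})

test_that("fit errors are reported for unusable segments", {
  expect_error(fit_harmonics(seq(0, 4, by = 0.1), rnorm(41), T = 10),
               "full period")
  expect_error(fit_harmonics(seq(0, 10, length.out = 5), rnorm(5), T = 10),
               "samples")
  # 8 distinct sample times cannot identify 9 parameters
  t8 <- rep(seq(0, 7 / 8, by = 1 / 8), 2)
  expect_error(fit_harmonics(t8, rep(0.3, 16), T = 1), "rank deficient")
})

test_that("noisy recovery stays within linear-regression sampling theory", {
  T <- 5; N <- 500
  tt <- seq(0, 2 * T - 2 * T / N, length.out = N)
  A <- c(0.1, 0.05, 0.03, 0.02)
  tau <- c(0.2, 0.55, 0.1, 0.8)
  truth <- 0.4
  for (k in 1:4) truth <- truth + A[k] * sin(k * 2 * pi * (tt - tau[k] * T) / T)
  sigma <- 0.005
  se <- sigma * sqrt(2 / N)     # analytic SE of each a_k, b_k coefficient
  n_bad <- 0L; n_tot <- 0L
  for (seed in 1:60) {
    set.seed(seed)
    fit <- fit_harmonics(tt, truth + rnorm(N, sd = sigma), T)
    err <- abs(fit$A - A)
    n_bad <- n_bad + sum(err > 4 * se)
    n_tot <- n_tot + 4L
    expect_lt(max(err), 6 * se)
  }
  expect_lt(n_bad / n_tot, 0.01)
})

test_that("reconstruction is periodic and reproduces the fit residual", {
  T <- 8
  tt <- seq(0, 2 * T - 0.1, by = 0.1)
  set.seed(3)
  y <- 0.35 + 0.06 * sin(2 * pi * tt / T) + rnorm(length(tt), sd = 0.004)
  fit <- fit_harmonics(tt, y, T)
  yhat <- reconstruct_harmonics(fit, tt)
  expect_equal(sqrt(mean((y - yhat)^2)), fit$residual_rms,
               tolerance = 1e-12)
  expect_equal(reconstruct_harmonics(fit, tt + T), yhat, tolerance = 1e-12)
  # all-zero amplitudes reconstruct the constant offset
  fit0 <- fit_harmonics(tt, rep(0.2, length(tt)), T)
  expect_equal(reconstruct_harmonics(fit0, c(0, 1, 2)), rep(0.2, 3))
})

test_that("fits are invariant to a global time shift up to phase", {
  T <- 6
  tt <- seq(0, T - 0.01, by = 0.01)
  A <- c(0.07, 0.02, 0.01, 0.004); tau <- c(0.3, 0.6, 0.15, 0.9)
  sig <- function(t) {
    y <- 0.5
    for (k in 1:4) y <- y + A[k] * sin(k * 2 * pi * (t - tau[k] * T) / T)
    y
  }
  set.seed(11)
  for (delta in runif(5, -10, 10)) {
    f0 <- fit_harmonics(tt, sig(tt), T)
    fd <- fit_harmonics(tt, sig(tt + delta), T)
    expect_equal(fd$A, f0$A, tolerance = 1e-9)
    for (k in 1:4) {
      # the shifted signal's tau_k moves by -delta (mod T/k)
      shift <- (fd$tau_frac[k] - f0$tau_frac[k] + delta / T) * k
      expect_lt(min(abs(shift - round(shift))), 1e-7)
    }
  }
})

test_that("residuals never increase with more harmonics", {
  T <- 4
  tt <- seq(0, 2 * T - 0.05, by = 0.05)
  set.seed(21)
  y <- 0.4 + 0.05 * sin(2 * pi * tt / T) +
    0.02 * sin(3 * 2 * pi * tt / T + 1) + rnorm(length(tt), 0, 0.01)
  rms <- vapply(1:6, function(nh)
    fit_harmonics(tt, y, T, n_harmonics = nh)$residual_rms, numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("replicate aggregation averages parameters and phases correctly", {
  T <- 5
  tt <- seq(0, T - 0.02, by = 0.02)
  mk <- function(A1, tau1) {
    fit_harmonics(tt, 0.4 + A1 * sin(2 * pi * (tt - tau1 * T) / T), T)
  }
  # identical fits: mean = fit, SE = 0
  agg <- aggregate_fits(list(mk(0.1, 0.2), mk(0.1, 0.2), mk(0.1, 0.2)))
  expect_equal(agg$mean[agg$parameter == "A1"], 0.1, tolerance = 1e-9)
  expect_equal(agg$se, rep(0, nrow(agg)), tolerance = 1e-8)
  expect_identical(attr(agg, "n"), 3L)

  # amplitudes {0.1, 0.2, 0.3}: mean 0.2, SE = sd/sqrt(3)
  agg2 <- aggregate_fits(list(mk(0.1, 0.2), mk(0.2, 0.2), mk(0.3, 0.2)))
  expect_equal(agg2$mean[agg2$parameter == "A1"], 0.2, tolerance = 1e-9)
  expect_equal(agg2$se[agg2$parameter == "A1"], 0.1 / sqrt(3),
               tolerance = 1e-6)

  # phases {0.95, 0.05, 0.00}: circular mean 0, not 1/3
  agg3 <- aggregate_fits(list(mk(0.1, 0.95), mk(0.1, 0.05), mk(0.1, 0)))
  mu <- agg3$mean[agg3$parameter == "tau1_frac"]
  expect_lt(min(abs(c(mu, mu - 1))), 1e-6)

  expect_error(aggregate_fits(list(mk(0.1, 0.2))), "at least 2")
  f_other <- fit_harmonics(seq(0, 7.98, by = 0.02),
                           rep(0.4, 400), T = 8)
  expect_error(aggregate_fits(list(mk(0.1, 0.2), f_other)), "periods")
})

test_that("aggregated fits export with annotation columns", {
  T <- 5
  tt <- seq(0, T - 0.02, by = 0.02)
  mk <- function(A1) fit_harmonics(tt, 0.4 + A1 * sin(2 * pi * tt / T), T)
  agg <- aggregate_fits(list(mk(0.1), mk(0.12), mk(0.11)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_aggregated_csv(agg, "WT", "100-800", path)
  d <- read.csv(path)
  expect_named(d, c("genotype", "range", "T", "parameter", "mean",
                    "se", "n"))
  expect_equal(unique(d$n), 3)
  expect_equal(unique(d$T), 5)
  expect_equal(d$mean[d$parameter == "A1"], 0.11, tolerance = 1e-6)
})
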