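#' Fit an offset-plus-harmonics model to a periodic signal
#'
#' Least-squares fit of
#' `A0 + sum_k A_k * sin(k * 2*pi*(t - tau_k)/T)`, `k = 1..n_harmonics`,
#' to a steady-state periodic fluorescence segment. The nonlinear
#' amplitude/phase parameterization is solved exactly through its linear
#' reparameterization `A_k sin(k w (t - tau_k)) = a_k sin(k w t) +
#' b_k cos(k w t)`: ordinary linear least squares followed by
#' `A_k = sqrt(a_k^2 + b_k^2)` and `tau_k` from `atan2`, which makes the
#' fit deterministic and globally optimal. Amplitudes are reported
#' non-negative with the sign absorbed into the phase; phase fractions
#' `tau_k/T` are reported modulo 1 (each `tau_k` is only identified
#' modulo `T/k`).
#'
#' @param times Sample times (s), covering at least one full period on a
#'   (near-)uniform grid.
#' @param values Signal values (ChlF units).
#' @param T Oscillation period (s), known from the protocol.
#' @param n_harmonics Number of harmonic components (default 4).
#' @return An object of class `harmonic_fit`: list with `A0`, `A`
#'   (amplitudes), `tau_frac` (phase fractions tau_k/T in \[0,1)), `a`,
#'   `b` (linear coefficients), `T`, `n_harmonics`, `residual_rms`, `n`.
#' @export
fit_harmonics <- function(times, values, T, n_harmonics = 4L) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  if (T <= 0) stop("period T must be > 0")
  span <- diff(range(times))
  dts <- diff(sort(times))
  dt_est <- stats::median(dts[dts > 0])
  if (!is.finite(dt_est)) dt_est <- 0
  # a uniform grid over [0, T) spans T - dt yet covers a full period
  if (span < T - 1.5 * dt_est - 1e-12)
    stop("segment must cover at least one full period")
  nh <- as.integer(n_harmonics)
  npar <- 2L * nh + 1L
  if (length(times) < npar)
    stop("need at least ", npar, " samples to fit ", nh, " harmonics")
  w <- 2 * pi / T
  X <- matrix(1, nrow = length(times), ncol = npar)
  for (k in seq_len(nh)) {
    X[, 2L * k] <- sin(k * w * times)
    X[, 2L * k + 1L] <- cos(k * w * times)
  }
  qrx <- qr(X)
  if (qrx$rank < npar)
    stop("design matrix is rank deficient; cannot identify ", npar,
         " parameters from these samples")
  coef <- qr.coef(qrx, values)
  res <- values - X %*% coef
  a <- coef[seq(2L, npar, by = 2L)]
  b <- coef[seq(3L, npar, by = 2L)]
  A <- sqrt(a^2 + b^2)
  # a_k = A_k cos(k w tau_k), b_k = -A_k sin(k w tau_k)
  tau <- atan2(-b, a) / (w * seq_len(nh))
  tau_frac <- (tau / T) %% 1
  tau_frac[A < 1e-300] <- 0
  structure(list(A0 = unname(coef[1L]), A = unname(A),
                 tau_frac = unname(tau_frac), a = unname(a),
                 b = unname(b), T = T, n_harmonics = nh,
                 residual_rms = sqrt(mean(res^2)), n = length(times)),
            class = "harmonic_fit")
}

#' Evaluate a harmonic fit
#'
#' Evaluates the fitted offset-plus-harmonics model at the given times;
#' exactly `T`-periodic.
#'
#' @param fit A [fit_harmonics()] object.
#' @param times Times (s) at which to evaluate.
#' @return Numeric vector of model values.
#' @export
reconstruct_harmonics <- function(fit, times) {
  stopifnot(inherits(fit, "harmonic_fit"))
  w <- 2 * pi / fit$T
  out <- rep(fit$A0, length(times))
  for (k in seq_len(fit$n_harmonics)) {
    out <- out + fit$A[k] *
      sin(k * w * (times - fit$tau_frac[k] * fit$T))
  }
  out
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("Harmonic fit, T =", x$T, "s,", x$n_harmonics, "harmonics\n")
  cat("  A0 =", signif(x$A0, 6), "\n")
  for (k in seq_len(x$n_harmonics))
    cat(sprintf("  A%d = %.6g  tau%d/T = %.6g\n", k, x$A[k], k,
                x$tau_frac[k]))
  cat("  residual RMS =", signif(x$residual_rms, 4), "on", x$n,
      "samples\n")
  invisible(x)
}

circular_mean_se <- function(frac) {
  z <- exp(2i * pi * frac)
  m <- mean(z)
  mu <- (Arg(m) / (2 * pi)) %% 1
  Rbar <- Mod(m)
  # circular standard deviation mapped back to phase-fraction units
  sd_c <- if (Rbar >= 1) 0 else sqrt(-2 * log(Rbar)) / (2 * pi)
  c(mean = mu, se = sd_c / sqrt(length(frac)))
}

#' Aggregate harmonic fits across biological replicates
#'
#' Per-parameter mean and standard error (sample SD / sqrt(n)) over
#' replicate fits of the same period. Phase fractions are averaged on the
#' circle (direction of the mean resultant vector) so that phases
#' straddling the wrap-around, e.g. {0.95, 0.05}, average to 0 rather
#' than 0.5; their SE is the circular standard deviation divided by
#' sqrt(n).
#'
#' @param fits List of >= 2 [fit_harmonics()] objects with equal period
#'   and harmonic count.
#' @return An object of class `aggregated_fit`: data frame with columns
#'   `parameter`, `mean`, `se`, plus attributes `n` and `T`.
#' @export
aggregate_fits <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 replicate fits")
  stopifnot(all(vapply(fits, inherits, logical(1), "harmonic_fit")))
  Ts <- vapply(fits, `[[`, numeric(1), "T")
  if (diff(range(Ts)) > 1e-9 * Ts[1])
    stop("replicate fits have mixed periods")
  nh <- unique(vapply(fits, `[[`, integer(1), "n_harmonics"))
  if (length(nh) != 1L) stop("replicate fits have mixed harmonic counts")
  n <- length(fits)
  rows <- list()
  vals <- vapply(fits, `[[`, numeric(1), "A0")
  rows[[1]] <- data.frame(parameter = "A0", mean = mean(vals),
                          se = stats::sd(vals) / sqrt(n))
  for (k in seq_len(nh)) {
    Ak <- vapply(fits, function(f) f$A[k], numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(parameter = sprintf("A%d", k), mean = mean(Ak),
                 se = stats::sd(Ak) / sqrt(n))
    ph <- circular_mean_se(vapply(fits, function(f) f$tau_frac[k],
                                  numeric(1)))
    rows[[length(rows) + 1L]] <-
      data.frame(parameter = sprintf("tau%d_frac", k), mean = ph[["mean"]],
                 se = ph[["se"]])
  }
  out <- do.call(rbind, rows)
  structure(out, n = n, T = Ts[1],
            class = c("aggregated_fit", "data.frame"))
}

#' Export aggregated fits as a tidy CSV
#'
#' One row per parameter with its replicate mean and standard error,
#' annotated with the genotype and light range the fits came from.
#'
#' @param agg An [aggregate_fits()] result.
#' @param genotype Genotype label for the annotation column.
#' @param range Light-range label (e.g. `"100-800"`).
#' @param path Output CSV path; when `NULL` the data frame is returned
#'   instead.
#' @return The exported data frame (invisibly when written to file).
#' @export
write_aggregated_csv <- function(agg, genotype, range, path = NULL) {
  stopifnot(inherits(agg, "aggregated_fit"))
  out <- data.frame(genotype = genotype, range = range,
                    T = attr(agg, "T"),
                    parameter = agg$parameter, mean = agg$mean,
                    se = agg$se, n = attr(agg, "n"))
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
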