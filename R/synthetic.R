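#' Specification for synthetic periodic fluorescence traces
#'
#' Describes a noisy periodic ChlF-like signal with known ground truth:
#' an offset-plus-harmonics waveform sampled on a uniform grid with
#' additive i.i.d. Gaussian noise, emulating the statistical structure of
#' instrument traces (0.1-s effective sampling after on-board averaging,
#' three biological replicates). Used to validate the harmonic fitting
#' and loop analyses independently of the kinetic model.
#'
#' @param T Period (s).
#' @param A0 Offset (ChlF units).
#' @param A Amplitudes of harmonics 1..K (ChlF units, >= 0).
#' @param tau_frac Phase fractions tau_k/T in \[0, 1), same length as `A`.
#' @param noise_sd Gaussian noise SD (ChlF units, >= 0).
#' @param n_replicates Number of replicate traces (default 3).
#' @param n_cycles Cycles per replicate (default 5).
#' @param sample_interval Grid spacing (s, default 0.1).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(T, A0, A, tau_frac, noise_sd = 0.005,
                           n_replicates = 3L, n_cycles = 5L,
                           sample_interval = 0.1, seed = 1L) {
  if (length(A) != length(tau_frac))
    stop("A and tau_frac must have equal length")
  if (any(A < 0)) stop("amplitudes must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (T <= 0 || sample_interval <= 0 || n_cycles < 1 || n_replicates < 1)
    stop("invalid synthetic specification")
  structure(list(T = T, A0 = A0, A = A, tau_frac = tau_frac,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 n_cycles = as.integer(n_cycles),
                 sample_interval = sample_interval, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic replicate traces
#'
#' Evaluates the specified offset-plus-harmonics waveform on the sampling
#' grid and adds independent Gaussian noise per replicate. Replicates
#' differ only by their noise draws; the RNG is seeded from the
#' specification (restoring the caller's RNG state afterwards), so the
#' output is fully reproducible.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `times`, `truth` (noise-free signal), and
#'   `replicates` (list of value vectors, one per replicate).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  times <- seq(0, spec$T * spec$n_cycles - spec$sample_interval,
               by = spec$sample_interval)
  truth <- rep(spec$A0, length(times))
  w <- 2 * pi / spec$T
  for (k in seq_along(spec$A)) {
    truth <- truth + spec$A[k] * sin(k * w * (times - spec$tau_frac[k] * spec$T))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  reps <- lapply(seq_len(spec$n_replicates), function(i) {
    truth + stats::rnorm(length(truth), sd = spec$noise_sd)
  })
  list(times = times, truth = truth, replicates = reps)
}

#' Write synthetic replicates in the trace CSV format
#'
#' Exports a generated synthetic data set as one CSV per replicate (same
#' `time`/`ChlF` columns as simulator traces) plus a JSON metadata
#' sidecar flagged `synthetic`, recording the generating specification.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem (default "synthetic").
#' @return Character vector of the CSV paths, invisibly.
#' @export
write_synthetic_csv <- function(spec, dir, stem = "synthetic") {
  g <- generate_synthetic(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(spec$n_replicates)
  for (i in seq_len(spec$n_replicates)) {
    paths[i] <- file.path(dir, sprintf("%s_rep%d.csv", stem, i))
    utils::write.csv(data.frame(time = g$times, ChlF = g$replicates[[i]]),
                     paths[i], row.names = FALSE)
  }
  meta <- list(synthetic = TRUE, spec = unclass(spec),
               package_version = as.character(utils::packageVersion("photoloop")))
  jsonlite::write_json(meta, file.path(dir, paste0(stem, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
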