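# Per-segment analysis of periodic traces and the command-line layer.

#' Analyse every oscillation segment of a trace
#'
#' For each oscillation segment: discards the transient cycles,
#' phase-averages the steady-state cycles ([extract_loop()]), fits the
#' offset-plus-four-harmonic model to the averaged cycle
#' ([fit_harmonics()]) and computes loop orientation, normalized signed
#' area and classification ([orientation_and_area()], [classify_loop()]).
#'
#' @param trace A `photoloop_trace`.
#' @param n_harmonics Harmonics in the fit (default 4).
#' @return List with data frames `fits` (one row per segment: offset,
#'   amplitudes, phase fractions, residual RMS) and `loops` (one row per
#'   segment: orientation, area index, classification, branch summary).
#' @export
analyze_trace <- function(trace, n_harmonics = 4L) {
  segs <- unique(trace$segment)
  segs <- segs[segs != "pre"]
  fits <- list()
  loops <- list()
  for (seg in segs) {
    loop <- extract_loop(trace, seg)
    tt <- loop$phase * loop$T
    fit <- fit_harmonics(tt, loop$chlf, loop$T, n_harmonics = n_harmonics)
    frow <- data.frame(segment = seg, T = loop$T, A0 = fit$A0)
    for (k in seq_len(n_harmonics)) {
      frow[[sprintf("A%d", k)]] <- fit$A[k]
      frow[[sprintf("tau%d_frac", k)]] <- fit$tau_frac[k]
    }
    frow$residual_rms <- fit$residual_rms
    fits[[seg]] <- frow
    loops[[seg]] <- data.frame(
      segment = seg, T = loop$T,
      orientation = loop$orientation,
      area_index = loop$area_index,
      classification = classify_loop(loop),
      branch_diff = branch_difference(loop),
      chlf_mean = mean(loop$chlf),
      chlf_min = min(loop$chlf), chlf_max = max(loop$chlf))
  }
  list(fits = do.call(rbind, c(fits, list(make.row.names = FALSE))),
       loops = do.call(rbind, c(loops, list(make.row.names = FALSE))))
}

#' Run configuration for command-line entry points
#'
#' Resolves a genotype preset (or parameter file) and a light range into
#' the full (parameters, protocol) pair used by [cmd_simulate()].
#'
#' @param genotype `"WT"`, `"npq1"` or `"npq4"`; ignored when
#'   `params_file` is given.
#' @param range Light range, either `c(u_min, u_max)` or a shorthand
#'   string like `"100-800"`.
#' @param params_file Optional YAML parameter file ([read_params()]).
#' @param schedule `"standard"` (the full experimental period sequence)
#'   or a `photoloop_protocol`.
#' @param out_dir Output directory.
#' @param quantization Passed to [standard_schedule()] when
#'   `schedule = "standard"`.
#' @param seed Integer seed recorded in the metadata (only synthetic-data
#'   generation is stochastic; the simulation pipeline is deterministic).
#' @return An object of class `photoloop_config`.
#' @export
run_config <- function(genotype = "WT", range = "100-800",
                       params_file = NULL, schedule = "standard",
                       out_dir = ".", quantization = NA, seed = 1L) {
  params <- if (!is.null(params_file)) read_params(params_file)
            else genotype_preset(genotype)
  if (is.character(range)) {
    parts <- suppressWarnings(
      as.numeric(strsplit(range, "-", fixed = TRUE)[[1L]]))
    if (length(parts) != 2L || any(is.na(parts)))
      stop("range shorthand must look like '100-800'")
    range <- parts
  }
  protocol <- if (inherits(schedule, "photoloop_protocol")) schedule
              else if (identical(schedule, "standard"))
                standard_schedule(range[1L], range[2L],
                                  quantization = quantization)
              else stop("schedule must be 'standard' or a photoloop_protocol")
  structure(list(params = params, protocol = protocol, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "photoloop_config")
}

#' Simulate a configured run and write its outputs
#'
#' Runs [simulate_protocol()] for the resolved configuration and writes
#' `trace.csv` plus its JSON metadata sidecar into the output directory.
#'
#' @param config A [run_config()].
#' @return Path of the written trace CSV, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "photoloop_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  trace <- simulate_protocol(config$protocol, config$params)
  path <- file.path(config$out_dir, "trace.csv")
  write_trace_csv(trace, path)
  invisible(path)
}

#' Analyse a written trace and export fit/loop tables
#'
#' Reads a trace CSV (with its sidecar), runs [analyze_trace()] and
#' writes `fits.csv` and `loops.csv` next to it (or into `out_dir`).
#'
#' @param trace_file Path to a trace CSV written by [cmd_simulate()].
#' @param out_dir Output directory; defaults to the trace's directory.
#' @param n_harmonics Harmonics in the fits (default 4).
#' @return Named character vector with the two output paths, invisibly.
#' @export
cmd_analyze <- function(trace_file, out_dir = dirname(trace_file),
                        n_harmonics = 4L) {
  trace <- read_trace_csv(trace_file)
  res <- analyze_trace(trace, n_harmonics = n_harmonics)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- file.path(out_dir, "fits.csv")
  lp <- file.path(out_dir, "loops.csv")
  utils::write.csv(res$fits, fp, row.names = FALSE)
  utils::write.csv(res$loops, lp, row.names = FALSE)
  invisible(c(fits = fp, loops = lp))
}

#' Plot a stimulus-response loop
#'
#' Draws the `(PAR, ChlF)` loop with the ascending branch in orange-yellow
#' and the descending branch in blue, mirroring the conventional
#' presentation of oscillating-light fluorescence data.
#'
#' @param x A `hysteresis_loop`.
#' @param ... Further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.hysteresis_loop <- function(x, ...) {
  br <- split_phases(x)
  plot(x$light, x$chlf, type = "n",
       xlab = expression(PAR ~ (mu * mol ~ photons ~ m^-2 ~ s^-1)),
       ylab = expression(F * minute / F[M]), ...)
  lines(c(x$light, x$light[1]), c(x$chlf, x$chlf[1]), col = "grey70")
  points(x$light[br$ascending], x$chlf[br$ascending], col = "goldenrod",
         pch = 16, cex = 0.6)
  points(x$light[br$descending], x$chlf[br$descending], col = "steelblue",
         pch = 16, cex = 0.6)
  legend("topleft", bty = "n",
         legend = c("ascending", "descending",
                    paste0(x$orientation, ", index ",
                           signif(x$area_index, 3))),
         col = c("goldenrod", "steelblue", NA), pch = c(16, 16, NA))
  invisible(x)
}
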