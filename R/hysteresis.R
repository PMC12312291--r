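# Stimulus-response (PAR vs ChlF) loop construction and analysis.

#' Construct a hysteresis loop from paired light/response samples
#'
#' Low-level constructor used both by [extract_loop()] and by tests with
#' synthetic loops: one steady-state cycle of `(light, ChlF)` samples in
#' time order, assumed to start at the light minimum (ascending first).
#'
#' @param light Light values over one cycle (time-ordered).
#' @param chlf Response values over one cycle.
#' @param T Cycle period (s).
#' @param tol Orientation tolerance on the normalized area index below
#'   which the loop is reported as having no orientation.
#' @return An object of class `hysteresis_loop`.
#' @export
hysteresis_loop <- function(light, chlf, T, tol = 0.02) {
  if (length(light) != length(chlf)) stop("light and chlf lengths differ")
  if (length(light) < 8L) stop("need at least 8 samples per loop")
  loop <- structure(list(light = as.numeric(light),
                         chlf = as.numeric(chlf),
                         phase = seq(0, 1, length.out = length(light) + 1L)[
                           seq_along(light)],
                         T = T, tol = tol),
                    class = "hysteresis_loop")
  oa <- orientation_and_area(loop)
  loop$orientation <- oa$orientation
  loop$area_index <- oa$area_index
  br <- split_phases(loop)
  loop$ascending <- br$ascending
  loop$descending <- br$descending
  loop
}

#' Extract the steady-state loop of a trace segment
#'
#' Discards the initial transient cycles of a segment (the first cycle
#' for the 480-s period, the first two cycles for all shorter periods)
#' and phase-averages the remaining cycles into a single loop on the
#' within-cycle phase grid. Phase-averaging suppresses residual
#' aperiodicity and, for noisy experimental-style input, measurement
#' noise; set `phase_average = FALSE` to keep only the final cycle.
#'
#' @param trace A `photoloop_trace` (from [simulate_protocol()] or
#'   [read_trace_csv()]).
#' @param segment Segment label (e.g. `"T=60s"`) or period in seconds.
#' @param discard Number of leading cycles to drop; `NULL` (default)
#'   applies the standard rule above.
#' @param phase_average Average retained cycles (default) or keep the
#'   last one only.
#' @param tol Orientation tolerance, see [orientation_and_area()].
#' @return A `hysteresis_loop`.
#' @export
extract_loop <- function(trace, segment, discard = NULL,
                         phase_average = TRUE, tol = 0.02) {
  seg <- resolve_segment(trace, segment)
  d <- trace[trace$segment == seg, ]
  prot <- attr(trace, "protocol")
  Tper <- if (!is.null(prot)) {
    tab <- segment_table(prot)
    tab$period[match(seg, tab$segment)]
  } else NA_real_
  if (length(Tper) == 0L || is.na(Tper)) {
    # fall back to the sampling grid: cycle length from the labels
    Tper <- max(d$time[d$cycle == 1L]) - min(d$time[d$cycle == 1L]) +
      diff(d$time[1:2])
  }
  ncyc <- max(d$cycle)
  if (is.null(discard)) discard <- if (Tper >= 480) 1L else 2L
  if (ncyc - discard < 1L)
    stop("segment '", seg, "' has ", ncyc, " cycles; cannot discard ",
         discard, " and keep at least one")
  keep <- d[d$cycle > discard, ]
  per_cycle_n <- tabulate(keep$cycle)
  n <- min(per_cycle_n[per_cycle_n > 0])
  cyc_list <- split(seq_len(nrow(keep)), keep$cycle)
  idx <- lapply(cyc_list, function(i) i[seq_len(n)])
  light_m <- rowMeans(vapply(idx, function(i) keep$light[i], numeric(n)))
  chlf_m <- if (phase_average) {
    rowMeans(vapply(idx, function(i) keep$ChlF[i], numeric(n)))
  } else keep$ChlF[idx[[length(idx)]]]
  hysteresis_loop(light_m, chlf_m, Tper, tol = tol)
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(seq_len(n)[-1L], 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' Loop orientation and signed area index
#'
#' Signed area of the `(light, ChlF)` polygon by the shoelace formula
#' (positive = counter-clockwise, i.e. a response lagging the stimulus;
#' negative = clockwise, i.e. the response maximum precedes the stimulus
#' maximum), normalized by the bounding-box area
#' `range(light) * range(ChlF)` to a dimensionless index in \[-1, 1\].
#' Orientation is `"none"` when `|index|` falls below the tolerance.
#'
#' @param loop A `hysteresis_loop`.
#' @param tol Orientation tolerance on the index (default: the loop's own
#'   tolerance, 0.02 unless overridden at construction).
#' @return List with `orientation` (`"CCW"`, `"CW"` or `"none"`),
#'   `area_index` (signed) and `area` (signed, raw units).
#' @export
orientation_and_area <- function(loop, tol = NULL) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  if (is.null(tol)) tol <- loop$tol
  dx <- diff(range(loop$light))
  if (dx <= 0) stop("degenerate loop: zero light range")
  dy <- diff(range(loop$chlf))
  area <- shoelace_area(loop$light, loop$chlf)
  index <- if (dy <= 0) 0 else area / (dx * dy)
  orientation <- if (abs(index) < tol) "none" else
    if (index > 0) "CCW" else "CW"
  list(orientation = orientation, area_index = index, area = area)
}

#' Classify a loop as constitutive, regulatory or negligible
#'
#' Counter-clockwise loops (response lags the light, as produced by the
#' intrinsic delays of the primary photosynthetic reactions at short
#' oscillation periods) are classified `"constitutive"`; clockwise loops
#' (fluorescence already declining during the ascending light phase,
#' produced by the delayed qE regulatory response at long periods) are
#' `"regulatory"`; loops without resolvable orientation are
#' `"negligible"`.
#'
#' @param loop A `hysteresis_loop`.
#' @return One of `"constitutive"`, `"regulatory"`, `"negligible"`.
#' @export
classify_loop <- function(loop) {
  switch(orientation_and_area(loop)$orientation,
         CCW = "constitutive", CW = "regulatory", none = "negligible")
}

#' Split a loop into ascending and descending light branches
#'
#' Branch membership follows the sign of the light change along the
#' cycle; samples at the extremes are assigned to the branch they
#' terminate (the ascending branch ends at the light maximum, the
#' descending branch at the minimum). Plateau samples of a quantized
#' waveform inherit the branch of the preceding change.
#'
#' @param loop A `hysteresis_loop`.
#' @return List with logical masks `ascending` and `descending` covering
#'   all samples.
#' @export
split_phases <- function(loop) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  x <- loop$light
  n <- length(x)
  dx <- diff(c(x, x[1L]))        # change following each sample
  dirn <- sign(dx)
  # propagate direction across plateaus (quantized waveforms)
  for (i in seq_len(n)) if (dirn[i] == 0) dirn[i] <- dirn[if (i == 1) n else i - 1L]
  if (all(dirn == 0)) dirn[] <- 1
  # sample i belongs to the branch it terminates: use the preceding change
  prev <- c(dirn[n], dirn[-n])
  asc <- prev > 0
  asc[which.max(x)] <- TRUE
  asc[which.min(x)] <- FALSE
  list(ascending = asc, descending = !asc)
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat("Hysteresis loop, T =", x$T, "s,", length(x$light), "samples\n")
  cat("  light range:", paste(signif(range(x$light), 4), collapse = " - "),
      " ChlF range:", paste(signif(range(x$chlf), 4), collapse = " - "), "\n")
  cat("  orientation:", x$orientation,
      " area index:", signif(x$area_index, 4),
      " class:", classify_loop(x), "\n")
  invisible(x)
}

#' Compare loop branches at matched light levels
#'
#' Interpolates both branches onto a common light grid and returns the
#' mean signed difference `descending - ascending`; positive values mean
#' the response is higher while the light is falling (a lagging,
#' counter-clockwise response).
#'
#' @param loop A `hysteresis_loop`.
#' @param n_grid Number of interior light levels to compare.
#' @return Mean of `ChlF_descending - ChlF_ascending` over the grid.
#' @export
branch_difference <- function(loop, n_grid = 25L) {
  br <- split_phases(loop)
  xa <- loop$light[br$ascending]; ya <- loop$chlf[br$ascending]
  xd <- loop$light[br$descending]; yd <- loop$chlf[br$descending]
  lo <- max(min(xa), min(xd)); hi <- min(max(xa), max(xd))
  grid <- seq(lo, hi, length.out = n_grid + 2L)[-c(1L, n_grid + 2L)]
  fa <- stats::approx(xa, ya, xout = grid, ties = mean)$y
  fd <- stats::approx(xd, yd, xout = grid, ties = mean)$y
  mean(fd - fa, na.rm = TRUE)
}
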