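#' Oscillating-light protocol
#'
#' Defines the forcing waveform of an experiment: a constant
#' pre-illumination phase followed by an ordered sequence of sinusoidal
#' oscillation segments. Within a segment the intensity follows
#' `u0 - u1*cos(2*pi*t_seg/T)` with `u0 = (u_min+u_max)/2` and
#' `u1 = (u_max-u_min)/2`, so every segment starts at the minimum and
#' ascends; segment transitions are phase-reset and therefore continuous
#' (all segments share `u_min` at their boundaries). Optionally the ideal
#' sine is quantized to a fixed number of equally spaced intensity levels,
#' emulating the digital-to-analog converter of the light source.
#'
#' @param u_min,u_max Oscillation extremes (umol photons m-2 s-1,
#'   `0 < u_min < u_max`).
#' @param segments Two-column matrix or data frame `(period_s, cycles)`;
#'   periods > 0, cycle counts >= 1.
#' @param pre_illum Length-2 numeric `c(duration_s, intensity)`; the
#'   intensity defaults to the oscillation mean `(u_min+u_max)/2`.
#' @param quantization `NULL` (ideal sine) or the number of equally spaced
#'   intensity levels spanning `[u_min, u_max]` (integer >= 2).
#' @param sample_interval Output grid spacing (s).
#' @return An object of class `photoloop_protocol`.
#' @seealso [standard_schedule()], [waveform()]
#' @export
light_protocol <- function(u_min, u_max, segments,
                           pre_illum = c(0, (u_min + u_max) / 2),
                           quantization = NULL,
                           sample_interval = 0.1) {
  if (!(u_min > 0 && u_max > u_min))
    stop("need 0 < u_min < u_max")
  segments <- as.data.frame(segments)
  names(segments) <- c("period", "cycles")
  if (any(segments$period <= 0)) stop("all periods must be > 0")
  if (any(segments$cycles < 1) || any(segments$cycles != round(segments$cycles)))
    stop("all cycle counts must be integers >= 1")
  if (length(pre_illum) == 1L) pre_illum <- c(pre_illum, (u_min + u_max) / 2)
  if (pre_illum[1] < 0 || pre_illum[2] < 0)
    stop("pre-illumination duration and intensity must be >= 0")
  if (!is.null(quantization)) {
    quantization <- as.integer(quantization)
    if (quantization < 2L) stop("quantization must be >= 2 levels")
  }
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  p <- list(u_min = u_min, u_max = u_max, segments = segments,
            pre_illum = as.numeric(pre_illum), quantization = quantization,
            sample_interval = sample_interval)
  class(p) <- "photoloop_protocol"
  p
}

#' Standard experimental light schedule
#'
#' The full oscillating-light sequence used throughout the package: 10 min
#' of constant pre-illumination at the oscillation mean, then three cycles
#' with an 8-min period, five cycles each with 4-min, 2-min, 1-min, 30-s
#' and 10-s periods, and ten cycles each with 5-s and 1-s periods. For the
#' three canonical amplitude ranges the DAC emulation defaults to the
#' instrument's granularity: 8 intensity levels for 100-200, 22 for
#' 100-400 and 49 for 100-800 umol photons m-2 s-1; other ranges default
#' to an ideal sine.
#'
#' @inheritParams light_protocol
#' @param quantization Number of DAC levels; `NA` (default) picks the
#'   canonical value for the three standard ranges, `NULL` disables
#'   quantization.
#' @return A `photoloop_protocol`.
#' @export
standard_schedule <- function(u_min, u_max, quantization = NA,
                              sample_interval = 0.1) {
  segs <- data.frame(period = c(480, 240, 120, 60, 30, 10, 5, 1),
                     cycles = c(3, 5, 5, 5, 5, 5, 10, 10))
  if (length(quantization) == 1L && is.na(quantization)) {
    key <- paste0(u_min, "-", u_max)
    quantization <- switch(key, "100-200" = 8L, "100-400" = 22L,
                           "100-800" = 49L, NULL)
  }
  light_protocol(u_min, u_max, segs,
                 pre_illum = c(600, (u_min + u_max) / 2),
                 quantization = quantization,
                 sample_interval = sample_interval)
}

#' Total protocol duration
#'
#' @param protocol A `photoloop_protocol`.
#' @return Duration in seconds (pre-illumination plus all segments).
#' @export
protocol_duration <- function(protocol) {
  protocol$pre_illum[1] +
    sum(protocol$segments$period * protocol$segments$cycles)
}

#' Segment table of a protocol
#'
#' One row per protocol phase with its label, period, cycle count and
#' absolute start/end times. The pre-illumination phase is labelled
#' `"pre"`; oscillation segments are labelled by their period, e.g.
#' `"T=60s"`.
#'
#' @param protocol A `photoloop_protocol`.
#' @return A data frame with columns `segment`, `period`, `cycles`,
#'   `t_start`, `t_end`.
#' @export
segment_table <- function(protocol) {
  segs <- protocol$segments
  lab <- paste0("T=", ifelse(segs$period == round(segs$period),
                             segs$period, signif(segs$period, 6)), "s")
  dur <- segs$period * segs$cycles
  t0 <- protocol$pre_illum[1] + cumsum(c(0, dur[-length(dur)]))
  out <- data.frame(segment = c("pre", lab),
                    period = c(NA_real_, segs$period),
                    cycles = c(NA_real_, segs$cycles),
                    t_start = c(0, t0),
                    t_end = c(protocol$pre_illum[1], t0 + dur))
  out
}

quantize_light <- function(u, protocol) {
  n <- protocol$quantization
  if (is.null(n)) return(u)
  step <- (protocol$u_max - protocol$u_min) / (n - 1L)
  protocol$u_min + round((u - protocol$u_min) / step) * step
}

#' Evaluate the light waveform
#'
#' Intensity emitted at time `t` (vectorized). During pre-illumination the
#' constant pre-illumination intensity is returned; within an oscillation
#' segment the phase-reset sine `u0 - u1*cos(2*pi*t_seg/T)`, quantized if
#' the protocol requests it.
#'
#' @param t Time(s) in seconds, within `[0, protocol_duration(protocol)]`.
#' @param protocol A `photoloop_protocol`.
#' @return PAR in umol photons m-2 s-1.
#' @export
waveform <- function(t, protocol) {
  total <- protocol_duration(protocol)
  if (any(t < 0) || any(t > total + 1e-9))
    stop("t outside the protocol schedule [0, ", total, "]")
  u0 <- (protocol$u_min + protocol$u_max) / 2
  u1 <- (protocol$u_max - protocol$u_min) / 2
  out <- numeric(length(t))
  tab <- segment_table(protocol)
  pre_end <- tab$t_end[1]
  osc <- t >= pre_end
  out[!osc] <- protocol$pre_illum[2]
  if (any(osc)) {
    ts <- t[osc]
    idx <- findInterval(ts, tab$t_start[-1], rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    idx[idx > nrow(protocol$segments)] <- nrow(protocol$segments)
    Tper <- protocol$segments$period[idx]
    tseg <- ts - tab$t_start[-1][idx]
    u <- u0 - u1 * cos(2 * pi * tseg / Tper)
    out[osc] <- quantize_light(u, protocol)
  }
  out
}

#' @export
print.photoloop_protocol <- function(x, ...) {
  cat("Light protocol ", x$u_min, "-", x$u_max,
      " umol photons m-2 s-1\n", sep = "")
  cat("  pre-illumination: ", x$pre_illum[1], " s at ", x$pre_illum[2],
      "\n  segments:\n", sep = "")
  print(x$segments, row.names = FALSE)
  cat("  quantization: ",
      if (is.null(x$quantization)) "none" else
        paste0(x$quantization, " levels"),
      "; sampling ", x$sample_interval, " s\n", sep = "")
  invisible(x)
}

#' Export a waveform as a time/intensity CSV
#'
#' @param protocol A `photoloop_protocol`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(protocol, path) {
  t <- seq(0, protocol_duration(protocol), by = protocol$sample_interval)
  utils::write.csv(data.frame(time = t, light = waveform(t, protocol)),
                   path, row.names = FALSE)
  invisible(path)
}
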