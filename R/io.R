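# Trace CSV + JSON metadata sidecar input/output.

protocol_to_list <- function(protocol) {
  list(u_min = protocol$u_min, u_max = protocol$u_max,
       segments = protocol$segments,
       pre_illum = protocol$pre_illum,
       quantization = protocol$quantization,
       sample_interval = protocol$sample_interval)
}

protocol_from_list <- function(x) {
  light_protocol(x$u_min, x$u_max,
                 as.data.frame(x$segments),
                 pre_illum = as.numeric(unlist(x$pre_illum)),
                 quantization = x$quantization,
                 sample_interval = x$sample_interval)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), "_meta.json")

#' Write a simulation trace to CSV with a metadata sidecar
#'
#' The trace is written as a tidy CSV (one row per sample: time, light,
#' the six state variables, RCII_closed, ChlF, q, NPQ, segment, cycle);
#' the full resolved parameter set, protocol and package version go into
#' a `<stem>_meta.json` sidecar so that any run can be reproduced
#' bit-for-bit from its recorded metadata.
#'
#' @param trace A `photoloop_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "photoloop_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(
    synthetic = FALSE,
    params = unclass(attr(trace, "params")),
    protocol = protocol_to_list(attr(trace, "protocol")),
    package_version = as.character(utils::packageVersion("photoloop")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation trace written by [write_trace_csv()]
#'
#' Restores the trace data frame and, when the JSON sidecar is present,
#' its `params` and `protocol` attributes.
#'
#' @param path CSV path.
#' @return A `photoloop_trace`.
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "light", "ChlF", "segment", "cycle")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("malformed trace '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  sc <- sidecar_path(path)
  params <- protocol <- NULL
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$params)) {
      pl <- meta$params
      pl$genotype <- as.character(pl$genotype)
      params <- do.call(model_parameters, pl)
    }
    if (!is.null(meta$protocol)) protocol <- protocol_from_list(meta$protocol)
  }
  structure(tr, params = params, protocol = protocol,
            class = c("photoloop_trace", "data.frame"))
}
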