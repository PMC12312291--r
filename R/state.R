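#' Model state at one instant
#'
#' The six dynamic variables of the kinetic model: the oxidized
#' plastoquinone pool `PQ_ox` (molecules per PSII, in \[0, PQ_tot\]), the
#' oxidized fraction of PSI donors `PI_ox` (in \[0, 1\]), the lumen free H+
#' concentration `H_L` (uM, > 0), the adenylate pool in ATP form `ATP`
#' (molecules per PSII, in \[0, A_tot\]), and the two quencher fractions
#' `Zea` and `PsbS_act` (in \[0, 1\]).
#'
#' @param PQ_ox Oxidized plastoquinone per PSII (molecules).
#' @param PI_ox Oxidized fraction of PSI donors.
#' @param H_L Lumen free H+ concentration (uM).
#' @param ATP Adenylate in ATP form (molecules per PSII).
#' @param Zea Zeaxanthin fraction of the xanthophyll pool.
#' @param PsbS_act Protonated (active) PsbS fraction.
#' @return An object of class `photoloop_state` (a named numeric vector).
#' @export
model_state <- function(PQ_ox, PI_ox, H_L, ATP, Zea, PsbS_act) {
  s <- c(PQ_ox = PQ_ox, PI_ox = PI_ox, H_L = H_L, ATP = ATP,
         Zea = Zea, PsbS_act = PsbS_act)
  if (length(s) != 6L || any(!is.finite(s)))
    stop("state variables must be single finite numbers")
  class(s) <- "photoloop_state"
  s
}

state_names <- function() {
  c("PQ_ox", "PI_ox", "H_L", "ATP", "Zea", "PsbS_act")
}

as_state <- function(y) {
  s <- as.numeric(y)[1:6]
  names(s) <- state_names()
  class(s) <- "photoloop_state"
  s
}

#' Validate a model state against its parameter bounds
#'
#' @param state A `photoloop_state` object.
#' @param params A `photoloop_params` object supplying the pool sizes.
#' @param tol Numerical slack on the bounds (absolute).
#' @return `state`, invisibly; stops if any variable is out of bounds.
#' @export
validate_state <- function(state, params, tol = 1e-9) {
  stopifnot(inherits(state, "photoloop_state"))
  ok <- state[["PQ_ox"]] >= -tol && state[["PQ_ox"]] <= params$PQ_tot + tol &&
    state[["PI_ox"]] >= -tol && state[["PI_ox"]] <= 1 + tol &&
    state[["H_L"]] > 0 &&
    state[["ATP"]] >= -tol && state[["ATP"]] <= params$A_tot + tol &&
    state[["Zea"]] >= -tol && state[["Zea"]] <= 1 + tol &&
    state[["PsbS_act"]] >= -tol && state[["PsbS_act"]] <= 1 + tol
  if (!ok) {
    bad <- paste(sprintf("%s=%.6g", names(state), as.numeric(state)),
                 collapse = ", ")
    stop("state outside invariant bounds: ", bad)
  }
  invisible(state)
}

#' @export
print.photoloop_state <- function(x, ...) {
  cat("Model state:\n")
  print(signif(unclass(x), 6))
  invisible(x)
}
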