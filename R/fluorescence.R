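#' Quenching factor
#'
#' Multiplicative non-photochemical quenching factor
#' `q = (1 - Zea_max*Zea) * (1 - PsbS_max*PsbS_act)`, acting both on the
#' PSII excitation rate (quenchers are photoprotective) and on the
#' fluorescence yield; `q = F_M'/F_M`.
#'
#' @param Zea Zeaxanthin fraction in \[0, 1\] (vectorized).
#' @param PsbS_act Active PsbS fraction in \[0, 1\] (vectorized).
#' @param params A [model_parameters()] object.
#' @return Quench factor in (0, 1\].
#' @export
quench_factor <- function(Zea, PsbS_act, params) {
  if (any(Zea < 0 | Zea > 1) || any(PsbS_act < 0 | PsbS_act > 1))
    stop("quencher fractions must lie in [0, 1]")
  quench_factor_num(Zea, PsbS_act, params)
}

#' Normalized chlorophyll fluorescence yield
#'
#' Instantaneous fluorescence normalized to the dark-adapted maximum,
#' `ChlF = F'(t)/F_M = q*(1-B) / (1 + q*phi/(1-phi)) + q*B`, with
#' `B` the closed-centre fraction, `q` the quench factor and
#' `phi = phi_II_max = Fv/Fm`. This closed form is identical to the
#' two-step computation `F_M' = q*F_M`, `F_0'` by the Oxborough-Baker
#' approximation `F_0' = F_0 / (Fv/Fm + F_0/F_M')`, and
#' `F' = F_0' + B*(F_M' - F_0')`. Strictly increasing in both `B` and `q`;
#' bounded by `chlf <= q` with equality at `B = 1` (the saturating-pulse
#' limit `F_M'/F_M`).
#'
#' @param RCII_closed Closed PSII fraction `B` in \[0, 1\] (vectorized).
#' @param q Quench factor in (0, 1\] (vectorized).
#' @param params A [model_parameters()] object (supplies `phi_II_max`).
#' @return Normalized yield in (0, 1\].
#' @export
chlf <- function(RCII_closed, q, params) {
  if (any(RCII_closed < 0 | RCII_closed > 1))
    stop("RCII_closed must lie in [0, 1]")
  if (any(q <= 0 | q > 1)) stop("q must lie in (0, 1]")
  phi <- params$phi_II_max
  q * (1 - RCII_closed) / (1 + q * phi / (1 - phi)) + q * RCII_closed
}

#' Non-photochemical quenching parameter
#'
#' `NPQ = (F_M - F_M')/F_M' = 1/q - 1`.
#'
#' @param q Quench factor in (0, 1\] (vectorized).
#' @return NPQ, dimensionless and >= 0.
#' @export
npq_parameter <- function(q) {
  if (any(q <= 0)) stop("q must be > 0")
  1 / q - 1
}
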