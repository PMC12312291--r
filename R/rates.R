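# Rate laws and the ODE right-hand side.
#
# Conventions: electron fluxes are e- PSII-1 s-1; the PSII <-> PQ mass
# action acts per PQ molecule (PQ_ox in molecules, 0..PQ_tot), so the
# lumped transfer ceiling is k1_plus * PQ_tot rather than k1_plus; protons
# are accounted per PSII and converted to lumen concentration by beta_H;
# ATP is in molecules per PSII.

hill_activation <- function(H, K, n) {
  if (any(H <= 0)) stop("lumen H+ concentration must be > 0")
  1 / (1 + (K / H)^n)
}

#' Violaxanthin de-epoxidation rate
#'
#' Rate of zeaxanthin formation, `k3 * (1 - Zea) * 1/(1 + (KQ_VDE/H_L)^n_VDE)`:
#' first order in the remaining violaxanthin with a Hill-type activation by
#' lumen acidity (half-active at `H_L = KQ_VDE`).
#'
#' @param state A [model_state()] object.
#' @param params A [model_parameters()] object.
#' @return Rate in s-1 (fraction of the xanthophyll pool per second).
#' @export
rate_v3 <- function(state, params) {
  params$k3 * (1 - state[["Zea"]]) *
    hill_activation(state[["H_L"]], params$KQ_VDE, params$n_VDE)
}

#' PsbS activation rate
#'
#' Rate of PsbS protonation,
#' `k9 * (1 - PsbS_act) * 1/(1 + (KQ_PsbS/H_L)^n_PsbS)`; same Hill-type
#' lumen-pH dependence as [rate_v3()] with its own half-activation constant
#' and (flatter) Hill coefficient.
#'
#' @inheritParams rate_v3
#' @return Rate in s-1.
#' @export
rate_v9 <- function(state, params) {
  params$k9 * (1 - state[["PsbS_act"]]) *
    hill_activation(state[["H_L"]], params$KQ_PsbS, params$n_PsbS)
}

#' ATP formation rate
#'
#' Net ATP-synthase rate per PSII,
#' `k5 * ((A_tot - ATP) - a * ATP / H_L^(14/3))`. The exponent 14/3 is the
#' H+/ATP stoichiometry of a c14-ring ATP synthase; the `a` term is an
#' empirical back-pressure that lets the net rate become negative (ATP
#' hydrolysis) when the lumen is nearly neutral.
#'
#' @inheritParams rate_v3
#' @return Rate in ATP molecules PSII-1 s-1 (may be negative).
#' @export
rate_v5 <- function(state, params) {
  H <- state[["H_L"]]
  if (H <= 0) stop("lumen H+ concentration must be > 0")
  params$k5 * ((params$A_tot - state[["ATP"]]) -
                 params$a * state[["ATP"]] / H^(14 / 3))
}

quench_factor_num <- function(Zea, PsbS_act, params) {
  (1 - params$Zea_max * Zea) * (1 - params$PsbS_max * PsbS_act)
}

# Closed PSII fraction for given excitation rate kL (s-1) and PQ pool
# split P (oxidized molecules) / R (reduced molecules).
rcii_closed_kl <- function(kL, P, R, params) {
  (kL + params$k1_minus * R) / (kL + params$k1_minus * R + params$k1_plus * P)
}

#' Closed PSII reaction-centre fraction
#'
#' Quasi-steady fraction of closed PSII centres,
#' `B = (kL + k1_minus*R) / (kL + k1_minus*R + k1_plus*P)`, where
#' `P = PQ_ox` and `R = PQ_tot - PQ_ox` are the oxidized/reduced PQ pools
#' in molecules and `kL = sigma_II * q * light` is the quencher-attenuated
#' PSII excitation rate. Closure is treated as an algebraic (dependent)
#' variable: its intrinsic relaxation is far faster than every other
#' process in the model. `B` increases with light and with pool reduction;
#' `B = 0` in darkness with a fully oxidized pool and `B -> 1` as
#' `light -> Inf`.
#'
#' @inheritParams rate_v3
#' @param light Photosynthetically active radiation
#'   (umol photons m-2 s-1, >= 0).
#' @return Closed fraction in \[0, 1\].
#' @export
rcii_closed <- function(state, light, params) {
  if (any(light < 0)) stop("light must be >= 0")
  q <- quench_factor_num(state[["Zea"]], state[["PsbS_act"]], params)
  kL <- params$sigma_II * q * light
  P <- state[["PQ_ox"]]
  rcii_closed_kl(kL, P, params$PQ_tot - P, params)
}

# Core RHS on a plain numeric state vector; returns derivatives and the
# derived fluxes. Kept free of S3 dispatch and validation: it is called
# from the inner loop of the integrator.
rhs_core <- function(y, light, params) {
  P <- y[[1L]]; PI_ox <- y[[2L]]; H <- y[[3L]]
  ATP <- y[[4L]]; Zea <- y[[5L]]; PsbS <- y[[6L]]
  R <- params$PQ_tot - P

  q <- (1 - params$Zea_max * Zea) * (1 - params$PsbS_max * PsbS)
  kL <- params$sigma_II * q * light
  denom <- kL + params$k1_minus * R + params$k1_plus * P
  B <- (kL + params$k1_minus * R) / denom
  J2 <- kL * params$k1_plus * P / denom
  J_bf <- params$k2 * R * PI_ox

  h_v <- H^(14 / 3)
  v5 <- params$k5 * ((params$A_tot - ATP) - params$a * ATP / h_v)
  v3 <- params$k3 * (1 - Zea) / (1 + (params$KQ_VDE / H)^params$n_VDE)
  v9 <- params$k9 * (1 - PsbS) / (1 + (params$KQ_PsbS / H)^params$n_PsbS)

  v5_pump <- if (params$allow_atpase_reversal) v5 else max(v5, 0)
  dH <- params$beta_H * (params$n_H * J2 - (14 / 3) * v5_pump) -
    params$k_leak * (H - params$H_0)

  list(dy = c(PQ_ox = (J_bf - J2) / params$nu_e,
              PI_ox = params$sigma_I * light * (1 - PI_ox) - J_bf,
              H_L = dH,
              ATP = v5 - params$k6 * ATP,
              Zea = v3 - params$k4 * Zea,
              PsbS_act = v9 - params$k10 * PsbS),
       J2 = J2, J_bf = J_bf, B = B, v5 = v5, q = q)
}

#' ODE right-hand side
#'
#' Time derivatives of the six state variables under a given light
#' forcing. Electron transport: PSII reduces the PQ pool at net flux
#' `J2 = k1_plus*P*B - k1_minus*R*(1-B)` (e- PSII-1 s-1) and the pool is
#' re-oxidized towards the PSI donor side at `J_bf = k2*R*PI_ox`; PSI
#' donors are oxidized by PSI photochemistry at `sigma_I*light*(1-PI_ox)`.
#' Protons enter the lumen with the electron flux (`n_H` H+ per e-), leave
#' through the ATP synthase (14/3 H+ per ATP; reverse proton pumping by
#' ATP hydrolysis is excluded unless `allow_atpase_reversal`) and through a
#' passive leak towards the resting concentration `H_0`. ATP, zeaxanthin
#' and active PsbS follow their formation rates ([rate_v5()], [rate_v3()],
#' [rate_v9()]) minus first-order decay (`k6`, `k4`, `k10`).
#'
#' @param t Time (s), passed to `light_fn`.
#' @param state A [model_state()] object.
#' @param light_fn Function mapping time (s) to PAR
#'   (umol photons m-2 s-1).
#' @param params A [model_parameters()] object.
#' @return Named numeric vector of the six derivatives, with the derived
#'   quantities `J2`, `J_bf`, `B`, `v5` and `q` attached as attributes.
#' @export
ode_rhs <- function(t, state, light_fn, params) {
  stopifnot(inherits(state, "photoloop_state"))
  validate_state(state, params, tol = 1e-6)
  light <- light_fn(t)
  if (!is.finite(light) || light < 0) stop("light_fn(t) must be >= 0")
  out <- rhs_core(as.numeric(state), light, params)
  if (any(!is.finite(out$dy)))
    stop("non-finite derivative at t = ", t)
  structure(out$dy, J2 = out$J2, J_bf = out$J_bf, B = out$B,
            v5 = out$v5, q = out$q)
}
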