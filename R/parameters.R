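#' Model parameter set
#'
#' Constructs the full parameter set of the six-variable kinetic model of
#' photosynthetic electron transport with two-component non-photochemical
#' quenching (PsbS protonation and the violaxanthin/zeaxanthin cycle).
#' Defaults are the shipped calibrated wild-type values: the literature
#' rate constants of the lumped PSII/PQ electron transfer, the quencher
#' (de)activation kinetics and the ATP back-pressure constant are fixed,
#' while the transport/conversion constants not available in print
#' (`k2`, `k5`, `sigma_II`, `sigma_I`, `beta_H`, `k_leak`) carry the values
#' produced by [calibrate_parameters()], which anchors the wild-type steady
#' state at 1000 umol photons m-2 s-1 to approximately 60 O2 PSII-1 s-1 and
#' 93 ATP ATP-synthase-1 s-1.
#'
#' @param k1_plus,k1_minus Lumped forward/backward PSII <-> PQ electron
#'   transfer rate constants (s-1, per PQ molecule).
#' @param k2 PQH2 re-oxidation rate constant towards the PSI donor side
#'   (s-1, per reduced PQ molecule and oxidized donor fraction; calibrated).
#' @param k3,k4 Effective violaxanthin de-epoxidation / zeaxanthin
#'   epoxidation rate constants (s-1).
#' @param k5 ATP-synthase rate constant (s-1; calibrated).
#' @param k6 ATP consumption rate constant (s-1).
#' @param k9,k10 PsbS protonation (activation) / deactivation rate
#'   constants (s-1).
#' @param KQ_VDE,KQ_PsbS Half-activation lumen H+ concentrations of the two
#'   quenchers (uM).
#' @param n_VDE,n_PsbS Hill coefficients of quencher activation.
#' @param Zea_max,PsbS_max Maximal quenching depths of the two quenchers
#'   (dimensionless fractions).
#' @param a Empirical ATP back-pressure constant (dimensionless).
#' @param phi_II_max Dark-adapted maximal PSII quantum yield Fv/Fm.
#' @param PQ_tot Plastoquinone pool size per PSII (molecules).
#' @param nu_e Electrons carried per PQ molecule.
#' @param A_tot Total adenylate pool (ATP molecules per PSII).
#' @param sigma_II,sigma_I Effective excitation rate per unit PAR for PSII
#'   and PSI ((umol photons m-2 s-1)-1 s-1; calibrated).
#' @param beta_H Conversion from per-PSII proton flux to lumen free-H+
#'   concentration change (uM per H+ PSII-1); absorbs lumen buffering.
#' @param n_H Protons deposited in the lumen per transported electron.
#' @param k_leak Passive proton leak rate constant (s-1; calibrated).
#' @param H_0 Resting lumen free H+ concentration (uM).
#' @param allow_atpase_reversal If `TRUE` the proton-efflux term also runs
#'   in reverse when net ATP hydrolysis pumps protons into the lumen;
#'   by default reverse proton pumping is excluded.
#' @param genotype Genotype label, one of `"WT"`, `"npq1"`, `"npq4"`.
#'
#' @return An object of class `photoloop_params` (a named list).
#' @seealso [genotype_preset()], [calibrate_parameters()], [read_params()]
#' @export
model_parameters <- function(k1_plus = 250,
                             k1_minus = 100,
                             k2 = 114.285714285714,
                             k3 = 0.01,
                             k4 = 0.001,
                             k5 = 11.1066767941617,
                             k6 = 8,
                             k9 = 0.05,
                             k10 = 0.004,
                             KQ_VDE = 1,
                             KQ_PsbS = 1,
                             n_VDE = 6,
                             n_PsbS = 4,
                             Zea_max = 0.3,
                             PsbS_max = 0.3,
                             a = 9.202e-2,
                             phi_II_max = 0.83,
                             PQ_tot = 7,
                             nu_e = 2,
                             A_tot = 10,
                             sigma_II = 0.781485496786867,
                             sigma_I = 0.8,
                             beta_H = 0.001,
                             n_H = 1,
                             k_leak = 0.0058974358974359,
                             H_0 = 0.1,
                             allow_atpase_reversal = FALSE,
                             genotype = "WT") {
  p <- list(k1_plus = k1_plus, k1_minus = k1_minus, k2 = k2, k3 = k3,
            k4 = k4, k5 = k5, k6 = k6, k9 = k9, k10 = k10,
            KQ_VDE = KQ_VDE, KQ_PsbS = KQ_PsbS, n_VDE = n_VDE,
            n_PsbS = n_PsbS, Zea_max = Zea_max, PsbS_max = PsbS_max,
            a = a, phi_II_max = phi_II_max, PQ_tot = PQ_tot, nu_e = nu_e,
            A_tot = A_tot, sigma_II = sigma_II, sigma_I = sigma_I,
            beta_H = beta_H, n_H = n_H, k_leak = k_leak, H_0 = H_0,
            allow_atpase_reversal = isTRUE(allow_atpase_reversal),
            genotype = genotype)
  class(p) <- "photoloop_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a [model_parameters()] object:
#' non-negative rate constants, Hill coefficients >= 1, quenching depths in
#' \[0, 1), `0 < phi_II_max < 1`, positive half-activation constants and
#' positive pool sizes. Called by the constructors; exported for use on
#' deserialized parameter files.
#'
#' @param params A `photoloop_params` object.
#' @return `params`, invisibly; stops with an informative error otherwise.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "photoloop_params"))
  rates <- c("k1_plus", "k1_minus", "k2", "k3", "k4", "k5", "k6", "k9",
             "k10", "sigma_II", "sigma_I", "beta_H", "k_leak")
  for (nm in rates) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single finite number >= 0")
  }
  if (params$n_VDE < 1 || params$n_PsbS < 1)
    stop("Hill coefficients must be >= 1")
  for (nm in c("Zea_max", "PsbS_max")) {
    v <- params[[nm]]
    if (v < 0 || v >= 1) stop("'", nm, "' must lie in [0, 1)")
  }
  if (params$phi_II_max <= 0 || params$phi_II_max >= 1)
    stop("'phi_II_max' must lie in (0, 1)")
  if (params$KQ_VDE <= 0 || params$KQ_PsbS <= 0)
    stop("half-activation constants KQ must be > 0")
  if (params$PQ_tot < 1) stop("'PQ_tot' must be >= 1")
  if (params$A_tot <= 0) stop("'A_tot' must be > 0")
  if (params$nu_e <= 0) stop("'nu_e' must be > 0")
  if (params$n_H <= 0) stop("'n_H' must be > 0")
  if (params$H_0 <= 0) stop("'H_0' must be > 0")
  if (!params$genotype %in% c("WT", "npq1", "npq4"))
    stop("unknown genotype '", params$genotype,
         "'; valid presets: WT, npq1, npq4")
  invisible(params)
}

#' Genotype parameter presets
#'
#' Returns the parameter set for one of the three Arabidopsis genotypes
#' studied with the model. `"WT"` is the full calibrated wild-type set;
#' `"npq1"` (no violaxanthin de-epoxidase activity) reduces `k3` by a
#' factor of 1000; `"npq4"` (no PsbS protein) reduces `k9` by a factor of
#' 1000. All other parameters are identical across genotypes, so in the
#' mutants the affected quencher simply never accumulates.
#'
#' @param name Genotype name: `"WT"`, `"npq1"` or `"npq4"`.
#' @return A `photoloop_params` object.
#' @export
genotype_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("WT", "npq1", "npq4"))
    stop("unknown genotype preset; valid presets: WT, npq1, npq4")
  p <- model_parameters()
  if (name == "npq1") p$k3 <- p$k3 / 1000
  if (name == "npq4") p$k9 <- p$k9 / 1000
  p$genotype <- name
  validate_parameters(p)
  p
}

#' @export
print.photoloop_params <- function(x, ...) {
  cat("Kinetic model parameters (genotype ", x$genotype, ")\n", sep = "")
  flat <- unlist(x[vapply(x, is.numeric, logical(1))])
  print(signif(flat, 6))
  invisible(x)
}

#' Write a parameter set to a YAML file
#'
#' Serializes a parameter set as a flat key-value YAML mapping whose keys
#' are exactly the parameter field names, so files round-trip through
#' [read_params()].
#'
#' @param params A `photoloop_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_parameters(params)
  x <- unclass(params)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a parameter set from a YAML file
#'
#' @param path Path to a YAML file written by [write_params()] (or edited
#'   by hand; missing keys fall back to the wild-type defaults).
#' @return A `photoloop_params` object.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(model_parameters, x)
}
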