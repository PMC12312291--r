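# Shared fixtures. Simulations are cached for the duration of the test
# session so expensive runs (the full standard schedule in particular)
# happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

steady_cached <- function(genotype, light) {
  cached(paste("ss", genotype, light, sep = "_"),
         steady_state(light, genotype_preset(genotype)))
}

# Single-period oscillation run started from the mean-light steady state
# (the per-segment analysis mode: transients die within the discarded
# cycles).
mini_trace <- function(genotype, u_min, u_max, Tper, cycles, dt = 0.1) {
  key <- paste("tr", genotype, u_min, u_max, Tper, cycles, dt, sep = "_")
  cached(key, {
    p <- genotype_preset(genotype)
    prot <- light_protocol(u_min, u_max,
                           data.frame(period = Tper, cycles = cycles),
                           pre_illum = c(0, (u_min + u_max) / 2),
                           quantization = NULL, sample_interval = dt)
    simulate_protocol(prot, p, steady_state((u_min + u_max) / 2, p))
  })
}

mini_loop <- function(genotype, u_min, u_max, Tper, cycles, dt = 0.1) {
  extract_loop(mini_trace(genotype, u_min, u_max, Tper, cycles, dt), Tper)
}

wt_full_trace <- function() {
  cached("wt_full",
         simulate_protocol(standard_schedule(100, 800),
                           genotype_preset("WT")))
}

# Independent winding-sign oracle for convex loops: sign of the cross
# products of consecutive edges (constant around a convex polygon).
convex_winding_sign <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L); k <- c(3:n, 1L, 2L)
  cr <- (x[j] - x) * (y[k] - y[j]) - (y[j] - y) * (x[k] - x[j])
  sgn <- sign(cr[abs(cr) > 1e-12 * max(abs(cr))])
  if (all(sgn > 0)) 1 else if (all(sgn < 0)) -1 else 0
}
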