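test_that("steady states satisfy flux balance and the dark limit", {
  wt <- model_parameters()
  dark <- steady_cached("WT", 0)
  # at the resting lumen pH the steep Hill factors leave only a trace of
  # quencher activation (PsbS ~ 1e-3 because its Hill curve is flatter)
  expect_lt(dark[["Zea"]], 1e-4)
  expect_lt(dark[["PsbS_act"]], 5e-3)
  expect_equal(o2_rate(dark, 0, wt), 0, tolerance = 1e-10)
  expect_lt(abs(atp_rate_per_synthase(dark, wt)), 1)

  ss <- steady_cached("WT", 1000)
  rhs <- ode_rhs(0, ss, function(t) 1000, wt)
  expect_lt(max(abs(rhs)), 1e-7)
  # electron flux balance J2 = J_bf at the fixed point
  expect_equal(attr(rhs, "J2"), attr(rhs, "J_bf"),
               tolerance = 1e-6)
})

test_that("o2 rate is the stoichiometric quarter of the electron flux", {
  wt <- model_parameters()
  ss <- steady_cached("WT", 1000)
  rhs <- ode_rhs(0, ss, function(t) 1000, wt)
  expect_equal(o2_rate(ss, 1000, wt), attr(rhs, "J2") / 4)
  expect_equal(atp_rate_per_synthase(ss, wt), 2 * attr(rhs, "v5"))
})

test_that("the npq4 fixed point fluoresces more than wild type", {
  wt <- model_parameters()
  n4 <- genotype_preset("npq4")
  ss_wt <- steady_cached("WT", 1000)
  ss_n4 <- steady_cached("npq4", 1000)
  chlf_of <- function(s, p) {
    chlf(rcii_closed(s, 1000, p),
         quench_factor(s[["Zea"]], s[["PsbS_act"]], p), p)
  }
  expect_gt(chlf_of(ss_n4, n4), chlf_of(ss_wt, wt))
})

test_that("simulation is deterministic and converges to the steady state", {
  p <- genotype_preset("WT")
  prot <- light_protocol(100, 800, data.frame(period = 5, cycles = 2),
                         pre_illum = c(30, 450), quantization = NULL)
  tr1 <- simulate_protocol(prot, p)
  tr2 <- simulate_protocol(prot, p)
  expect_identical(tr1$ChlF, tr2$ChlF)
  expect_identical(tr1$H_L, tr2$H_L)

  # constant-light-only protocol approaches steady_state()
  prot_c <- light_protocol(100, 800, data.frame(period = 1, cycles = 1),
                           pre_illum = c(3000, 450), quantization = NULL,
                           sample_interval = 1)
  tr <- simulate_protocol(prot_c, p, steady_state(430, p))
  ss <- steady_state(450, p)
  pre_end <- tr[tr$segment == "pre", ]
  last <- pre_end[nrow(pre_end), ]
  for (nm in c("PQ_ox", "PI_ox", "H_L", "ATP"))
    expect_equal(last[[nm]], ss[[nm]], tolerance = 1e-4)
})

test_that("state variables stay within their bounds along trajectories", {
  set.seed(7)
  p <- genotype_preset("WT")
  for (i in 1:3) {
    u1 <- runif(1, 50, 400)
    u2 <- u1 + runif(1, 50, 800)
    Tper <- sample(c(2, 7, 33), 1)
    prot <- light_protocol(u1, u2, data.frame(period = Tper, cycles = 3),
                           pre_illum = c(20, (u1 + u2) / 2),
                           quantization = NULL)
    tr <- simulate_protocol(prot, p)
    expect_true(all(tr$PQ_ox >= -1e-9 & tr$PQ_ox <= p$PQ_tot + 1e-9))
    expect_true(all(tr$PI_ox >= -1e-9 & tr$PI_ox <= 1 + 1e-9))
    expect_true(all(tr$H_L > 0))
    expect_true(all(tr$ATP >= -1e-9 & tr$ATP <= p$A_tot + 1e-9))
    expect_true(all(tr$Zea >= -1e-9 & tr$Zea <= 1 + 1e-9))
    expect_true(all(tr$PsbS_act >= -1e-9 & tr$PsbS_act <= 1 + 1e-9))
    expect_true(all(diff(tr$time) > 0))
  }
})

test_that("periodicity diagnostic is exact on constructed traces", {
  # strictly periodic synthetic trace -> zero deviation
  base <- sin(2 * pi * (0:9) / 10) * 0.05 + 0.4
  fake <- data.frame(time = seq(0, 3.9, by = 0.1),
                     light = rep(150, 40),
                     ChlF = rep(base, 4),
                     segment = "T=1s", cycle = rep(1:4, each = 10))
  class(fake) <- c("photoloop_trace", "data.frame")
  expect_equal(max(periodic_steady(fake, 1)), 0)
  expect_true(attr(periodic_steady(fake, 1), "steady"))

  # constant-offset drift of d per cycle -> RMS exactly d
  d <- 3e-3
  fake$ChlF <- fake$ChlF + d * (fake$cycle - 1)
  ps <- periodic_steady(fake, 1)
  expect_equal(as.numeric(ps), rep(d, 3), tolerance = 1e-12)
  expect_false(attr(ps, "steady"))
  expect_error(periodic_steady(fake[fake$cycle == 1, ], 1), "cycles")
})

test_that("single-period runs reach the periodic steady state", {
  # fast oscillation: strictly periodic within the discarded cycles
  ps1 <- periodic_steady(mini_trace("WT", 100, 800, 1, 12), 1)
  expect_lt(tail(ps1, 1), 1e-4)
  # slow oscillation: the xanthophyll pool keeps relaxing (tau ~ 600 s),
  # so consecutive cycles converge but retain a small monotone drift
  ps60 <- periodic_steady(mini_trace("WT", 100, 800, 60, 5), 60)
  expect_lt(tail(ps60, 1), 5e-3)
  expect_true(all(diff(ps60) < 0))
})

test_that("the full schedule converges towards periodicity in every segment", {
  tr <- wt_full_trace()
  for (Tper in c(480, 240, 120, 60, 30, 10, 5, 1)) {
    ps <- periodic_steady(tr, Tper)
    # slow xanthophyll relaxation leaves a small monotone drift; the
    # retained cycles must be converging and close to periodic
    expect_lt(tail(ps, 1), 2e-3)
    if (length(ps) > 2) expect_lt(tail(ps, 1), ps[1] + 1e-12)
  }
})

test_that("quencher dynamics separate time scales across periods", {
  tr1 <- mini_trace("WT", 100, 800, 1, 12)
  tr240 <- mini_trace("WT", 100, 800, 240, 4)
  pp <- function(tr, n) {
    d <- tr[tr$cycle == max(tr$cycle, na.rm = TRUE) & !is.na(tr$cycle), ]
    diff(range(d[[n]]))
  }
  expect_lt(pp(tr1, "Zea"), 1e-3)
  expect_lt(pp(tr1, "PsbS_act"), 1e-3)
  expect_gt(pp(tr240, "PsbS_act"), 100 * pp(tr1, "PsbS_act"))
})

test_that("the fluorescence response is low-pass in the forcing frequency", {
  a1 <- function(Tper, cycles) {
    loop <- mini_loop("WT", 100, 800, Tper, cycles)
    fit_harmonics(loop$phase * loop$T, loop$chlf, loop$T)$A[1]
  }
  expect_lt(a1(1, 12), a1(10, 8))
})

test_that("higher harmonics vanish at least quadratically at small amplitude", {
  h_amp <- function(u1) {
    p <- genotype_preset("WT")
    prot <- light_protocol(450 - u1, 450 + u1,
                           data.frame(period = 10, cycles = 6),
                           pre_illum = c(0, 450), quantization = NULL)
    tr <- simulate_protocol(prot, p, steady_state(450, p))
    loop <- extract_loop(tr, 10)
    fit_harmonics(loop$phase * loop$T, loop$chlf, loop$T)$A
  }
  A_small <- h_amp(25)
  A_big <- h_amp(100)   # 4x the amplitude
  for (k in 2:4) {
    expect_lt(A_small[k] / A_small[1], 0.2)
    # quadratic (or faster) decay: a 4x amplitude reduction should shrink
    # the relative 2nd harmonic by at least ~4x (allowing 30% slack)
    expect_lt(A_small[k] / A_small[1], (A_big[k] / A_big[1]) / 4 * 1.3)
  }
})
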