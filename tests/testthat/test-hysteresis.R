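lagged_pair <- function(delta, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  list(x = sin(th), y = sin(th - delta))
}

test_that("signed area matches the analytic Lissajous formula", {
  # x = sin(wt), y = sin(wt - delta): enclosed signed area = pi*sin(delta);
  # a lagging response (delta > 0) is counter-clockwise
  for (delta in seq(-3, 3, by = 0.3)) {
    p <- lagged_pair(delta)
    loop <- hysteresis_loop(p$x + 2, p$y + 2, T = 1)
    oa <- orientation_and_area(loop)
    expect_equal(oa$area, pi * sin(delta), tolerance = 0.01 * pi)
    if (abs(sin(delta)) > 0.1) {
      expect_equal(oa$orientation, if (sin(delta) > 0) "CCW" else "CW")
    }
  }
  # in-phase: degenerate line, no orientation
  p0 <- lagged_pair(0)
  loop0 <- hysteresis_loop(p0$x + 2, p0$y + 2, T = 1)
  oa0 <- orientation_and_area(loop0)
  expect_equal(oa0$area, 0, tolerance = 1e-12)
  expect_equal(oa0$orientation, "none")
  # leading response: clockwise
  pl <- lagged_pair(-pi / 2)
  expect_equal(orientation_and_area(
    hysteresis_loop(pl$x + 2, pl$y + 2, 1))$orientation, "CW")
})

test_that("shoelace orientation agrees with a winding oracle on convex loops", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    th <- sort(runif(n, 0, 2 * pi))
    r <- runif(1, 0.5, 3)
    x <- 5 + r * cos(th); y <- 2 + 0.3 * r * sin(th)
    if (i %% 2 == 0) { x <- rev(x); y <- rev(y) }   # clockwise half the time
    oracle <- convex_winding_sign(x, y)
    oa <- orientation_and_area(hysteresis_loop(x, y, 1, tol = 0))
    expect_equal(sign(oa$area_index), oracle)
  }
})

test_that("orientation is invariant to positive affine axis rescaling", {
  p <- lagged_pair(0.7)
  base <- orientation_and_area(hysteresis_loop(p$x + 2, p$y + 2, 1))
  for (i in 1:5) {
    sx <- runif(1, 0.1, 50); sy <- runif(1, 1e-3, 10)
    ox <- runif(1, 0, 100); oy <- runif(1, 0, 1)
    oa <- orientation_and_area(
      hysteresis_loop(sx * (p$x + 2) + ox, sy * (p$y + 2) + oy, 1))
    expect_equal(oa$orientation, base$orientation)
    expect_equal(oa$area_index, base$area_index, tolerance = 1e-9)
  }
  expect_lte(abs(base$area_index), 1)
  expect_error(orientation_and_area(
    hysteresis_loop(rep(2, 20), seq(0, 1, length.out = 20), 1)),
    "degenerate")
})

test_that("loops are built from retained cycles with the standard discards", {
  # synthetic trace with known per-cycle values: cycle c has constant
  # offset c so the averaged loop reveals exactly which cycles were kept
  mk_trace <- function(Tper, ncyc, label) {
    n <- Tper * 10
    ph <- seq(0, 1, length.out = n + 1)[1:n]
    light <- 450 - 350 * cos(2 * pi * ph)
    d <- do.call(rbind, lapply(seq_len(ncyc), function(cc) {
      data.frame(time = (cc - 1) * Tper + ph * Tper, light = light,
                 ChlF = 0.3 + 0.01 * cc + 0.05 * sin(2 * pi * ph),
                 segment = label, cycle = cc)
    }))
    class(d) <- c("photoloop_trace", "data.frame")
    d
  }
  # 480-s segment with 3 cycles: discard 1, average cycles 2-3
  tr480 <- mk_trace(480, 3, "T=480s")
  loop <- extract_loop(tr480, 480)
  expect_equal(mean(loop$chlf), 0.3 + 0.01 * mean(c(2, 3)),
               tolerance = 1e-12)
  # 60-s segment with 5 cycles: discard 2, average cycles 3-5
  tr60 <- mk_trace(60, 5, "T=60s")
  loop60 <- extract_loop(tr60, 60)
  expect_equal(mean(loop60$chlf), 0.3 + 0.01 * mean(3:5), tolerance = 1e-12)
  # perfectly periodic trace: loop identical to any single retained cycle
  trp <- mk_trace(60, 5, "T=60s")
  trp$ChlF <- trp$ChlF - 0.01 * trp$cycle
  loop_p <- extract_loop(trp, 60)
  one <- trp$ChlF[trp$cycle == 5]
  expect_equal(loop_p$chlf, one, tolerance = 1e-12)
  # insufficient cycles
  expect_error(extract_loop(mk_trace(60, 2, "T=60s"), 60), "discard")
})

test_that("branches split at the light extremes", {
  n <- 100
  ph <- seq(0, 1, length.out = n + 1)[1:n]
  light <- 450 - 350 * cos(2 * pi * ph)
  y <- 0.4 + 0.05 * sin(2 * pi * (ph - 0.05))
  loop <- hysteresis_loop(light, y, 60)
  br <- split_phases(loop)
  expect_true(all(br$ascending | br$descending))
  expect_true(!any(br$ascending & br$descending))
  # symmetric sine: branch sizes differ by at most 2
  expect_lte(abs(sum(br$ascending) - sum(br$descending)), 2)
  # ascending branch terminates at the light maximum
  expect_true(br$ascending[which.max(light)])
  expect_true(br$descending[which.min(light)])
})

test_that("loop classification maps orientations to hysteresis types", {
  p <- lagged_pair(0.8)
  expect_equal(classify_loop(hysteresis_loop(p$x + 2, p$y + 2, 1)),
               "constitutive")
  pcw <- lagged_pair(-0.8)
  expect_equal(classify_loop(hysteresis_loop(pcw$x + 2, pcw$y + 2, 1)),
               "regulatory")
  p0 <- lagged_pair(0.005)
  expect_equal(classify_loop(hysteresis_loop(p0$x + 2, p0$y + 2, 1)),
               "negligible")
})

test_that("simulated branch asymmetries match the hysteresis phenomenology", {
  # short period: lagging response, ascending branch below descending
  loop1 <- mini_loop("WT", 100, 800, 1, 12)
  expect_gt(branch_difference(loop1), 0)
  # long period: regulation leads, ChlF maximum precedes the light maximum
  loop60 <- mini_loop("WT", 100, 800, 60, 5)
  ph_light <- loop60$phase[which.max(loop60$light)]
  ph_chlf <- loop60$phase[which.max(loop60$chlf)]
  expect_lt(ph_chlf, ph_light)
})
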