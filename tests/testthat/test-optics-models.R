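test_that("absorption enters the reflectance only through the Beer-Lambert factor", {
  t <- seq(0.05, 10, length.out = 400)
  geom <- probeGeometry(rho = 3, nTissue = 1.4)
  v <- 29.9792458 / 1.4
  for (musp in c(5, 10, 15)) {
    withAbs <- trsReflectance(t, opticalProperties(0.1, musp, 687), geom)
    lowAbs <- trsReflectance(t, opticalProperties(1e-9, musp, 687), geom)
    ratio <- curveValues(withAbs) / curveValues(lowAbs)
    expect_equal(ratio, exp(-(0.1 - 1e-9) * v * t), tolerance = 1e-12)
  }
})

test_that("reflectance is nonnegative, vanishes at early times, and peaks once", {
  t <- seq(0.002, 10, length.out = 5000)
  r <- trsReflectance(t, opticalProperties(0.1, 10, 687), probeGeometry())
  vals <- curveValues(r)
  expect_true(all(vals >= 0))
  expect_lt(vals[1L], 1e-30 * max(vals))  # -> 0 as t -> 0+
  d <- diff(vals)
  signChanges <- sum(diff(sign(d[d != 0])) != 0)
  expect_identical(signChanges, 1L)  # exactly one interior maximum
})

test_that("reflectance peak time matches the independent closed-form oracle", {
  t <- seq(1e-4, 10, length.out = 100001)
  r <- trsReflectance(t, opticalProperties(0.1, 10, 687),
                      probeGeometry(rho = 3, nTissue = 1.4))
  tPeak <- t[which.max(curveValues(r))]
  expect_equal(tPeak, fixture_tpeak, tolerance = 1e-3)
  # and pointwise against the oracle evaluation
  expect_equal(curveValues(r), oracle_refl(t, 0.1, 10, 3, 1.4),
               tolerance = 1e-12)
})

test_that("reflectance broadens and peaks later as scattering grows", {
  t <- seq(0.002, 10, length.out = 8192)
  peaks <- widths <- numeric(0)
  for (musp in c(5, 10, 15)) {
    r <- trsReflectance(t, opticalProperties(0.1, musp, 687), probeGeometry())
    peaks <- c(peaks, t[which.max(curveValues(r))])
    widths <- c(widths, fwhm(r))
  }
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(widths) > 0))
})

test_that("reflectance input validation and diffusion-regime warning", {
  expect_error(trsReflectance(c(0, 1, 2), opticalProperties(0.1, 10, 687)),
               "positive")
  expect_warning(
    trsReflectance(seq(0.1, 5, by = 0.1), opticalProperties(0.5, 0.4, 687)),
    "diffusion")
})

test_that("g1 is normalized, flat at zero flow, and matches the half-decay oracle", {
  tau <- default_tau()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5, nTissue = 1.37)
  g1 <- dcsG1(tau, props, flowSpec(1e-8), geom)
  vals <- curveValues(g1)
  expect_equal(vals[1L], 1)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  flat <- dcsG1(tau, props, flowSpec(0), geom)
  expect_equal(curveValues(flat), rep(1, length(tau)))
  # half-decay delay against the frozen bisection fixture
  cross <- approx(vals, tau, xout = 0.5)$y
  expect_equal(cross, fixture_tau_half, tolerance = 1e-2)
  expect_error(dcsG1(c(-1e-7, 1e-6), props, flowSpec(1e-8), geom),
               "nonnegative")
})

test_that("g1 decreases strictly with delay and with BFI on a parameter grid", {
  tau <- defaultDelayGrid(1e-7, 1e-3, 30)
  geom <- probeGeometry(rho = 2.5)
  for (mua in c(0.05, 0.2)) for (musp in c(5, 15)) {
    props <- opticalProperties(mua, musp, 785)
    prev <- NULL
    for (b in c(1e-9, 1e-8, 8e-8)) {
      v <- curveValues(dcsG1(tau, props, flowSpec(b), geom))
      expect_true(all(diff(v) < 0))
      if (!is.null(prev)) expect_true(all(v < prev))
      prev <- v
    }
  }
})

test_that("Siegert relation maps g1 to [1, 1+beta] and round-trips", {
  tau <- default_tau()
  g1 <- dcsG1(tau, opticalProperties(0.1, 10, 785), flowSpec(1e-8),
              probeGeometry(rho = 2.5))
  g2 <- siegertG2(g1, 0.5)
  vals <- curveValues(g2)
  expect_equal(vals[1L], 1.5)
  expect_true(all(vals >= 1 & vals <= 1.5))
  expect_true(all(diff(vals) <= 0))
  back <- sqrt((vals - 1) / 0.5)
  # below ~0.05 the (g2 - 1) subtraction loses the last digits to rounding,
  # so the 1e-12 round trip is asserted where the relation is well-posed
  keep <- curveValues(g1) > 0.05
  expect_equal(back[keep], curveValues(g1)[keep], tolerance = 1e-12)
  keepLow <- curveValues(g1) > 0
  expect_equal(back[keepLow], curveValues(g1)[keepLow], tolerance = 1e-6)
  # printed-precision arithmetic: beta 0.49 at g1 = 0.3
  g1fix <- modelCurve(c(0, 1), c(1, 0.3), "g1")
  expect_equal(curveValues(siegertG2(g1fix, 0.49))[2L], 1.0441)
  g1zero <- modelCurve(c(0, 1), c(1, 0), "g1")
  expect_equal(curveValues(siegertG2(g1zero, 0.7))[2L], 1)
  expect_error(siegertG2(g1, 0), "beta")
  expect_error(siegertG2(g1, 1.2), "beta")
})

test_that("g1 mixtures are convex combinations with the fixture tail value", {
  tau <- default_tau()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5, nTissue = 1.37)
  fast <- dcsG1(tau, props, flowSpec(1e-8), geom)
  slow <- dcsG1(tau, props, flowSpec(1e-10), geom)
  single <- mixG1(list(list(curve = fast, weight = 1)))
  expect_equal(curveValues(single), curveValues(fast))
  same <- mixG1(list(list(curve = fast, weight = 0.5),
                     list(curve = fast, weight = 0.5)))
  expect_equal(curveValues(same), curveValues(fast))
  mixed <- mixG1(list(list(curve = fast, weight = 0.75),
                      list(curve = slow, weight = 0.25)))
  mv <- curveValues(mixed)
  expect_equal(mv[1L], 1)
  expect_true(all(mv <= pmax(curveValues(fast), curveValues(slow)) + 1e-12))
  expect_true(all(mv >= pmin(curveValues(fast), curveValues(slow)) - 1e-12))
  # fixture value on a grid holding tau = 1e-3 exactly
  tauX <- c(0, 1e-5, 1e-4, 1e-3, 1e-2)
  mx <- mixG1(list(
    list(curve = dcsG1(tauX, props, flowSpec(1e-8), geom), weight = 0.75),
    list(curve = dcsG1(tauX, props, flowSpec(1e-10), geom), weight = 0.25)))
  at1e3 <- curveValues(mx)[4L]
  expect_equal(at1e3, fixture_mix_1e3, tolerance = 1e-6)
  expect_gt(at1e3, 0.05)  # the non-zero tail plateau signature
  badGrid <- dcsG1(tau * 2, props, flowSpec(1e-8), geom)
  expect_error(mixG1(list(list(curve = fast, weight = 0.5),
                          list(curve = badGrid, weight = 0.5))), "grid")
  expect_error(mixG1(list(list(curve = fast, weight = 0.6),
                          list(curve = slow, weight = 0.6))), "sum to 1")
})
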