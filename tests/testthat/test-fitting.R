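make_irf_std <- function() makeIRF(0.4, 2.5, defaultTimeGrid())

test_that("noiseless DTOF round trips recover the optical properties within 1%", {
  irf <- make_irf_std()
  geom <- probeGeometry()
  for (mua in c(0.05, 0.1, 0.2)) for (musp in c(5, 10, 15)) {
    clean <- simulateDTOF(opticalProperties(mua, musp, 687), geom, irf,
                          totalCounts = 1e6, backgroundRate = 0,
                          noise = FALSE)
    fit <- fitDTOF(clean, irf, geom = geom)
    expect_true(fit@converged)
    expect_lt(abs(mua(fit) / mua - 1), 0.01)
    expect_lt(abs(musp(fit) / musp - 1), 0.01)
  }
})

test_that("Poisson-noised DTOF at 1e6 counts recovers within 5%", {
  irf <- make_irf_std()
  geom <- probeGeometry()
  noisy <- simulateDTOF(opticalProperties(0.1, 10, 687), geom, irf,
                        totalCounts = 1e6, backgroundRate = 1, seed = 1)
  fit <- fitDTOF(noisy, irf, geom = geom)
  expect_true(fit@converged)
  expect_lt(abs(mua(fit) / 0.1 - 1), 0.05)
  expect_lt(abs(musp(fit) / 10 - 1), 0.05)
})

test_that("low-dynamic-range histograms are refused, not fitted", {
  irf <- make_irf_std()
  # peak ~50 counts over background 10: under one decade of dynamic range
  weak <- simulateDTOF(opticalProperties(0.1, 10, 687), probeGeometry(), irf,
                       totalCounts = 2.5e4, backgroundRate = 10, seed = 2)
  expect_lt(max(curveValues(weak)), 120)
  err <- tryCatch(fitDTOF(weak, irf), error = function(e) e)
  expect_s3_class(err, "diffuseQC_dynamic_range_error")
  expect_match(conditionMessage(err), "insufficient dynamic range")
})

test_that("a matched model fits better than a 50%-perturbed absorption", {
  irf <- make_irf_std()
  geom <- probeGeometry()
  noisy <- simulateDTOF(opticalProperties(0.1, 10, 687), geom, irf,
                        1e6, 1, seed = 3)
  resid_at <- function(muaFixed) {
    clean <- simulateDTOF(opticalProperties(muaFixed, 10, 687), geom, irf,
                          totalCounts = 1, backgroundRate = 0, noise = FALSE)
    m <- curveValues(clean)
    y <- curveValues(noisy) - 1
    idx <- y > max(y) * 0.01
    s <- sum(m[idx] * y[idx]) / sum(m[idx]^2)
    sum((s * m[idx] - y[idx])^2 / pmax(y[idx], 1))
  }
  expect_lt(resid_at(0.1), resid_at(0.15))
})

test_that("hemoglobin inversion solves the two-wavelength linear system", {
  # construction oracle: forward-compute mua from known concentrations
  cHbO2 <- 5e-5
  cHHb <- 2.5e-5
  mua687 <- log(10) * (fixture_eps$eps_hbo2[1L] * cHbO2 +
                       fixture_eps$eps_hhb[1L] * cHHb)
  mua830 <- log(10) * (fixture_eps$eps_hbo2[2L] * cHbO2 +
                       fixture_eps$eps_hhb[2L] * cHHb)
  h <- computeHemodynamics(mua687, mua830, eps = fixture_eps)
  expect_equal(h@cHbO2, cHbO2, tolerance = 1e-10)
  expect_equal(h@cHHb, cHHb, tolerance = 1e-10)
  expect_equal(sto2(h), 100 * cHbO2 / (cHbO2 + cHHb), tolerance = 1e-10)
  expect_true(h@physical)
})

test_that("StO2 limiting cases and scale invariance hold", {
  # pure oxyhemoglobin: StO2 = 100%
  muaPure <- log(10) * fixture_eps$eps_hbo2 * 4e-5
  h100 <- computeHemodynamics(muaPure[1L], muaPure[2L], eps = fixture_eps)
  expect_equal(sto2(h100), 100, tolerance = 1e-9)
  # symmetric extinction table + equal mua at both wavelengths: StO2 = 50%
  sym <- data.frame(wavelength_nm = c(687, 830),
                    eps_hbo2 = c(500, 1500), eps_hhb = c(1500, 500))
  hs <- computeHemodynamics(0.12, 0.12, eps = sym)
  expect_equal(sto2(hs), 50, tolerance = 1e-9)
  # scaling both concentrations leaves StO2 unchanged
  h1 <- computeHemodynamics(0.1, 0.14, eps = fixture_eps)
  h3 <- computeHemodynamics(0.3, 0.42, eps = fixture_eps)
  expect_equal(sto2(h1), sto2(h3), tolerance = 1e-9)
  # singular extinction matrix is a configuration error
  sing <- data.frame(wavelength_nm = c(687, 830),
                     eps_hbo2 = c(500, 500), eps_hhb = c(1500, 1500))
  expect_error(computeHemodynamics(0.1, 0.12, eps = sing), "singular")
  # negative concentration flagged, not clipped
  neg <- computeHemodynamics(0.01, 0.30, eps = fixture_eps)
  expect_false(neg@physical)
  expect_true(neg@cHHb < 0 || neg@cHbO2 < 0)
})

test_that("beta estimation reads the plateau and degenerates correctly", {
  tau <- defaultDelayGrid()
  g1 <- dcsG1(tau, opticalProperties(0.1, 10, 785), flowSpec(1e-8),
              probeGeometry(rho = 2.5))
  g2c <- g2Curve(tau, curveValues(siegertG2(g1, 0.49)), countRate = 90)
  expect_equal(estimateBeta(g2c), 0.49, tolerance = 2e-2)
  flat <- g2Curve(tau, rep(1, length(tau)), countRate = 90)
  expect_equal(estimateBeta(flat), 0)
  short <- g2Curve(tau[tau > 1e-6], rep(1.4, sum(tau > 1e-6)), countRate = 90)
  err <- tryCatch(estimateBeta(short), error = function(e) e)
  expect_s3_class(err, "diffuseQC_plateau_error")
})

test_that("noiseless g2 fits recover BFI and beta within 1% across the BFI range", {
  tau <- defaultDelayGrid()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5)
  for (b in c(1e-9, 1e-8, 8e-8)) {
    g2m <- siegertG2(dcsG1(tau, props, flowSpec(b), geom), 0.49)
    fit <- fitG2(g2Curve(tau, curveValues(g2m), countRate = 90), props, geom)
    expect_true(fit@converged)
    expect_lt(abs(bfi(fit) / b - 1), 0.01)
    expect_lt(abs(coherenceBeta(fit) / 0.49 - 1), 0.02)
  }
})

test_that("noisy g2 fits at 50 kHz x 300 s recover BFI within 10%", {
  tau <- defaultDelayGrid()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5)
  for (b in c(1e-9, 1e-8, 8e-8)) {
    g2m <- siegertG2(dcsG1(tau, props, flowSpec(b), geom), 0.49)
    noisy <- simulateG2(g2m, countRate = 50, duration = 300,
                        seed = round(1e9 * b) + 11)
    fit <- fitG2(noisy, props, geom)
    expect_true(fit@converged)
    expect_lt(abs(bfi(fit) / b - 1), 0.10)
  }
})

test_that("the g1 cutoff excludes plateau-level mixture tails from the fit", {
  tau <- defaultDelayGrid()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5)
  # mixture with a 0.25-weight immobile component: tail plateau ~0.25 < 0.3
  mixed <- mixG1(list(
    list(curve = dcsG1(tau, props, flowSpec(1e-8), geom), weight = 0.75),
    list(curve = dcsG1(tau, props, flowSpec(0), geom), weight = 0.25)))
  g2m <- siegertG2(mixed, 0.49)
  fit <- fitG2(g2Curve(tau, curveValues(g2m), countRate = 40), props, geom)
  g1meas <- sqrt(pmax(curveValues(g2m) - 1, 0) / fit@beta)
  # every point the fit used satisfied the cutoff; the 0.25-plateau did not
  expect_true(all(g1meas[g1meas >= fit@cutoffValue] >= 0.3))
  expect_lt(min(g1meas), 0.3)
  expect_true(fit@converged)
})

test_that("a homogeneous fit of a two-component mixture shows poor model agreement", {
  tau <- defaultDelayGrid()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5)
  pure <- siegertG2(dcsG1(tau, props, flowSpec(1.1e-8), geom), 0.49)
  mixed <- siegertG2(mixG1(list(
    list(curve = dcsG1(tau, props, flowSpec(1.1e-8), geom), weight = 0.75),
    list(curve = dcsG1(tau, props, flowSpec(1e-10), geom), weight = 0.25))),
    0.49)
  noise <- function(g2m) simulateG2(g2m, countRate = 40, duration = 300,
                                    seed = 21)
  fitPure <- fitG2(noise(pure), props, geom)
  fitMix <- fitG2(noise(mixed), props, geom)
  expect_gt(fitMix@residual, 5 * fitPure@residual)
  expect_true("poor model agreement" %in% fitMix@reliabilityFlag)
  expect_false("poor model agreement" %in% fitPure@reliabilityFlag)
})

test_that("BFI below the ergodicity bound is flagged unreliable", {
  tau <- defaultDelayGrid()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5)
  g2m <- siegertG2(dcsG1(tau, props, flowSpec(1e-10), geom), 0.49)
  fit <- fitG2(g2Curve(tau, curveValues(g2m), countRate = 90), props, geom)
  expect_true(fit@converged)
  expect_lt(bfi(fit), 3e-10)
  expect_true("unreliable" %in% fit@reliabilityFlag)
})
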