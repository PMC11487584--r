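test_that("generated IRFs have unit area and the requested width", {
  grid <- defaultTimeGrid()
  dt <- grid[2L] - grid[1L]
  irf <- makeIRF(fwhm = 0.4, t0 = 1.0, tGrid = grid)
  expect_equal(sum(curveValues(irf)) * dt, 1, tolerance = 1e-9)
  expect_true(abs(fwhm(irf) - 0.4) <= dt)
  expect_error(makeIRF(fwhm = 0.001, t0 = 1.0, tGrid = defaultTimeGrid(10, 1000)),
               "resolution")
  expect_error(makeIRF(fwhm = 0.4, t0 = 20, tGrid = grid), "inside")
})

test_that("IRF convolution preserves signal area without wrap-around", {
  grid <- defaultTimeGrid()
  irf <- makeIRF(0.4, 2.5, grid)
  refl <- trsReflectance(grid, opticalProperties(0.14, 11, 687),
                         probeGeometry())
  conv <- convolveWithIRF(refl, irf)
  dt <- grid[2L] - grid[1L]
  # area preserved up to the (negligible) truncated tail
  expect_equal(sum(curveValues(conv)), sum(curveValues(refl)),
               tolerance = 1e-6)
  # no counts can precede both the IRF onset and the physical signal
  expect_lt(max(curveValues(conv)[grid < 1.0]), 1e-12 * max(curveValues(conv)))
})

test_that("simulated DTOFs are seeded, normalized, and Poisson-consistent", {
  grid <- defaultTimeGrid()
  irf <- makeIRF(0.4, 2.5, grid)
  props <- opticalProperties(0.14, 11, 687)
  geom <- probeGeometry()
  # expectation normalization: noise-free signal sums to totalCounts
  clean <- simulateDTOF(props, geom, irf, totalCounts = 1e6,
                        backgroundRate = 0, noise = FALSE)
  expect_equal(sum(curveValues(clean)), 1e6, tolerance = 1e-6)
  # seeded reproducibility
  a <- simulateDTOF(props, geom, irf, 1e5, 1, seed = 42)
  b <- simulateDTOF(props, geom, irf, 1e5, 1, seed = 42)
  expect_identical(curveValues(a), curveValues(b))
  # law of large numbers at 1e8 counts: high-expectation bins track the model
  big <- simulateDTOF(props, geom, irf, 1e8, 0, seed = 7)
  expectBig <- curveValues(clean) * 100
  hi <- expectBig > 1e5
  relDev <- abs(curveValues(big)[hi] - expectBig[hi]) / expectBig[hi]
  expect_lt(max(relDev), 0.01)
  expect_error(simulateDTOF(props, geom, irf, 1e5, backgroundRate = -1),
               "nonnegative")
  expect_error(simulateDTOF(props, geom, irf, 0), "positive")
})

test_that("Poisson noise has unit variance-to-mean ratio", {
  grid <- defaultTimeGrid(10, 256)
  irf <- makeIRF(0.4, 2.5, grid)
  props <- opticalProperties(0.14, 11, 687)
  onebin <- vapply(seq_len(200), function(k) {
    h <- simulateDTOF(props, probeGeometry(), irf, totalCounts = 3e4,
                      backgroundRate = 100, seed = 1000 + k)
    curveValues(h)[10L]  # pre-pulse bin with expectation 100
  }, numeric(1))
  ratio <- var(onebin) / mean(onebin)
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("g2 simulation adds seeded noise and afterpulsing with the stated shape", {
  tau <- defaultDelayGrid()
  g1 <- dcsG1(tau, opticalProperties(0.1, 10, 785), flowSpec(1e-8),
              probeGeometry(rho = 2.5))
  g2i <- siegertG2(g1, 0.49)
  # noise -> 0 limit at very large count rate
  quiet <- simulateG2(g2i, countRate = 1e7, duration = 300, seed = 1)
  expect_lt(max(abs(curveValues(quiet) - curveValues(g2i))), 1e-3)
  # seeded reproducibility
  n1 <- simulateG2(g2i, 50, 300, seed = 5)
  n2 <- simulateG2(g2i, 50, 300, seed = 5)
  expect_identical(curveValues(n1), curveValues(n2))
  # afterpulsing inflates the shortest delays and dies off by 7 tau_ap
  ap <- simulateG2(g2i, 1e7, 300, afterpulsingAmp = 0.2,
                   afterpulsingTau = 1e-6, seed = 2)
  lift <- curveValues(ap) - curveValues(quiet)
  expect_gt(lift[1L], 0.15)
  expect_lt(max(abs(lift[tau > 7e-6])), 0.2 * 1e-3 + 2e-3)
  # the inflated plateau raises the estimated beta above the construction one
  expect_gt(estimateBeta(ap), 0.49)
})

test_that("curve averaging is a pointwise mean with bookkeeping", {
  grid <- defaultTimeGrid(10, 512)
  irf <- makeIRF(0.4, 2.5, grid)
  props <- opticalProperties(0.14, 11, 687)
  one <- simulateDTOF(props, probeGeometry(), irf, 1e5, 1, seed = 3)
  same <- averageCurves(rep(list(one), 100))
  expect_equal(curveValues(same), curveValues(one))
  expect_equal(same@nAveraged, 100 * one@nAveraged)
  # averaging n seeded realizations shrinks the noise like 1/sqrt(n)
  reps <- lapply(1:100, function(k)
    simulateDTOF(props, probeGeometry(), irf, 1e5, 1, seed = 2000 + k))
  avg <- averageCurves(reps)
  expected <- curveValues(simulateDTOF(props, probeGeometry(), irf, 1e5, 1,
                                       noise = FALSE))
  hot <- expected > 200
  sdSingle <- sd((curveValues(reps[[1L]]) - expected)[hot] /
                 sqrt(expected[hot]))
  sdMean <- sd((curveValues(avg) - expected)[hot] / sqrt(expected[hot]))
  expect_lt(abs(sdMean / (sdSingle / 10) - 1), 0.3)
  other <- simulateDTOF(props, probeGeometry(),
                        makeIRF(0.4, 2.5, defaultTimeGrid(10, 256)), 1e5, 1,
                        seed = 4)
  expect_error(averageCurves(list(one, other)), "grid")
  expect_error(averageCurves(list()), "empty")
})

test_that("peak normalization preserves shape and rejects flat curves", {
  grid <- defaultTimeGrid(10, 512)
  irf <- makeIRF(0.4, 2.5, grid)
  h <- simulateDTOF(opticalProperties(0.14, 11, 687), probeGeometry(), irf,
                    1e5, 1, seed = 9)
  n1 <- normalizeToPeak(h)
  expect_equal(max(curveValues(n1)), 1)
  scaled <- dtofHistogram(h@tGrid, curveValues(h) * 7, 687)
  n7 <- normalizeToPeak(scaled)
  expect_equal(curveValues(n7), curveValues(n1))
  zero <- dtofHistogram(grid, numeric(length(grid)), 687)
  expect_error(normalizeToPeak(zero), "maximum")
})
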