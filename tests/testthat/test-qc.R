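test_that("FWHM is the interpolated half-maximum width and is scale invariant", {
  # symmetric triangle: height 1, base 2 ns -> width at half maximum 1 ns
  x <- seq(0, 2, by = 0.01)
  tri <- pmax(0, 1 - abs(x - 1))
  expect_equal(fwhm(tri, abscissa = x), 1.0, tolerance = 1e-12)
  expect_equal(fwhm(tri * 37.5, abscissa = x), 1.0, tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 50)
  err <- tryCatch(fwhm(ramp, abscissa = seq_len(50)), error = function(e) e)
  expect_s3_class(err, "diffuseQC_width_error")
})

test_that("TRS metrics fill the printed definitions", {
  grid <- defaultTimeGrid()
  irf <- makeIRF(0.4, 4.0, grid)
  # histogram shaped exactly like the IRF plus a noisy flat background
  set.seed(11)
  counts <- round(2e5 * curveValues(irf) * (grid[2L] - grid[1L])) +
    rpois(length(grid), 4)
  d <- dtofHistogram(grid, counts, 687)
  m <- trsQCMetrics(d, irf)
  expect_equal(m@rfwhm, 1, tolerance = 0.05)
  expect_lt(abs(m@dfwhm), 0.05)
  expect_lt(abs(m@peakDelay), 0.02)  # within a few bins of zero
  # SNR/dynamic range follow their definitions on the same background window
  bgIdx <- which(grid < 4.0 - 5 * 0.4)
  expect_equal(m@snr, max(counts) / sd(counts[bgIdx]), tolerance = 1e-12)
  expect_equal(m@dynamicRange,
               log10(max(counts) / max(mean(counts[bgIdx]), 1)),
               tolerance = 1e-12)
  # rfwhm/dfwhm arithmetic at the printed example values
  m2 <- qcMetrics(fwhmDtof = 1.2, fwhmIrf = 0.4, rfwhm = 3.0, dfwhm = 0.8)
  expect_equal(m2@rfwhm, 3.0)
  expect_equal(m2@dfwhm, 0.8)
})

test_that("noiseless zero-background curves raise a configuration error, not infinite SNR", {
  grid <- defaultTimeGrid()
  irf <- makeIRF(0.4, 2.5, grid)
  clean <- simulateDTOF(opticalProperties(0.14, 11, 687), probeGeometry(),
                        irf, 1e6, 0, noise = FALSE)
  err <- tryCatch(trsQCMetrics(clean, irf), error = function(e) e)
  expect_s3_class(err, "diffuseQC_config_error")
  err2 <- tryCatch(classifyQC(qcMetrics(snr = Inf)), error = function(e) e)
  expect_s3_class(err2, "diffuseQC_config_error")
})

test_that("diffusive simulations always broaden the DTOF (rFWHM > 1, dFWHM > 0)", {
  grid <- defaultTimeGrid()
  irf <- makeIRF(0.4, 2.5, grid)
  for (musp in c(5, 10, 15)) for (mua in c(0.07, 0.2)) {
    d <- simulateDTOF(opticalProperties(mua, musp, 687), probeGeometry(),
                      irf, 1e6, 1, seed = round(1000 * mua + musp))
    m <- trsQCMetrics(d, irf)
    expect_gt(m@rfwhm, 1)
    expect_gt(m@dfwhm, 0)
  }
})

test_that("DCS metrics carry count rate, fit results and tail plateau", {
  tau <- defaultDelayGrid()
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5)
  mixed <- mixG1(list(
    list(curve = dcsG1(tau, props, flowSpec(1e-8), geom), weight = 0.75),
    list(curve = dcsG1(tau, props, flowSpec(1e-10), geom), weight = 0.25)))
  g2m <- g2Curve(tau, curveValues(siegertG2(mixed, 0.49)), countRate = 0.3)
  fit <- fitG2(g2m, props, geom)
  m <- dcsQCMetrics(g2m, fit)
  expect_equal(m@countRate, 0.3)
  expect_equal(m@bfi, bfi(fit))
  expect_gt(m@tailPlateau, 0.05)
  # metrics survive a missing fit
  m0 <- dcsQCMetrics(g2m, NULL)
  expect_true(m0@fitRefused)
  expect_true(is.finite(m0@beta))
})

test_that("classification encodes the exclusion and plausibility guidelines", {
  # SNR below 10 is a hard exclusion
  v <- classifyQC(qcMetrics(snr = 5, dynamicRange = 3.5))
  expect_identical(verdictLabel(v), "reject")
  expect_match(verdictReasons(v)$rule, "snr", all = FALSE)
  # count rate below the 0.5 kHz noise floor is hard
  v2 <- classifyQC(qcMetrics(countRate = 0.3))
  expect_identical(verdictLabel(v2), "reject")
  expect_match(verdictReasons(v2)$rule, "noise level", all = FALSE)
  # BFI below the 3e-10 ergodicity bound is a plausibility flag
  v3 <- classifyQC(qcMetrics(bfi = 1e-10, countRate = 90))
  expect_identical(verdictLabel(v3), "suspect")
  expect_match(verdictReasons(v3)$rule, "unreliable BFI", all = FALSE)
  # a tail plateau means the g1 tail never reached zero
  v4 <- classifyQC(qcMetrics(tailPlateau = 0.2))
  expect_identical(verdictLabel(v4), "suspect")
  expect_match(verdictReasons(v4)$rule, "tail", all = FALSE)
  # the healthy operating point raises nothing
  v5 <- classifyQC(qcMetrics(snr = 900, dynamicRange = 3.4, rfwhm = 2.0,
                             dfwhm = 0.4, peakDelay = 0.79, countRate = 90,
                             beta = 0.49, bfi = 1.2e-8, tailPlateau = 0.01,
                             sto2 = 67))
  expect_identical(verdictLabel(v5), "acceptable")
  expect_identical(nrow(verdictReasons(v5)), 0L)
})

test_that("classification is monotone and its reasons reproduce the label", {
  base <- list(snr = 5, dynamicRange = 2, rfwhm = 0.9, dfwhm = -0.1,
               peakDelay = 0.2, countRate = 0.3, beta = 0.7, bfi = 5e-7,
               tailPlateau = 0.3, sto2 = 90)
  good <- list(snr = 500, dynamicRange = 3.6, rfwhm = 2, dfwhm = 0.4,
               peakDelay = 0.8, countRate = 90, beta = 0.49, bfi = 1e-8,
               tailPlateau = 0.01, sto2 = 65)
  sev <- c(acceptable = 1L, suspect = 2L, reject = 3L)
  lab <- function(fields) verdictLabel(classifyQC(do.call(qcMetrics, fields)))
  for (f in names(base)) {
    worse <- base
    better <- base
    better[[f]] <- good[[f]]
    expect_lte(sev[lab(better)], sev[lab(worse)])
  }
  # reason completeness: severity column alone reproduces the label
  v <- classifyQC(do.call(qcMetrics, base))
  r <- verdictReasons(v)
  relabel <- if (any(r$severity == "hard")) "reject"
             else if (nrow(r)) "suspect" else "acceptable"
  expect_identical(relabel, verdictLabel(v))
})

test_that("secondary-decay detection separates mixtures from single decays", {
  tau <- c(0, defaultDelayGrid())
  props <- opticalProperties(0.1, 10, 785)
  geom <- probeGeometry(rho = 2.5)
  pure <- dcsG1(tau, props, flowSpec(1e-8), geom)
  resPure <- detectSecondaryDecay(pure, props, geom)
  expect_false(resPure$present)
  mixed <- mixG1(list(list(curve = pure, weight = 0.75),
                      list(curve = dcsG1(tau, props, flowSpec(1e-10), geom),
                           weight = 0.25)))
  resMix <- detectSecondaryDecay(mixed, props, geom)
  expect_true(resMix$present)
  expect_lt(abs(resMix$slowWeight - 0.25), 0.05)
  flat <- dcsG1(tau, props, flowSpec(0), geom)
  err <- tryCatch(detectSecondaryDecay(flat, props, geom),
                  error = function(e) e)
  expect_s3_class(err, "diffuseQC_flat_error")
})

test_that("rule sets round-trip through YAML and JSON and feed serialized verdicts", {
  rules <- defaultQCRules()
  rules@snrMin <- 12
  rules@betaWindow <- c(0.3, 0.6)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("rules.", ext))
    writeQCRules(rules, path)
    back <- readQCRules(path)
    for (s in slotNames("QCRuleSet"))
      expect_equal(slot(back, s), slot(rules, s), info = s)
  }
  expect_error(readQCRules(file.path(tempdir(), "absent.yaml")), "not found")
  m <- qcMetrics(snr = 5, dynamicRange = 2.5)
  v <- classifyQC(m, rules = rules)
  js <- verdictToJSON(v, m, rules)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$label, "reject")
  expect_true(all(c("rule", "observed", "bound", "severity") %in%
                  names(parsed$reasons)))
  expect_equal(parsed$rules$snr_min, 12)
  expect_equal(parsed$metrics$snr, 5)
})
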