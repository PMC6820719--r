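# Event detection against generator ground truth, dwell fits, capture rate,
# translocation classifier.

# overlap-match detected events to ground truth
matchEvents <- function(truth, detected) {
  td <- events(truth); dd <- events(detected)
  if (!nrow(td) || !nrow(dd)) return(c(hits = 0L, fp = nrow(dd)))
  hits <- 0L
  used <- logical(nrow(dd))
  for (i in seq_len(nrow(td))) {
    ov <- which(!used & dd$start < td$end[i] & dd$end > td$start[i])
    if (length(ov)) { hits <- hits + 1L; used[ov[1]] <- TRUE }
  }
  c(hits = hits, fp = sum(!used))
}

test_that("pure-noise traces yield empty event tables", {
  g <- genCurrentTrace(traceSpec(61.5, 0.7, eventRate = 0, dwellMean = 2e-3,
                                 blockadeDepth = 0.5, duration = 2,
                                 seed = 91))
  ev <- detectEvents(g$trace, kSigma = 5)
  expect_equal(nrow(events(ev)), 0L)
  expect_error(detectEvents(g$trace, kSigma = -1), "parameter error")
})

test_that("well-separated deep events are detected with no false positives", {
  # ~200 events, depth 50%, noise 2% of I0, k = 5
  g <- genCurrentTrace(traceSpec(61.5, 0.02 * 61.5, eventRate = 10,
                                 dwellMean = 2e-3, blockadeDepth = 0.5,
                                 duration = 20, seed = 92))
  ev <- detectEvents(g$trace, kSigma = 5)
  td <- events(g$truth)
  visible <- sum(td$dwell >= 5e-5)
  m <- matchEvents(g$truth, ev)
  expect_gte(m[["hits"]] / visible, 0.98)
  expect_equal(m[["fp"]], 0L)
  # blockade depth 0.5 reproduced per event
  expect_equal(median(events(ev)$ires_over_i0), 0.5, tolerance = 0.02)
  expect_equal(abs(openPoreCurrent(ev)), 61.5, tolerance = 0.2)
})

test_that("event tables are invariant to a constant trace offset", {
  g <- genCurrentTrace(traceSpec(61.5, 1.0, eventRate = 20,
                                 dwellMean = 2e-3, blockadeDepth = 0.5,
                                 duration = 5, seed = 93))
  ev1 <- detectEvents(g$trace, kSigma = 5)
  tr2 <- CurrentTrace(currentValues(g$trace) + 15,
                      samplingRate = samplingRate(g$trace),
                      voltage = voltage(g$trace))
  ev2 <- detectEvents(tr2, kSigma = 5)
  expect_equal(nrow(events(ev1)), nrow(events(ev2)))
  expect_equal(events(ev1)$start, events(ev2)$start, tolerance = 1e-9)
  expect_equal(openPoreCurrent(ev2) - openPoreCurrent(ev1), 15,
               tolerance = 0.15)
})

test_that("negative-polarity traces run through the same detection path", {
  g <- genCurrentTrace(traceSpec(-56.7, 1.0, eventRate = 20,
                                 dwellMean = 2e-3, blockadeDepth = 0.5,
                                 duration = 5, seed = 94))
  ev <- detectEvents(g$trace, kSigma = 5)
  expect_gt(nrow(events(ev)), 50)
  expect_equal(openPoreCurrent(ev), -56.7, tolerance = 0.2)
  expect_true(all(events(ev)$ires_over_i0 > 0))
})

test_that("dwell fits: mean identity, SE-level recovery, censoring correction", {
  f0 <- fitDwellExponential(rep(2e-3, 40), method = "mle", minDwell = 0)
  expect_equal(tauHat(f0), 2e-3)

  set.seed(95)
  d <- rexp(5000, rate = 1 / 2e-3)
  f1 <- fitDwellExponential(d, method = "mle", minDwell = 0)
  expect_lt(abs(tauHat(f1) - 2e-3), 3 * 2e-3 / sqrt(5000))
  expect_true(f1@ci[1] <= tauHat(f1) && tauHat(f1) <= f1@ci[2])

  # left truncation at 0.5 ms: uncorrected mean = tau + cutoff by
  # memorylessness; the correction recovers tau
  trunc <- d[d >= 5e-4]
  fT <- fitDwellExponential(trunc, method = "mle", minDwell = 5e-4)
  expect_equal(fT@details$tau_uncorrected, 2.5e-3, tolerance = 0.1)
  expect_equal(tauHat(fT), 2e-3, tolerance = 0.1)

  # histogram fit agrees with MLE within 10% on clean samples
  fH <- fitDwellExponential(d, method = "histogram", minDwell = 0)
  expect_lt(abs(tauHat(fH) - tauHat(f1)) / tauHat(f1), 0.10)

  expect_error(fitDwellExponential(rexp(10, 1), method = "histogram"),
               "at least 30")
  expect_error(fitDwellExponential(rep(1e-4, 50), method = "mle",
                                   minDwell = 1e-4), "degenerate")
})

test_that("capture rate: periodic limit, definitional identity, Poisson recovery", {
  ev <- EventTable(data.frame(start = seq(0, 0.9, 0.1),
                              end = seq(0, 0.9, 0.1) + 1e-9,
                              dwell = 1e-9))
  cr <- captureRate(ev)
  expect_equal(cr@tauOn, 0.1, tolerance = 1e-6)
  expect_equal(captureFrequency(cr), 10, tolerance = 1e-4)
  expect_equal(captureFrequency(cr) * cr@tauOn, 1)

  # Poisson arrivals at 74.3 / s over 10 s, near-instant dwells
  g <- genCurrentTrace(traceSpec(61.5, 0.5, eventRate = 74.3,
                                 dwellMean = 5e-5, blockadeDepth = 0.5,
                                 duration = 10, seed = 96))
  cr2 <- captureRate(g$truth)
  n <- cr2@nIntervals
  expect_lt(abs(captureFrequency(cr2) - 74.3), 3 * 74.3 / sqrt(n))

  expect_error(captureRate(EventTable(data.frame(start = 1, end = 1.1,
                                                 dwell = 0.1))),
               "insufficient-data")
})

test_that("translocation classifier follows the voltage-dependence criterion", {
  # flat dwell series: bumping, no translocation
  flat <- data.frame(voltage = c(80, 100, 120, 140, 160),
                     tau = c(1.01, 0.99, 1.02, 1.00, 0.98) * 2e-3)
  expect_equal(as.character(classifyTranslocation(flat)),
               "no_translocation")

  # tau = A exp(-V/40): translocation (exact series; lm warns about the
  # perfect fit, which is expected here)
  v <- c(80, 100, 120, 140, 160)
  dec <- data.frame(voltage = v, tau = 5e-3 * exp(-v / 40))
  expect_equal(as.character(suppressWarnings(classifyTranslocation(dec))),
               "translocation")

  expect_error(classifyTranslocation(dec[1:2, ]), "at least 3")
  expect_error(classifyTranslocation(
    data.frame(voltage = c(80, 90, 100), tau = c(1, 1, 1))), "40 mV")

  # noisy but strongly varying series that fits neither rule
  odd <- data.frame(voltage = v, tau = c(1, 5, 1, 5, 1) * 1e-3)
  expect_equal(as.character(classifyTranslocation(odd)), "indeterminate")
})
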