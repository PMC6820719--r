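# Charge-displacement currents, densities, Gaussian histogram fits,
# selectivity.

test_that("a single +1 ion crossing L_z in time T carries I = e/T", {
  # L_z = 20 A crossed in 1 ns (wrapping once): I = e/ns =
  # 1.602e-19 C / 1e-9 s = 160.2 pA
  topo <- data.frame(particle_id = 1L, species = "K", charge = 1)
  z <- c(0, 5, 10, 15, 0)  # last hop wraps 15 -> 20 == 0
  coords <- array(rbind(0 * z, 0 * z, z), c(1, 3, 5))
  coords[1, , ] <- rbind(numeric(5), numeric(5), z)
  tr <- IonTrajectory(topo, coords, times = c(0, 250, 500, 750, 1000),
                      box = c(20, 20, 20), voltage = 150, dt = 250)
  est <- computeSpeciesCurrents(tr)
  expect_equal(currents(est)[["I_total"]], 1.602176634e-19 / 1e-9 * 1e12,
               tolerance = 1e-9)
  expect_equal(currents(est)[["I_Cl"]], 0)
})

test_that("drift-only phantom (D = 0) matches the analytic current to 1e-6", {
  cs <- cylinderSpec(6, length = 40)
  spec <- driftDiffusionSpec(50, 0, mobility = 2.4967e-4 / 0.5, field = 0.5,
                             duration = 1000, frameInterval = 10, seed = 61)
  est <- computeSpeciesCurrents(genIonTrajectory(spec, cs))
  truth <- analyticDriftCurrent(spec, cs)
  expect_lt(abs(currents(est)[["I_total"]] / truth[["I_total"]] - 1), 1e-6)
  expect_lt(abs(currents(est)[["I_K"]] / truth[["I_K"]] - 1), 1e-6)
  expect_equal(est@sdBlocks, 0, tolerance = 1e-9)
})

test_that("stochastic phantom recovers the analytic current within block SEs", {
  cs <- cylinderSpec(6, length = 40)
  # mobility*field chosen so the closed-form total is 100 pA
  mobE <- 100 * 40 / (1.602176634e5 * 2 * 50)
  ests <- lapply(1:5, function(s) {
    spec <- driftDiffusionSpec(50, 0.02, mobility = mobE / 0.5, field = 0.5,
                               duration = 20000, frameInterval = 10,
                               seed = 61 + s)
    computeSpeciesCurrents(genIonTrajectory(spec, cs))
  })
  vals <- vapply(ests, function(e) currents(e)[["I_total"]], 0)
  ses <- vapply(ests, function(e) e@sdBlocks / sqrt(5), 0)
  pooled <- mean(vals)
  pooledSE <- sqrt(sum(ses^2)) / 5
  expect_lt(abs(pooled - 100), 3 * pooledSE)
})

test_that("currents are additive and antisymmetric under field reversal", {
  cs <- cylinderSpec(6, length = 40)
  for (s in 1:3) {
    spec <- driftDiffusionSpec(20, 0.02, 0.05, field = 0.5, duration = 2000,
                               frameInterval = 10, seed = 70 + s)
    est <- computeSpeciesCurrents(genIonTrajectory(spec, cs))
    expect_equal(currents(est)[["I_total"]],
                 currents(est)[["I_K"]] + currents(est)[["I_Cl"]])
  }
  specP <- driftDiffusionSpec(30, 0, 0.05, field = 0.5, duration = 1000,
                              frameInterval = 10, seed = 74)
  specM <- driftDiffusionSpec(30, 0, 0.05, field = -0.5, duration = 1000,
                              frameInterval = 10, seed = 74)
  eP <- computeSpeciesCurrents(genIonTrajectory(specP, cs))
  eM <- computeSpeciesCurrents(genIonTrajectory(specM, cs))
  expect_equal(currents(eM)[["I_K"]], -currents(eP)[["I_K"]],
               tolerance = 1e-9)
  expect_equal(currents(eM)[["I_Cl"]], -currents(eP)[["I_Cl"]],
               tolerance = 1e-9)
  expect_equal(currents(eM)[["I_total"]], -currents(eP)[["I_total"]],
               tolerance = 1e-9)
})

test_that("density profile: uniform solution, empty species, volume scaling", {
  # uniform ions at 1 M = 6.022e-4 / A^3 in a R = 20, L = 100 cylinder
  R <- 20; L <- 100
  nIons <- round(6.022e-4 * pi * R^2 * L)
  tr <- uniformIonTraj(nIons, R, L, nFrames = 50, seed = 81)
  prof <- new("RadiusProfile",
              layers = data.frame(z_center = seq(0.5, L - 0.5, 1),
                                  radius_mean = R, radius_sd = 0,
                                  n_frames = 1),
              layerThickness = 1, zReference = "pore bottom = 0 A",
              landmarks = c(R220 = 73.5), flags = list())
  d <- densityProfile(tr, "CL", prof, step = 100)
  expect_equal(mean(layers(d)$density_mean), 6.022e-4, tolerance = 0.06)

  dK <- densityProfile(tr, "K", prof, step = 100)
  expect_true(all(layers(dK)$density_mean == 0))

  # uniform system: halving the analysis radius leaves density unchanged
  profHalf <- prof
  profHalf@layers$radius_mean <- R / 2
  dH <- densityProfile(tr, "CL", profHalf, step = 100)
  expect_equal(mean(layers(dH)$density_mean), 6.022e-4, tolerance = 0.12)
})

test_that("Gaussian histogram fit: location/scale, SE-level accuracy, bimodal flag", {
  f0 <- fitCurrentHistogram(rep(61.5, 200))
  expect_equal(f0$mean, 61.5)
  expect_equal(f0$sd, 0)
  expect_true(f0$degenerate)

  set.seed(82)
  x <- rnorm(1e5, 61.5, 0.7)
  f1 <- fitCurrentHistogram(x)
  expect_lt(abs(f1$mean - 61.5), 0.01)  # SE = 0.7/sqrt(1e5) = 0.0022
  expect_equal(f1$sd, 0.7, tolerance = 0.03)
  expect_false(f1$poor_fit)

  set.seed(83)
  bi <- c(rnorm(5e4, 30, 1), rnorm(5e4, 62, 1))
  expect_true(fitCurrentHistogram(bi)$poor_fit)
})

test_that("selectivity ratio: limits and the 3:1 mobility phantom", {
  mk <- function(ik, icl) new("CurrentEstimate", ITotal = ik + icl, IK = ik,
                              ICl = icl, sdBlocks = 0, voltage = 150,
                              nFrames = 2L, blockMeans = ik + icl)
  expect_equal(selectivityRatio(mk(0, 50)), 1.0)
  expect_equal(selectivityRatio(mk(25, 25)), 0.5)
  expect_error(selectivityRatio(mk(0, 0)), "undefined-ratio")

  cs <- cylinderSpec(6, length = 40)
  spec <- driftDiffusionSpec(50, 0.005, mobility = c(K = 0.01, CL = 0.03),
                             field = 0.5, duration = 5000,
                             frameInterval = 10, seed = 84)
  est <- computeSpeciesCurrents(genIonTrajectory(spec, cs))
  expect_equal(selectivityRatio(est), 0.75, tolerance = 0.05)
})
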