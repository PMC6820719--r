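# Pore axis, slice/ring radius profile, region diameters, RMSF.

test_that("pore axis: symmetry, translation equivariance, SE-scale accuracy", {
  ch <- genChannelStructure(cylinderSpec(6), seed = 41)
  ax <- computePoreAxis(ch$trajectory)
  expect_equal(ax$center, c(0, 0), tolerance = 1e-6)
  expect_equal(ax$direction, c(0, 0, 1))

  tr <- ch$trajectory
  tr@coords[, 1, ] <- tr@coords[, 1, ] + 5
  tr@coords[, 2, ] <- tr@coords[, 2, ] + 5
  ax2 <- computePoreAxis(tr)
  expect_equal(ax2$center, ax$center + c(5, 5), tolerance = 1e-9)
  expect_equal(ax2$zBottom, ax$zBottom)

  # jittered cylinder: axis recovered within the SE of the jitter mean
  set.seed(42)
  n <- 1e4
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]  # balanced ring
  topo <- data.frame(particle_id = 1:n, species = "PROT", charge = 0)
  coords <- array(c(3 + 6 * cos(th) + rnorm(n, 0, 0.1),
                    -2 + 6 * sin(th) + rnorm(n, 0, 0.1),
                    runif(n, 0, 40)), c(n, 3, 1))
  tj <- IonTrajectory(topo, coords, times = 0, box = c(30, 30, 40),
                      voltage = 0, dt = 1)
  expect_lt(max(abs(computePoreAxis(tj)$center - c(3, -2))), 0.02)

  topoW <- topo; topoW$species <- "WAT"
  expect_error(computePoreAxis(IonTrajectory(topoW, coords, times = 0,
                                             box = c(30, 30, 40),
                                             voltage = 0, dt = 1)),
               "no protein")
})

test_that("slice radius profile recovers cylinder radii within one increment", {
  for (r in c(3, 5, 8, 10)) {
    ch <- genChannelStructure(cylinderSpec(r, length = 40), seed = 43 + r)
    prof <- sliceRadiusProfile(ch$trajectory)
    expect_true(all(abs(layers(prof)$radius_mean - r) <= 0.5),
                label = sprintf("cylinder r = %g", r))
  }
})

test_that("radius values live on the 0.5 A grid starting at 1 A", {
  ch <- genChannelStructure(hourglassSpec(), seed = 44)
  prof <- sliceRadiusProfile(ch$trajectory)
  rr <- layers(prof)$radius_mean  # single frame: means are per-frame values
  expect_true(all(abs((rr - 1) / 0.5 - round((rr - 1) / 0.5)) < 1e-9))
  expect_true(all(rr >= 1))
})

test_that("hourglass profile bottoms out at the constructed waist", {
  ch <- genChannelStructure(hourglassSpec(), seed = 45)
  prof <- sliceRadiusProfile(ch$trajectory)
  expect_equal(profileArgmin(prof), 20, tolerance = 2)
  l <- layers(prof)
  expect_equal(min(l$radius_mean), 3, tolerance = 0.5)
})

test_that("a first annulus holding only wall atoms pins the radius at 1 A", {
  # plugged layer: wall atoms fill rho <= 1.5 in one slice
  ch <- genChannelStructure(cylinderSpec(6, length = 10), seed = 46)
  tr <- ch$trajectory
  set.seed(46)
  nPlug <- 300L
  rad <- 1.5 * sqrt(runif(nPlug))
  ang <- runif(nPlug, 0, 2 * pi)
  plug <- data.frame(particle_id = max(tr@topology$particle_id) + 1:nPlug,
                     species = "PROT", charge = 0)
  topo <- rbind(tr@topology, plug)
  coords <- array(NA_real_, c(nrow(topo), 3, 1))
  coords[seq_len(nParticles(tr)), , 1] <- tr@coords[, , 1]
  coords[nParticles(tr) + 1:nPlug, , 1] <-
    cbind(rad * cos(ang), rad * sin(ang), runif(nPlug, 4, 5))
  # remove water from the plugged slice so the first annulus is wall-only
  w <- topo$species == "WAT" & coords[, 3, 1] >= 4 & coords[, 3, 1] < 5
  keep <- !w
  tj <- IonTrajectory(topo[keep, ], coords[keep, , , drop = FALSE],
                      times = 0, box = tr@box, voltage = 0, dt = 1)
  prof <- sliceRadiusProfile(tj)
  expect_equal(layers(prof)$radius_mean[5], 1)
})

test_that("radius profile is invariant under rotation about the pore axis", {
  ch <- genChannelStructure(hourglassSpec(), seed = 47)
  tr <- ch$trajectory
  prof <- sliceRadiusProfile(tr)
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  tr2 <- tr
  tr2@coords[, , 1] <- tr@coords[, , 1] %*% R
  prof2 <- sliceRadiusProfile(tr2)
  expect_identical(layers(prof)$radius_mean, layers(prof2)$radius_mean)
})

test_that("diameterAtRegion averages 2x radius over the window", {
  l <- data.frame(z_center = seq(0.5, 99.5, 1), radius_mean = 6,
                  radius_sd = 0, n_frames = 1)
  prof <- new("RadiusProfile", layers = l, layerThickness = 1,
              zReference = "pore bottom = 0 A",
              landmarks = c(R282 = 88.5, R220 = 73.5, K238 = 22.5,
                            K242 = 10.5), flags = list())
  for (reg in c("R282", "R220", "K238", "K242"))
    expect_equal(unname(diameterAtRegion(prof, reg)["diameter_mean"]), 12)

  l2 <- l
  l2$radius_mean[l2$z_center %in% c(72.5, 73.5, 74.5)] <- c(5, 6, 7)
  prof2 <- new("RadiusProfile", layers = l2, layerThickness = 1,
               zReference = "pore bottom = 0 A",
               landmarks = c(R220 = 73.5), flags = list())
  expect_equal(unname(diameterAtRegion(prof2, "R220")["diameter_mean"]), 12)
  expect_error(diameterAtRegion(prof2, z = 300), "empty window")

  # hourglass waist diameter equals twice the waist radius within 1 A
  ch <- genChannelStructure(hourglassSpec(), seed = 48)
  prof3 <- sliceRadiusProfile(ch$trajectory)
  d <- diameterAtRegion(prof3, z = 20)
  expect_lte(abs(d[["diameter_mean"]] - 6), 1)  # one 2x0.5 A increment
})

test_that("RMSF: zero for static, closed form for jitter, rigid-motion invariant", {
  st <- proteinTraj(nAtoms = 30, nFrames = 10, seed = 51)
  r0 <- rmsfProfile(st)
  expect_true(all(r0$rmsf < 1e-10))

  tj <- proteinTraj(nAtoms = 50, nFrames = 500, jitterAtom = 7,
                    sigma = 0.5, seed = 52)
  r1 <- rmsfProfile(tj)
  # isotropic sigma = 0.5 per coordinate: RMSF = sqrt(3)*0.5 = 0.866
  expect_equal(r1$rmsf[7], sqrt(3) * 0.5, tolerance = 0.08)
  # superposition spreads ~sigma/sqrt(N) of the jitter onto the others
  expect_true(all(r1$rmsf[-7] < 0.1))

  # global rigid translation+rotation per frame leaves RMSF unchanged
  tj2 <- tj
  for (f in seq_len(nFrames(tj2))) {
    a <- 0.01 * f
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    tj2@coords[, , f] <- tj@coords[, , f] %*% R +
      matrix(rep(c(f, -f, 2 * f), each = 50), ncol = 3)
  }
  r2 <- rmsfProfile(tj2)
  expect_equal(r2$rmsf, r1$rmsf, tolerance = 1e-3)

  expect_error(rmsfProfile(st, frames = 1), "degenerate")
})
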