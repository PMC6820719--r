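# Phantom builders shared across test files.  Everything is generated in
# code; no fixture files.

cylinderSpec <- function(r, length = 40, density = 4, spacing = 1) {
  channelSpec(data.frame(z = c(0, length), r = c(r, r)),
              wallAtomSpacing = spacing, waterNumberDensity = density)
}

hourglassSpec <- function(density = 4) {
  channelSpec(data.frame(z = c(0, 20, 40), r = c(8, 3, 8)),
              waterNumberDensity = density)
}

# trajectory of uniformly re-placed ions in a cylinder (independent frames),
# with a sparse wall so the pore axis is defined; used for density tests
uniformIonTraj <- function(nIons, R, L, nFrames, seed, species = "CL",
                           ionRadius = R) {
  set.seed(seed)
  nWall <- 60L
  th <- seq(0, 2 * pi, length.out = nWall + 1L)[-1]
  wall <- cbind(R * cos(th), R * sin(th),
                rep(seq(0, L, length.out = 6), length.out = nWall))
  topo <- data.frame(
    particle_id = seq_len(nWall + nIons),
    species = c(rep("PROT", nWall), rep(species, nIons)),
    charge = c(rep(0, nWall),
               rep(unname(c(K = 1, CL = -1, WAT = 0)[species]), nIons)))
  coords <- array(NA_real_, c(nWall + nIons, 3L, nFrames))
  for (f in seq_len(nFrames)) {
    rad <- ionRadius * sqrt(runif(nIons))
    ang <- runif(nIons, 0, 2 * pi)
    coords[, , f] <- rbind(wall,
                           cbind(rad * cos(ang), rad * sin(ang),
                                 runif(nIons, 0, L)))
  }
  IonTrajectory(topo, coords, times = (seq_len(nFrames) - 1) * 100,
                box = c(4 * R, 4 * R, L), voltage = 0, dt = 100)
}

# static protein trajectory with optional per-atom Gaussian jitter
proteinTraj <- function(nAtoms = 50, nFrames = 200, jitterAtom = NULL,
                        sigma = 0, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(nAtoms * 3, sd = 10), ncol = 3)
  coords <- array(rep(base, nFrames), c(nAtoms, 3L, nFrames))
  if (!is.null(jitterAtom))
    coords[jitterAtom, , ] <- coords[jitterAtom, , ] +
      rnorm(3 * nFrames, sd = sigma)
  topo <- data.frame(particle_id = seq_len(nAtoms), species = "PROT",
                     charge = 0)
  IonTrajectory(topo, coords, times = seq_len(nFrames) - 1,
                box = c(100, 100, 100), voltage = 0, dt = 1)
}

# z of the profile minimum, tie-broken by the midpoint of tied layers
profileArgmin <- function(profile) {
  l <- layers(profile)
  mean(l$z_center[l$radius_mean == min(l$radius_mean)])
}
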