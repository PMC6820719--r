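## Synthetic generators with known ground truth.
##
## Three parameter bundles (plain validated lists): channelSpec() describes a
## pseudo-atom channel wall with a piecewise-linear radius profile filled
## with water particles; driftDiffusionSpec() describes 1-D drift-diffusion
## ion motion along z under a uniform axial field with hard-wall lateral
## confinement; traceSpec() describes a two-state (open/blocked) current
## trace with Gaussian noise, Poisson event arrivals and exponential dwells.
## All generators are deterministic given their seed.

#' Channel phantom specification
#'
#' @param knots two-column matrix/data.frame of (z, r) knots in Angstrom;
#'   the radius profile is piecewise linear between them.  r(z) must be
#'   positive everywhere and knots sorted by z.
#' @param length channel length in Angstrom (defaults to the z of the last
#'   knot).
#' @param wallAtomSpacing spacing of wall pseudo-atoms on the surface, in
#'   Angstrom.
#' @param waterNumberDensity pseudo-water particles per cubic Angstrom.
#'   The default (4.0) oversamples real water on purpose: it is a sampling
#'   resolution chosen so that every 0.5 Angstrom annulus of a 1 Angstrom
#'   layer is populated, which is what the slice/ring radius algorithm
#'   probes.  The phantom tests geometry, not hydration physics.
#' @return a `ChannelSpec` (validated list).
#' @export
channelSpec <- function(knots, length = NULL, wallAtomSpacing = 1.0,
                        waterNumberDensity = 4.0) {
  knots <- as.data.frame(knots)
  names(knots) <- c("z", "r")
  if (nrow(knots) < 2L) stop("need at least two radius knots")
  if (any(diff(knots$z) <= 0)) stop("knots must be sorted by z")
  if (any(knots$r <= 0)) stop("r(z) must be positive everywhere")
  if (is.null(length)) length <- max(knots$z)
  if (wallAtomSpacing <= 0 || waterNumberDensity <= 0)
    stop("spacing and density must be positive")
  structure(list(knots = knots, length = length,
                 wallAtomSpacing = wallAtomSpacing,
                 waterNumberDensity = waterNumberDensity),
            class = "ChannelSpec")
}

#' Local channel radius r(z) of a spec (piecewise linear, clamped at ends)
#' @param spec a `ChannelSpec`.
#' @param z positions in Angstrom.
#' @return radii in Angstrom.
#' @export
channelRadiusAt <- function(spec, z) {
  approx(spec$knots$z, spec$knots$r, xout = z, rule = 2)$y
}

#' Drift-diffusion ion motion specification
#'
#' Each ion takes Euler-Maruyama steps along z:
#' `dz = q * mobility * field * dt + sqrt(2 D dt) * N(0,1)`, with periodic
#' wrap in z and lateral hard-wall confinement at r(z).  The expected
#' steady-state per-species drift current has the closed form
#' `I_s = n_s * q_s^2 * mobility * field * e / L_z`
#' (see [analyticDriftCurrent()]).
#'
#' @param nIonsPerSpecies ions of each of K and Cl.
#' @param diffusionCoefficient D in Angstrom^2/ps (>= 0).
#' @param mobility in Angstrom^2/(ps * mV/Angstrom); sign enters via the
#'   ion charge.  Either a scalar (both species) or a named vector
#'   `c(K =, CL =)` for species-dependent mobility.
#' @param field uniform axial field in mV/Angstrom (signed).
#' @param duration total simulated time in ps.
#' @param frameInterval time between stored frames in ps.
#' @param seed RNG seed.
#' @return a `DriftDiffusionSpec` (validated list).
#' @export
driftDiffusionSpec <- function(nIonsPerSpecies, diffusionCoefficient,
                               mobility, field, duration, frameInterval,
                               seed = 1L) {
  if (duration < frameInterval || frameInterval <= 0)
    stop("need duration >= frameInterval > 0")
  if (diffusionCoefficient < 0) stop("diffusion coefficient must be >= 0")
  if (length(mobility) == 1L) mobility <- c(K = mobility, CL = mobility)
  if (!all(c("K", "CL") %in% names(mobility)))
    stop("mobility must be scalar or named c(K =, CL =)")
  structure(list(nIonsPerSpecies = as.integer(nIonsPerSpecies),
                 diffusionCoefficient = diffusionCoefficient,
                 mobility = mobility, field = field, duration = duration,
                 frameInterval = frameInterval, seed = as.integer(seed)),
            class = "DriftDiffusionSpec")
}

#' Two-state current trace specification
#'
#' Baseline Gaussian noise around the open-pore current; blockade events
#' arrive as a Poisson process, each dropping the current to
#' `openCurrent * (1 - blockadeDepth)` for an exponentially distributed
#' dwell.  Overlapping events are merged (and flagged) in the ground truth,
#' because detection cannot distinguish overlapped events.
#'
#' @param openCurrent I0 in pA (signed).
#' @param noiseSd baseline noise sd in pA.
#' @param eventRate Poisson arrival rate in events/s.
#' @param dwellMean mean dwell in s (exponential).
#' @param blockadeDepth fractional drop, in (0, 1].
#' @param duration trace length in s.
#' @param samplingRate Hz.
#' @param seed RNG seed.
#' @return a `TraceSpec` (validated list).
#' @export
traceSpec <- function(openCurrent, noiseSd, eventRate, dwellMean,
                      blockadeDepth, duration, samplingRate = 1e5,
                      seed = 1L) {
  if (blockadeDepth <= 0 || blockadeDepth > 1)
    stop("blockadeDepth must be in (0, 1]")
  if (eventRate * dwellMean >= 0.5)
    stop("events must be dilute: eventRate * dwellMean < 0.5")
  if (duration <= 0 || samplingRate <= 0 || noiseSd < 0)
    stop("invalid trace dimensions")
  structure(list(openCurrent = openCurrent, noiseSd = noiseSd,
                 eventRate = eventRate, dwellMean = dwellMean,
                 blockadeDepth = blockadeDepth, duration = duration,
                 samplingRate = samplingRate, seed = as.integer(seed)),
            class = "TraceSpec")
}

#' Generate a pseudo-atom channel structure filled with static water
#'
#' Wall pseudo-atoms are placed on rings of the surface r(z) at the
#' requested spacing (every ring offset by the golden angle so atoms do not
#' align in z); water particles fill the interior uniformly at the
#' requested number density.  Returns both a [PoreStructure-class] (walls)
#' and a single-frame [IonTrajectory-class] carrying walls plus water, the
#' direct substrate for [sliceRadiusProfile()].
#'
#' @param spec a [channelSpec()].
#' @param seed RNG seed for water placement.
#' @return list with elements `structure` (PoreStructure) and `trajectory`
#'   (one-frame IonTrajectory).  If any 1 Angstrom layer holds no water, a
#'   `sparse_water` warning flag is set in `trajectory@@topology`'s
#'   attributes.
#' @export
genChannelStructure <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ChannelSpec"))
  withSeed(seed, {
    L <- spec$length
    s <- spec$wallAtomSpacing
    zRows <- seq(0, L, by = s)
    golden <- pi * (3 - sqrt(5))
    wall <- do.call(rbind, lapply(seq_along(zRows), function(i) {
      z <- zRows[i]
      r <- channelRadiusAt(spec, z)
      n <- max(3L, round(2 * pi * r / s))
      th <- (seq_len(n) - 1) * 2 * pi / n + (i - 1) * golden
      data.frame(x = r * cos(th), y = r * sin(th), z = z)
    }))
    ## water count from the interior volume integral density * int pi r^2 dz
    zg <- seq(0, L, length.out = 2001)
    r2 <- channelRadiusAt(spec, zg)^2
    vol <- pi * sum((r2[-1] + r2[-length(r2)]) / 2 * diff(zg))
    nW <- round(spec$waterNumberDensity * vol)
    ## z ~ density proportional to r(z)^2, by rejection against max r^2
    zW <- numeric(0)
    rmax2 <- max(r2)
    while (length(zW) < nW) {
      cand <- runif(nW, 0, L)
      keep <- runif(nW) < channelRadiusAt(spec, cand)^2 / rmax2
      zW <- c(zW, cand[keep])
    }
    zW <- zW[seq_len(nW)]
    rad <- channelRadiusAt(spec, zW) * sqrt(runif(nW))
    th <- runif(nW, 0, 2 * pi)
    water <- data.frame(x = rad * cos(th), y = rad * sin(th), z = zW)

    rmax <- max(spec$knots$r)
    box <- c(2 * (rmax + 2 * s), 2 * (rmax + 2 * s), L)
    nP <- nrow(wall)
    atoms <- data.frame(atom_id = seq_len(nP), residue_name = "PRT",
                        residue_number = findInterval(wall$z, zRows),
                        chain_id = "A", species = "PROT",
                        x = wall$x, y = wall$y, z = wall$z,
                        radius = NA_real_, stringsAsFactors = FALSE)
    structure_ <- PoreStructure(atoms, box)
    topo <- data.frame(
      particle_id = seq_len(nP + nW),
      species = c(rep("PROT", nP), rep("WAT", nW)),
      charge = 0, stringsAsFactors = FALSE)
    coords <- array(NA_real_, c(nP + nW, 3L, 1L))
    coords[, 1, 1] <- c(wall$x, water$x)
    coords[, 2, 1] <- c(wall$y, water$y)
    coords[, 3, 1] <- c(wall$z, water$z)
    traj <- IonTrajectory(topo, coords, times = 0, box = box, voltage = 0,
                          dt = 1)
    ## flag layers left without water (density too low for the layering)
    lay <- findInterval(zW, seq(0, L, by = 1), rightmost.closed = TRUE)
    empty <- setdiff(seq_len(max(1, floor(L))), unique(lay))
    if (length(empty)) attr(traj@topology, "sparse_water") <- empty
    list(structure = structure_, trajectory = traj)
  })
}

#' Closed-form drift current of a drift-diffusion phantom
#'
#' `I_total = sum_s n_s q_s^2 mobility field e / L_z`, converted to pA.
#' Both species drift in opposite directions with opposite charge, so their
#' contributions add.
#'
#' @param spec a [driftDiffusionSpec()].
#' @param channel the [channelSpec()] providing L_z.
#' @return named numeric: `I_total`, `I_K`, `I_Cl` in pA.
#' @export
analyticDriftCurrent <- function(spec, channel) {
  L <- channel$length
  ## q^2 = 1 for both K(+1) and Cl(-1)
  IK <- spec$nIonsPerSpecies * spec$mobility[["K"]] * spec$field / L *
    .PA_PER_E_PS
  ICl <- spec$nIonsPerSpecies * spec$mobility[["CL"]] * spec$field / L *
    .PA_PER_E_PS
  c(I_total = IK + ICl, I_K = IK, I_Cl = ICl)
}

#' Generate a drift-diffusion ion trajectory in a channel
#'
#' Equal numbers of K+ and Cl- ions start uniformly distributed in the
#' channel interior and take one Euler-Maruyama step per stored frame:
#' axial drift `q * mobility * field * dt` plus `sqrt(2 D dt)` Gaussian
#' noise in all three coordinates; lateral positions are reflected at the
#' wall r(z); z wraps periodically over the channel length.  Stored
#' coordinates are wrapped; [computeSpeciesCurrents()] recovers
#' displacements by minimum image, which requires the per-frame drift to be
#' below L_z/2 (checked here).
#'
#' @param spec a [driftDiffusionSpec()].
#' @param channel a [channelSpec()].
#' @return an [IonTrajectory-class]; `voltage` metadata is
#'   `field * length` in mV.
#' @export
genIonTrajectory <- function(spec, channel) {
  stopifnot(inherits(spec, "DriftDiffusionSpec"),
            inherits(channel, "ChannelSpec"))
  L <- channel$length
  dt <- spec$frameInterval
  drift <- max(abs(spec$mobility * spec$field * dt))
  if (drift + 6 * sqrt(2 * spec$diffusionCoefficient * dt) >= L / 2)
    stop("stability error: per-frame step is not small against the channel",
         call. = FALSE)
  n <- spec$nIonsPerSpecies
  withSeed(spec$seed, {
    np <- 2L * n
    q <- rep(c(1, -1), each = n)
    species <- rep(c("K", "CL"), each = n)
    z <- runif(np, 0, L)
    rr <- channelRadiusAt(channel, z) * sqrt(runif(np))
    th <- runif(np, 0, 2 * pi)
    x <- rr * cos(th); y <- rr * sin(th)
    nf <- floor(spec$duration / dt) + 1L
    coords <- array(NA_real_, c(np, 3L, nf))
    coords[, , 1] <- cbind(x, y, z)
    sig <- sqrt(2 * spec$diffusionCoefficient * dt)
    v <- q * spec$mobility[species] * spec$field
    for (k in seq_len(nf - 1L)) {
      z <- (z + v * dt + sig * rnorm(np)) %% L
      x <- x + sig * rnorm(np)
      y <- y + sig * rnorm(np)
      ## lateral hard wall: reflect radially inside r(z)
      rw <- channelRadiusAt(channel, z)
      rad <- sqrt(x^2 + y^2)
      out <- rad > rw
      if (any(out)) {
        refl <- (2 * rw[out] - rad[out]) / rad[out]
        refl <- pmax(refl, 0)  # very large excursions land on the axis side
        x[out] <- x[out] * refl
        y[out] <- y[out] * refl
      }
      coords[, , k + 1L] <- cbind(x, y, z)
    }
    rmax <- max(channel$knots$r)
    IonTrajectory(
      data.frame(particle_id = seq_len(np), species = species, charge = q,
                 stringsAsFactors = FALSE),
      coords, times = (seq_len(nf) - 1) * dt,
      box = c(2 * rmax + 4, 2 * rmax + 4, L),
      voltage = spec$field * L, dt = dt)
  })
}

#' Generate a two-state current trace with ground-truth events
#'
#' @param spec a [traceSpec()].
#' @return list with `trace` (a [CurrentTrace-class]) and `truth` (an
#'   [EventTable-class] of the merged blockade intervals; overlap-merged
#'   events carry `merged = TRUE`).
#' @export
genCurrentTrace <- function(spec) {
  stopifnot(inherits(spec, "TraceSpec"))
  withSeed(spec$seed, {
    fs <- spec$samplingRate
    nSamp <- round(spec$duration * fs)
    cur <- spec$openCurrent + rnorm(nSamp, 0, spec$noiseSd)
    nEv <- rpois(1, spec$eventRate * spec$duration)
    if (nEv > 0) {
      starts <- sort(runif(nEv, 0, spec$duration))
      dwells <- rexp(nEv, rate = 1 / spec$dwellMean)
      ends <- pmin(starts + dwells, spec$duration)
      ## merge overlapping intervals; flag merges in the ground truth
      ms <- starts[1]; me <- ends[1]; mf <- FALSE
      outS <- numeric(0); outE <- numeric(0); outM <- logical(0)
      if (nEv > 1) for (i in 2:nEv) {
        if (starts[i] <= me) { me <- max(me, ends[i]); mf <- TRUE }
        else {
          outS <- c(outS, ms); outE <- c(outE, me); outM <- c(outM, mf)
          ms <- starts[i]; me <- ends[i]; mf <- FALSE
        }
      }
      outS <- c(outS, ms); outE <- c(outE, me); outM <- c(outM, mf)
      keep <- outE > outS
      outS <- outS[keep]; outE <- outE[keep]; outM <- outM[keep]
      blocked <- spec$openCurrent * (1 - spec$blockadeDepth)
      i0 <- pmin(floor(outS * fs) + 1, nSamp)
      i1 <- pmin(ceiling(outE * fs), nSamp)
      for (i in seq_along(outS)) {
        idx <- i0[i]:i1[i]
        cur[idx] <- blocked + rnorm(length(idx), 0, spec$noiseSd)
      }
      truth <- EventTable(
        data.frame(start = outS, end = outE, dwell = outE - outS,
                   mean_blockade_pA = blocked,
                   ires_over_i0 = 1 - spec$blockadeDepth, merged = outM),
        I0 = spec$openCurrent, baselineSd = spec$noiseSd,
        voltage = NA_real_, duration = spec$duration,
        params = unclass(spec))
    } else {
      truth <- EventTable(data.frame(), I0 = spec$openCurrent,
                          baselineSd = spec$noiseSd, voltage = NA_real_,
                          duration = spec$duration, params = unclass(spec))
    }
    list(trace = CurrentTrace(cur, fs, voltage = NA_real_,
                              label = "synthetic"),
         truth = truth)
  })
}

#' Generate per-voltage dwell-time series for the translocation classifier
#'
#' Translocating mode draws dwell means `baseDwell * exp(-|V|/decay)`;
#' non-translocating (bumping) mode keeps the dwell mean constant across
#' voltages.
#'
#' @param baseDwell dwell mean at V = 0 (translocating) or at every voltage
#'   (non-translocating), in seconds.
#' @param decayConstant voltage scale of the exponential decrease, in mV.
#' @param voltages numeric vector of at least 3 voltages (mV).
#' @param mode "translocating" or "non_translocating".
#' @param nEvents events drawn per voltage.
#' @param seed RNG seed.
#' @return list (one element per voltage) of `list(voltage =, events =)`
#'   where `events` is an [EventTable-class].
#' @export
genVoltageSeries <- function(baseDwell, decayConstant, voltages,
                             mode = c("translocating", "non_translocating"),
                             nEvents = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(voltages) < 3L)
    stop("input error: need at least 3 voltages", call. = FALSE)
  withSeed(seed, {
    lapply(voltages, function(v) {
      m <- if (mode == "translocating")
        baseDwell * exp(-abs(v) / decayConstant) else baseDwell
      d <- rexp(nEvents, rate = 1 / m)
      gaps <- rexp(nEvents, rate = 1 / (10 * m))
      start <- cumsum(gaps) + c(0, cumsum(d[-nEvents]))
      ev <- EventTable(
        data.frame(start = start, end = start + d, dwell = d,
                   mean_blockade_pA = NA_real_, ires_over_i0 = NA_real_,
                   merged = FALSE),
        voltage = v, duration = max(start + d),
        params = list(mode = mode, dwell_mean = m))
      list(voltage = v, events = ev)
    })
  })
}
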