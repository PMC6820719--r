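## Pore geometry from trajectories: axis, slice/ring radius profile,
## named-region diameters, per-residue RMSF.

.isProtein <- function(species) !(species %in% c("WAT", "K", "CL"))

#' Compute the pore axis of a frame
#'
#' The axis passes through the center of mass of the protein (pseudo-)atoms
#' and is oriented along +z (the membrane normal).  z = 0 is placed at the
#' lowest protein atom (pore-bottom convention).
#'
#' @param x an [IonTrajectory-class] or [PoreStructure-class].
#' @param frame frame index when `x` is a trajectory.
#' @return list with `center` (x, y of the axis), `zBottom` (z of the
#'   lowest protein atom in input coordinates) and `direction` (0, 0, 1).
#' @export
computePoreAxis <- function(x, frame = 1L) {
  if (is(x, "PoreStructure")) {
    sel <- .isProtein(x@atoms$species)
    if (!any(sel)) stop("input error: no protein particles", call. = FALSE)
    xyz <- as.matrix(x@atoms[sel, c("x", "y", "z")])
  } else if (is(x, "IonTrajectory")) {
    sel <- .isProtein(x@topology$species)
    if (!any(sel)) stop("input error: no protein particles", call. = FALSE)
    xyz <- x@coords[sel, , frame, drop = FALSE]
    dim(xyz) <- c(sum(sel), 3L)
  } else stop("unsupported input")
  list(center = c(mean(xyz[, 1]), mean(xyz[, 2])),
       zBottom = min(xyz[, 3]),
       direction = c(0, 0, 1))
}

#' Default analysis frame selection
#'
#' Discards the first quarter of the frames as equilibration, then strides
#' the remainder down to at most `maxFrames` frames.
#'
#' @param n number of frames available.
#' @param maxFrames cap on selected frames.
#' @return integer vector of frame indices.
#' @export
defaultFrameSelection <- function(n, maxFrames = 16L) {
  start <- floor(0.25 * n) + 1L
  sel <- start:n
  if (length(sel) > maxFrames)
    sel <- sel[unique(round(seq(1, length(sel), length.out = maxFrames)))]
  sel
}

#' Slice/ring local radius profile of the water-filled cavity
#'
#' Per 1 Angstrom z-layer and per frame, the local radius starts at 1
#' Angstrom and grows in 0.5 Angstrom increments while the ratio of water
#' to non-water atoms inside the added annulus exceeds `ratio` (default
#' 25\%).  An annulus holding water but no non-water atoms passes; an empty
#' annulus stops the iteration.  Radial distances are measured from the
#' per-frame pore axis ([computePoreAxis()]); z is measured from the pore
#' bottom.  The profile reports mean and sd of the layer radius across the
#' selected frames.
#'
#' @param traj an [IonTrajectory-class] containing WAT and non-WAT species.
#' @param frames frame indices; default [defaultFrameSelection()].
#' @param layerThickness slice thickness in Angstrom.
#' @param increment radial growth step in Angstrom.
#' @param ratio acceptance threshold for the water/non-water count ratio.
#' @param ratioMode `"w_over_p"` counts water/(non-water) as the ratio
#'   (the literal reading); `"w_over_all"` uses water/(all atoms).  The two
#'   behave identically on densely watered phantoms.
#' @param maxRadius hard ceiling; default `min(Lx, Ly)/2`.
#' @return a [RadiusProfile-class].
#' @export
sliceRadiusProfile <- function(traj, frames = NULL, layerThickness = 1.0,
                               increment = 0.5, ratio = 0.25,
                               ratioMode = c("w_over_p", "w_over_all"),
                               maxRadius = NULL) {
  stopifnot(is(traj, "IonTrajectory"))
  ratioMode <- match.arg(ratioMode)
  if (is.null(frames)) frames <- defaultFrameSelection(nFrames(traj))
  if (!length(frames)) stop("frame selection is empty", call. = FALSE)
  sp <- traj@topology$species
  isW <- sp %in% .WATER_SPECIES
  if (!any(isW) || !any(!isW))
    stop("trajectory must contain water and non-water species",
         call. = FALSE)
  if (is.null(maxRadius)) maxRadius <- min(traj@box[1], traj@box[2]) / 2
  prot <- .isProtein(sp)

  ## common layer grid sized from the protein z-extent over selected frames
  zspan <- max(vapply(frames, function(f) {
    z <- traj@coords[prot, 3, f]
    max(z) - min(z)
  }, 0))
  nLayers <- max(1L, ceiling(zspan / layerThickness - 1e-9))
  nShellMax <- max(1L, ceiling((maxRadius - 1) / increment))

  radMat <- matrix(NA_real_, nLayers, length(frames))
  emptyStart <- logical(nLayers)
  for (j in seq_along(frames)) {
    f <- frames[j]
    axis <- computePoreAxis(traj, f)
    xs <- traj@coords[, 1, f] - axis$center[1]
    ys <- traj@coords[, 2, f] - axis$center[2]
    zs <- traj@coords[, 3, f] - axis$zBottom
    rho <- sqrt(xs^2 + ys^2)
    lay <- floor(zs / layerThickness) + 1L
    lay[zs >= nLayers * layerThickness] <- nLayers  # top boundary inclusive
    ## shell index: k means rho in (1 + (k-1)*inc, 1 + k*inc]
    shell <- ceiling((rho - 1) / increment)
    inGrid <- lay >= 1L & lay <= nLayers & shell >= 1L & shell <= nShellMax
    wCnt <- matrix(0L, nLayers, nShellMax)
    pCnt <- matrix(0L, nLayers, nShellMax)
    iw <- inGrid & isW
    ip <- inGrid & !isW
    if (any(iw)) {
      t1 <- table(factor(lay[iw], levels = seq_len(nLayers)),
                  factor(shell[iw], levels = seq_len(nShellMax)))
      wCnt <- matrix(as.integer(t1), nLayers, nShellMax)
    }
    if (any(ip)) {
      t2 <- table(factor(lay[ip], levels = seq_len(nLayers)),
                  factor(shell[ip], levels = seq_len(nShellMax)))
      pCnt <- matrix(as.integer(t2), nLayers, nShellMax)
    }
    for (l in seq_len(nLayers)) {
      r <- 1
      for (k in seq_len(nShellMax)) {
        w <- wCnt[l, k]; p <- pCnt[l, k]
        if (w + p == 0L) { if (k == 1L) emptyStart[l] <- TRUE; break }
        pass <- if (ratioMode == "w_over_p") {
          if (p == 0L) TRUE else (w / p > ratio)
        } else (w / (w + p) > ratio)
        if (!pass) break
        r <- r + increment
        if (r >= maxRadius) break
      }
      radMat[l, j] <- min(r, maxRadius)
    }
  }
  means <- rowMeans(radMat)
  sds <- apply(radMat, 1, function(v) if (length(v) > 1) sd(v) else 0)
  layersDf <- data.frame(
    z_center = (seq_len(nLayers) - 0.5) * layerThickness,
    radius_mean = means, radius_sd = sds, n_frames = length(frames))
  RadiusProfile(layersDf, layerThickness,
                flags = list(empty_first_annulus = which(emptyStart),
                             per_frame = radMat))
}

#' Mean diameter at a named sensing region or explicit z
#'
#' Averages the diameter (2 x radius) over the layers within
#' `window / 2` of the landmark.  Landmarks default to the aerolysin
#' sensing-region positions above the pore bottom: R282 at 88.5, R220 at
#' 73.5 (cap), K238 at 22.5, K242 at 10.5 Angstrom (stem); they are
#' configurable through the profile's `landmarks` slot.
#'
#' @param profile a [RadiusProfile-class].
#' @param region one of the landmark names, or NULL when `z` is given.
#' @param z explicit position in Angstrom (overrides `region`).
#' @param window averaging window in Angstrom (default 3).
#' @return named numeric: `diameter_mean`, `diameter_sd` (Angstrom).
#' @export
diameterAtRegion <- function(profile, region = NULL, z = NULL, window = 3) {
  stopifnot(is(profile, "RadiusProfile"))
  if (is.null(z)) {
    if (is.null(region) || !region %in% names(profile@landmarks))
      stop("unknown region; give one of ",
           paste(names(profile@landmarks), collapse = ", "),
           " or an explicit z", call. = FALSE)
    z <- profile@landmarks[[region]]
  }
  l <- profile@layers
  sel <- abs(l$z_center - z) <= window / 2
  if (!any(sel))
    stop("input error: empty window at z = ", z, call. = FALSE)
  c(diameter_mean = mean(2 * l$radius_mean[sel]),
    diameter_sd = mean(2 * l$radius_sd[sel]))
}

## Kabsch: rotation R minimizing ||mobile %*% R - fixed|| (both centered)
.kabsch <- function(fixed, mobile) {
  s <- svd(t(mobile) %*% fixed)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Per-residue RMSF after rigid superposition
#'
#' Each frame is superposed (optimal rigid-body fit, Kabsch) onto the
#' frame-average structure before fluctuations are accumulated; the mean
#' structure is refined once after the first fit round.  RMSF of a residue
#' is the root of the mean squared deviation over its atoms and all frames.
#'
#' @param traj an [IonTrajectory-class]; only protein particles are used.
#' @param frames frame selection; default all frames.
#' @param residueMap optional integer vector mapping each protein particle
#'   to a residue number; defaults to one residue per particle.
#' @return data.frame with columns `residue_number`, `rmsf` (Angstrom).
#' @export
rmsfProfile <- function(traj, frames = NULL, residueMap = NULL) {
  stopifnot(is(traj, "IonTrajectory"))
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  if (length(frames) < 2L)
    stop("degenerate input: RMSF needs at least 2 frames", call. = FALSE)
  prot <- .isProtein(traj@topology$species)
  if (!any(prot)) stop("input error: no protein particles", call. = FALSE)
  na <- sum(prot)
  if (is.null(residueMap)) residueMap <- seq_len(na)
  stopifnot(length(residueMap) == na)

  X <- lapply(frames, function(f) {
    m <- traj@coords[prot, , f, drop = FALSE]; dim(m) <- c(na, 3L); m
  })
  ## center each frame, build mean, fit, refine mean once
  X <- lapply(X, function(m) sweep(m, 2, colMeans(m)))
  ref <- Reduce(`+`, X) / length(X)
  for (iter in 1:2) {
    X <- lapply(X, function(m) m %*% .kabsch(ref, m))
    ref <- Reduce(`+`, X) / length(X)
  }
  sq <- Reduce(`+`, lapply(X, function(m) rowSums((m - ref)^2))) / length(X)
  rmsf <- vapply(split(sq, residueMap), function(v) sqrt(mean(v)), 0)
  data.frame(residue_number = as.integer(names(rmsf)), rmsf = unname(rmsf))
}
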