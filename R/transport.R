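## Ionic currents by the charge-displacement method, z-resolved densities,
## Gaussian open-current statistics, selectivity.

#' Total and per-species ionic current from a biased trajectory
#'
#' Implements the charge-displacement estimator: for every consecutive
#' frame pair, the instantaneous current is
#' `I = (e / (dt * L_z)) * sum_i q_i dz_i`
#' over the ions in the analysis region, with displacements unwrapped by
#' minimum image in z (a particle must not drift more than L_z/2 between
#' stored frames).  Per-species sums give I_K and I_Cl; the total is their
#' sum, exactly.  The mean current is block-averaged (5 equal blocks by
#' default) and the uncertainty is the standard deviation over block means.
#'
#' @param traj an [IonTrajectory-class] with voltage and box metadata.
#' @param species species included (default K and Cl).
#' @param nBlocks number of equal blocks for the uncertainty.
#' @param zWindow optional c(zmin, zmax) restricting to ions whose midpoint
#'   z lies in the window; default: full periodic box.
#' @return a [CurrentEstimate-class] (currents in pA).
#' @export
computeSpeciesCurrents <- function(traj, species = c("K", "CL"),
                                   nBlocks = 5L, zWindow = NULL) {
  stopifnot(is(traj, "IonTrajectory"))
  nf <- nFrames(traj)
  if (nf < 2L) stop("input error: need at least 2 frames", call. = FALSE)
  Lz <- traj@box[3]
  if (!is.finite(Lz) || Lz <= 0)
    stop("metadata error: missing box L_z", call. = FALSE)
  dts <- diff(traj@times)
  if (any(dts <= 0)) stop("input error: zero or negative dt", call. = FALSE)

  top <- traj@topology
  perSpecies <- setNames(numeric(length(species)), species)
  instTotal <- numeric(nf - 1L)
  for (sp in species) {
    sel <- top$species == sp
    if (!any(sel)) next
    z <- traj@coords[sel, 3, , drop = FALSE]
    dim(z) <- c(sum(sel), nf)
    dz <- z[, -1, drop = FALSE] - z[, -nf, drop = FALSE]
    ## minimum-image unwrap in z
    dz <- dz - Lz * round(dz / Lz)
    q <- top$charge[sel]
    if (!is.null(zWindow)) {
      zm <- (z[, -1, drop = FALSE] + z[, -nf, drop = FALSE]) / 2
      dz[zm < zWindow[1] | zm > zWindow[2]] <- 0
    }
    inst <- colSums(dz * q) / (dts * Lz) * .PA_PER_E_PS
    perSpecies[sp] <- mean(inst)
    instTotal <- instTotal + inst
  }
  nB <- max(1L, min(nBlocks, nf - 1L))
  blk <- split(instTotal, cut(seq_along(instTotal), nB, labels = FALSE))
  blockMeans <- vapply(blk, mean, 0)
  IK <- if ("K" %in% species) perSpecies[["K"]] else 0
  ICl <- if ("CL" %in% species) perSpecies[["CL"]] else 0
  new("CurrentEstimate", ITotal = IK + ICl, IK = IK, ICl = ICl,
      sdBlocks = if (nB > 1) sd(blockMeans) else 0,
      voltage = traj@voltage, nFrames = as.integer(nf),
      blockMeans = unname(blockMeans))
}

#' z-resolved particle density of a species inside the pore cavity
#'
#' Per layer of the radius profile, counts the particles of the species
#' whose radial distance from the pore axis is at most the local cavity
#' radius, and divides by the cylindrical layer volume
#' `pi r(z)^2 dz`.  Frames are sampled at `step` ps (default 100 ps) and
#' the profile reports mean and standard deviation across sampled frames.
#'
#' @param traj an [IonTrajectory-class].
#' @param species species to count ("CL", "K", "WAT", ...).
#' @param radiusProfile a [RadiusProfile-class] defining the cavity.
#' @param step sampling step in ps.
#' @return a [DensityProfile-class] (particles per cubic Angstrom).
#' @export
densityProfile <- function(traj, species, radiusProfile, step = 100) {
  stopifnot(is(traj, "IonTrajectory"), is(radiusProfile, "RadiusProfile"))
  stride <- max(1L, round(step / traj@dt))
  frames <- seq(1L, nFrames(traj), by = stride)
  lay <- radiusProfile@layers
  dz <- radiusProfile@layerThickness
  sel <- traj@topology$species == species
  hasProt <- any(.isProtein(traj@topology$species))
  counts <- matrix(0, nrow(lay), length(frames))
  for (j in seq_along(frames)) {
    f <- frames[j]
    if (hasProt) {
      axis <- computePoreAxis(traj, f)
      cx <- axis$center[1]; cy <- axis$center[2]; z0 <- axis$zBottom
    } else { cx <- 0; cy <- 0; z0 <- 0 }
    if (!any(sel)) next
    xs <- traj@coords[sel, 1, f] - cx
    ys <- traj@coords[sel, 2, f] - cy
    zs <- traj@coords[sel, 3, f] - z0
    li <- floor((zs - (lay$z_center[1] - dz / 2)) / dz) + 1L
    ok <- li >= 1L & li <= nrow(lay)
    rho2 <- xs^2 + ys^2
    inCav <- ok & rho2 <= lay$radius_mean[pmax(li, 1L)]^2
    if (any(inCav))
      counts[, j] <- tabulate(li[inCav], nbins = nrow(lay))
  }
  vol <- pi * lay$radius_mean^2 * dz
  dens <- counts / vol
  zeroVol <- !is.finite(vol) | vol <= 0
  dens[zeroVol, ] <- NA_real_
  new("DensityProfile",
      layers = data.frame(
        z_center = lay$z_center,
        density_mean = rowMeans(dens),
        density_sd = if (length(frames) > 1) apply(dens, 1, sd)
                     else rep(0, nrow(lay))),
      species = species, voltage = traj@voltage, resolution = dz)
}

#' Fit a Gaussian to a current-sample histogram
#'
#' Least-squares Gaussian (`A exp(-(x-mu)^2 / 2 sigma^2)`) on the binned
#' histogram, with the maximum-likelihood sample mean/sd always reported as
#' fallback.  Fit quality is the reduced Pearson chi-square of the binned
#' fit; values above `poorFitThreshold` raise the `poor_fit` flag (e.g. for
#' bimodal input).
#'
#' @param samples numeric vector of currents (pA), length >= 100 for a
#'   meaningful histogram (shorter input falls back to MLE only).
#' @param nBins number of histogram bins.
#' @param poorFitThreshold reduced chi-square above which the fit is
#'   flagged poor.
#' @return list: `mean`, `sd` (the histogram-fit values when available,
#'   else MLE), `mle_mean`, `mle_sd`, `chi2_red`, `poor_fit`, `degenerate`.
#' @export
fitCurrentHistogram <- function(samples, nBins = 100L,
                                poorFitThreshold = 5) {
  m <- mean(samples); s <- sd(samples)
  if (!is.finite(s) || s == 0)
    return(list(mean = m, sd = 0, mle_mean = m, mle_sd = 0,
                chi2_red = NA_real_, poor_fit = FALSE, degenerate = TRUE))
  h <- graphics::hist(samples, breaks = nBins, plot = FALSE)
  x <- h$mids; y <- h$counts
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sg^2)),
                      start = list(A = max(y), mu = m, sg = s),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = m, sd = s, mle_mean = m, mle_sd = s,
                chi2_red = NA_real_, poor_fit = TRUE, degenerate = FALSE))
  cf <- coef(fit)
  pred <- cf[["A"]] * exp(-(x - cf[["mu"]])^2 / (2 * cf[["sg"]]^2))
  use <- pred > 1  # Pearson chi-square needs non-trivial expected counts
  chi2 <- sum((y[use] - pred[use])^2 / pred[use])
  dof <- max(1L, sum(use) - 3L)
  chi2red <- chi2 / dof
  list(mean = cf[["mu"]], sd = abs(cf[["sg"]]), mle_mean = m, mle_sd = s,
       chi2_red = chi2red, poor_fit = chi2red > poorFitThreshold,
       degenerate = FALSE)
}

#' Anion selectivity ratio of a current estimate
#'
#' `|I_Cl| / (|I_Cl| + |I_K|)`: 1 for a purely anion-carried current,
#' 0.5 for no selectivity.
#'
#' @param est a [CurrentEstimate-class].
#' @return dimensionless ratio in `[0, 1]`.
#' @export
selectivityRatio <- function(est) {
  stopifnot(is(est, "CurrentEstimate"))
  denom <- abs(est@ICl) + abs(est@IK)
  if (denom == 0)
    stop("undefined-ratio error: zero total current", call. = FALSE)
  abs(est@ICl) / denom
}
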