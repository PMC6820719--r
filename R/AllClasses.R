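## S4 containers for the pipeline.  Each class has a constructor of the same
## name that normalises inputs and a validity method that rejects (never
## repairs) violations of the documented invariants.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PoreStructure: a (pseudo-)atomic channel structure
#'
#' Atom records of a pore structure, either parsed from a PDB subset or
#' generated as pseudo-atoms, together with the periodic box and optional
#' membrane bounds.  Coordinates are in Angstrom; atom numbering is 1-based.
#' z-coordinates are stored untransformed; the pore-bottom (z = 0) convention
#' is applied by the geometry operations, not by readers.
#'
#' @slot atoms data.frame with columns `atom_id`, `residue_name`,
#'   `residue_number`, `chain_id`, `species`, `x`, `y`, `z`, `radius`
#'   (radius may be NA).
#' @slot box numeric(3), box lengths (Lx, Ly, Lz) in Angstrom.
#' @slot membraneBounds numeric(2) `(z_lo, z_hi)` or NULL.
#' @export
setClass("PoreStructure",
  representation(atoms = "data.frame", box = "numeric",
                 membraneBounds = "numericOrNULL"))

setValidity("PoreStructure", function(object) {
  a <- object@atoms
  need <- c("atom_id", "residue_name", "residue_number", "chain_id",
            "species", "x", "y", "z", "radius")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$atom_id)) return("atom_id values must be unique")
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
    return("atom coordinates must be finite")
  if (length(object@box) != 3L || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    return("box must be three positive finite lengths")
  mb <- object@membraneBounds
  if (!is.null(mb)) {
    if (length(mb) != 2L || mb[1] >= mb[2])
      return("membraneBounds must satisfy z_lo < z_hi")
    if (mb[1] < 0 || mb[2] > object@box[3])
      return("membraneBounds must lie within [0, Lz]")
  }
  TRUE
})

#' @rdname PoreStructure-class
#' @param atoms,box,membraneBounds see slots.
#' @return a `PoreStructure` object.
#' @export
PoreStructure <- function(atoms, box, membraneBounds = NULL) {
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("PoreStructure", atoms = atoms, box = as.numeric(box),
      membraneBounds = if (is.null(membraneBounds)) NULL
                       else as.numeric(membraneBounds))
}

#' IonTrajectory: time-ordered particle coordinates with bias metadata
#'
#' Fixed-topology trajectory of ions, water and protein pseudo-atoms.
#' Coordinates are wrapped into the periodic box; displacement-based
#' estimators unwrap by minimum image in z.
#'
#' @slot topology data.frame with columns `particle_id`, `species`
#'   (one of WAT, K, CL, PROT, OTHER), `charge` (elementary charges).
#' @slot coords numeric array `[n_particles, 3, n_frames]` in Angstrom.
#' @slot frameIndex integer vector, strictly increasing.
#' @slot times numeric vector of frame times in ps.
#' @slot box numeric(3) `(Lx, Ly, Lz)` in Angstrom.
#' @slot voltage applied bias in mV (signed).
#' @slot dt time between stored frames in ps.
#' @export
setClass("IonTrajectory",
  representation(topology = "data.frame", coords = "array",
                 frameIndex = "integer", times = "numeric",
                 box = "numeric", voltage = "numeric", dt = "numeric"))

setValidity("IonTrajectory", function(object) {
  top <- object@topology
  if (!all(c("particle_id", "species", "charge") %in% names(top)))
    return("topology needs particle_id, species, charge")
  if (anyDuplicated(top$particle_id)) return("particle_id must be unique")
  ok <- top$species %in% c("WAT", "K", "CL", "PROT", "OTHER")
  if (!all(ok)) return("species must be one of WAT, K, CL, PROT, OTHER")
  for (sp in names(.SPECIES_CHARGE)) {
    bad <- top$species == sp & top$charge != .SPECIES_CHARGE[[sp]]
    if (any(bad))
      return(sprintf("species %s must carry charge %+d e", sp,
                     .SPECIES_CHARGE[[sp]]))
  }
  d <- dim(object@coords)
  if (length(d) != 3L || d[1] != nrow(top) || d[2] != 3L)
    return("coords must be [n_particles, 3, n_frames]")
  nf <- d[3]
  if (length(object@frameIndex) != nf || length(object@times) != nf)
    return("frameIndex/times must match the number of frames")
  if (nf > 1L && any(diff(object@frameIndex) <= 0L))
    return("frame_index must be strictly increasing")
  if (length(object@box) != 3L || any(object@box <= 0))
    return("box must be three positive lengths")
  if (length(object@voltage) != 1L || length(object@dt) != 1L ||
      object@dt <= 0)
    return("voltage must be scalar and dt a positive scalar")
  TRUE
})

#' @rdname IonTrajectory-class
#' @param topology,coords,times,box,voltage,dt see slots.
#' @param frameIndex integer frame indices; defaults to `seq_len(n_frames)`.
#' @return an `IonTrajectory` object.
#' @export
IonTrajectory <- function(topology, coords, times, box, voltage, dt,
                          frameIndex = NULL) {
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  rownames(topology) <- NULL
  if (is.null(frameIndex)) frameIndex <- seq_len(dim(coords)[3])
  new("IonTrajectory", topology = topology, coords = coords,
      frameIndex = as.integer(frameIndex), times = as.numeric(times),
      box = as.numeric(box), voltage = as.numeric(voltage),
      dt = as.numeric(dt))
}

#' CurrentTrace: a uniformly sampled single-channel current recording
#'
#' @slot current numeric vector of samples in pA; sample k is at time
#'   `(k-1)/samplingRate` seconds.
#' @slot samplingRate sampling rate in Hz.
#' @slot voltage applied bias in mV (signed).
#' @slot filterCutoff low-pass cutoff in Hz (NA if unknown).
#' @slot label free-text label.
#' @export
setClass("CurrentTrace",
  representation(current = "numeric", samplingRate = "numeric",
                 voltage = "numeric", filterCutoff = "numeric",
                 label = "character"))

setValidity("CurrentTrace", function(object) {
  if (length(object@current) < 1L) return("trace must contain samples")
  if (!all(is.finite(object@current))) return("currents must be finite")
  if (object@samplingRate <= 0) return("sampling rate must be positive")
  TRUE
})

#' @rdname CurrentTrace-class
#' @param current,samplingRate,voltage,filterCutoff,label see slots.
#' @return a `CurrentTrace` object.
#' @export
CurrentTrace <- function(current, samplingRate, voltage,
                         filterCutoff = NA_real_, label = "") {
  new("CurrentTrace", current = as.numeric(current),
      samplingRate = as.numeric(samplingRate), voltage = as.numeric(voltage),
      filterCutoff = as.numeric(filterCutoff), label = label)
}

#' RadiusProfile: per-layer local pore radius along the channel axis
#'
#' Produced by [sliceRadiusProfile()].  z is measured from the pore bottom
#' (lowest protein atom) upward along +z.
#'
#' @slot layers data.frame with columns `z_center`, `radius_mean`,
#'   `radius_sd`, `n_frames`.
#' @slot layerThickness slice thickness in Angstrom.
#' @slot zReference character, the z origin convention.
#' @slot landmarks named numeric, z positions (Angstrom) of named regions.
#' @slot flags list of per-layer diagnostic flags.
#' @export
setClass("RadiusProfile",
  representation(layers = "data.frame", layerThickness = "numeric",
                 zReference = "character", landmarks = "numeric",
                 flags = "list"))

setValidity("RadiusProfile", function(object) {
  l <- object@layers
  need <- c("z_center", "radius_mean", "radius_sd", "n_frames")
  if (!all(need %in% names(l)))
    return(paste("layers must have columns:", paste(need, collapse = ", ")))
  if (any(l$radius_mean < 1)) return("radii are seeded at 1 Angstrom minimum")
  if (any(l$radius_sd < 0)) return("radius_sd must be non-negative")
  if (nrow(l) > 1L && any(diff(l$z_center) <= 0))
    return("layers must be sorted by z")
  TRUE
})

RadiusProfile <- function(layers, layerThickness,
                          zReference = "pore bottom = 0 A",
                          landmarks = .DEFAULT_LANDMARKS, flags = list()) {
  new("RadiusProfile", layers = as.data.frame(layers),
      layerThickness = layerThickness, zReference = zReference,
      landmarks = landmarks, flags = flags)
}

#' DensityProfile: z-resolved particle density of one species in the cavity
#'
#' @slot layers data.frame with `z_center`, `density_mean`, `density_sd`
#'   (particles per cubic Angstrom).
#' @slot species species counted.
#' @slot voltage bias (mV) of the source trajectory.
#' @slot resolution layer thickness in Angstrom.
#' @export
setClass("DensityProfile",
  representation(layers = "data.frame", species = "character",
                 voltage = "numeric", resolution = "numeric"))

setValidity("DensityProfile", function(object) {
  l <- object@layers
  if (!all(c("z_center", "density_mean", "density_sd") %in% names(l)))
    return("layers must have z_center, density_mean, density_sd")
  if (any(l$density_mean < 0, na.rm = TRUE)) return("density must be >= 0")
  TRUE
})

#' CurrentEstimate: charge-displacement current with per-species split
#'
#' Additivity `I_total = I_K + I_Cl` holds exactly (same frames, same
#' formula).  The uncertainty is the standard deviation over block averages.
#'
#' @slot ITotal,IK,ICl currents in pA.
#' @slot sdBlocks sd over block means of the total current, pA.
#' @slot voltage bias in mV.
#' @slot nFrames number of frames used.
#' @slot blockMeans per-block mean total currents, pA.
#' @export
setClass("CurrentEstimate",
  representation(ITotal = "numeric", IK = "numeric", ICl = "numeric",
                 sdBlocks = "numeric", voltage = "numeric",
                 nFrames = "integer", blockMeans = "numeric"))

setValidity("CurrentEstimate", function(object) {
  if (abs(object@ITotal - (object@IK + object@ICl)) >
      1e-9 * max(1, abs(object@ITotal)))
    return("I_total must equal I_K + I_Cl")
  if (object@sdBlocks < 0) return("sd must be non-negative")
  TRUE
})

#' EventTable: blockade events extracted from a current trace
#'
#' @slot events data.frame with columns `start`, `end`, `dwell` (s),
#'   `mean_blockade_pA`, `ires_over_i0`, `merged` (logical; ground-truth
#'   tables flag merged overlaps).
#' @slot I0 open-pore current in pA (signed).
#' @slot baselineSd baseline noise sd in pA.
#' @slot voltage bias in mV.
#' @slot duration trace duration in s.
#' @slot params detection / generation parameter snapshot.
#' @export
setClass("EventTable",
  representation(events = "data.frame", I0 = "numeric",
                 baselineSd = "numeric", voltage = "numeric",
                 duration = "numeric", params = "list"))

setValidity("EventTable", function(object) {
  e <- object@events
  need <- c("start", "end", "dwell")
  if (!all(need %in% names(e)))
    return("events must have start, end, dwell")
  if (nrow(e)) {
    if (any(e$dwell <= 0)) return("dwell = end - start must be positive")
    if (any(abs(e$end - e$start - e$dwell) > 1e-12 * pmax(1, e$end)))
      return("dwell must equal end - start")
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)] - 1e-12))
      return("events must be non-overlapping and time-ordered")
  }
  TRUE
})

EventTable <- function(events, I0 = NA_real_, baselineSd = NA_real_,
                       voltage = NA_real_, duration = NA_real_,
                       params = list()) {
  events <- as.data.frame(events)
  if (!nrow(events)) {
    events <- data.frame(start = numeric(), end = numeric(),
                         dwell = numeric(), mean_blockade_pA = numeric(),
                         ires_over_i0 = numeric(), merged = logical())
  }
  if (is.null(events$mean_blockade_pA)) events$mean_blockade_pA <- NA_real_
  if (is.null(events$ires_over_i0)) events$ires_over_i0 <- NA_real_
  if (is.null(events$merged)) events$merged <- FALSE
  rownames(events) <- NULL
  new("EventTable", events = events, I0 = I0, baselineSd = baselineSd,
      voltage = voltage, duration = duration, params = params)
}

#' DwellFit: exponential dwell-time fit
#'
#' @slot tau fitted time constant in seconds.
#' @slot ci numeric(2) confidence interval for tau.
#' @slot method "mle" or "histogram".
#' @slot nEvents number of events fitted.
#' @slot details list: uncorrected mean, histogram fit details, etc.
#' @export
setClass("DwellFit",
  representation(tau = "numeric", ci = "numeric", method = "character",
                 nEvents = "integer", details = "list"))

setValidity("DwellFit", function(object) {
  if (object@tau <= 0) return("tau must be positive")
  if (length(object@ci) == 2L && !any(is.na(object@ci)) &&
      (object@tau < object@ci[1] || object@tau > object@ci[2]))
    return("ci must contain tau")
  TRUE
})

#' CaptureRate: inter-event interval statistics
#'
#' `f * tauOn == 1` by construction.
#'
#' @slot tauOn mean inter-event interval in seconds.
#' @slot f capture frequency in Hz.
#' @slot ci numeric(2) confidence interval for tauOn.
#' @slot nIntervals number of inter-event intervals used.
#' @export
setClass("CaptureRate",
  representation(tauOn = "numeric", f = "numeric", ci = "numeric",
                 nIntervals = "integer"))

setValidity("CaptureRate", function(object) {
  if (object@tauOn <= 0) return("tauOn must be positive")
  if (abs(object@f * object@tauOn - 1) > 1e-12)
    return("f * tauOn must equal 1")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "PoreStructure", function(object) {
  cat(sprintf("PoreStructure: %d atoms, box %.1f x %.1f x %.1f A\n",
              nrow(object@atoms), object@box[1], object@box[2],
              object@box[3]))
  tab <- table(object@atoms$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
})

setMethod("show", "IonTrajectory", function(object) {
  cat(sprintf(
    "IonTrajectory: %d frames x %d particles, dt %.3g ps, %+g mV\n",
    nFrames(object), nParticles(object), object@dt, object@voltage))
  tab <- table(object@topology$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf(
    "CurrentTrace '%s': %d samples @ %g Hz (%.3g s), %+g mV\n",
    object@label, length(object@current), object@samplingRate,
    length(object@current) / object@samplingRate, object@voltage))
})

setMethod("show", "RadiusProfile", function(object) {
  l <- object@layers
  cat(sprintf(
    "RadiusProfile: %d layers of %.2g A (%s), radius %.1f-%.1f A\n",
    nrow(l), object@layerThickness, object@zReference,
    min(l$radius_mean), max(l$radius_mean)))
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf("DensityProfile[%s]: %d layers @ %.2g A, %+g mV\n",
              object@species, nrow(object@layers), object@resolution,
              object@voltage))
})

setMethod("show", "CurrentEstimate", function(object) {
  cat(sprintf(
    "CurrentEstimate @ %+g mV: I_total = %.4g +/- %.2g pA (I_K = %.4g, I_Cl = %.4g; %d frames)\n",
    object@voltage, object@ITotal, object@sdBlocks, object@IK, object@ICl,
    object@nFrames))
})

setMethod("show", "EventTable", function(object) {
  cat(sprintf(
    "EventTable: %d events, I0 = %.4g pA, voltage %+g mV, duration %.3g s\n",
    nrow(object@events), object@I0, object@voltage, object@duration))
})

setMethod("show", "DwellFit", function(object) {
  cat(sprintf("DwellFit (%s): tau = %.4g s [%.4g, %.4g], n = %d\n",
              object@method, object@tau, object@ci[1], object@ci[2],
              object@nEvents))
})

setMethod("show", "CaptureRate", function(object) {
  cat(sprintf("CaptureRate: tau_on = %.4g s, f = %.4g Hz (n = %d)\n",
              object@tauOn, object@f, object@nIntervals))
})
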