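## Accessor generics.  Slot access outside the package goes through these.

#' Number of frames in a trajectory
#' @param x an object with frames.
#' @return integer count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of particles / atoms
#' @param x an object with particles.
#' @return integer count.
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' Per-layer table of a profile object
#' @param x a `RadiusProfile` or `DensityProfile`.
#' @return data.frame of layers.
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' Event table of an `EventTable`
#' @param x an `EventTable`.
#' @return data.frame of events.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Applied bias in mV
#' @param x an object carrying voltage metadata.
#' @return numeric, mV (signed).
#' @export
setGeneric("voltage", function(x) standardGeneric("voltage"))

#' Current samples of a trace (pA)
#' @param x a `CurrentTrace`.
#' @return numeric vector.
#' @export
setGeneric("currentValues", function(x) standardGeneric("currentValues"))

#' Sampling rate (Hz)
#' @param x a `CurrentTrace`.
#' @return numeric, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Open-pore current I0 (pA)
#' @param x an `EventTable`.
#' @return numeric, pA (signed as recorded).
#' @export
setGeneric("openPoreCurrent", function(x) standardGeneric("openPoreCurrent"))

#' Fitted exponential time constant tau (s)
#' @param x a `DwellFit`.
#' @return numeric, seconds.
#' @export
setGeneric("tauHat", function(x) standardGeneric("tauHat"))

#' Capture frequency f = 1/tau_on (Hz)
#' @param x a `CaptureRate`.
#' @return numeric, Hz.
#' @export
setGeneric("captureFrequency",
           function(x) standardGeneric("captureFrequency"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "IonTrajectory", function(x) dim(x@coords)[3])

#' @rdname nParticles
#' @export
setMethod("nParticles", "IonTrajectory", function(x) nrow(x@topology))

#' @rdname nParticles
#' @export
setMethod("nParticles", "PoreStructure", function(x) nrow(x@atoms))

#' @rdname layers
#' @export
setMethod("layers", "RadiusProfile", function(x) x@layers)

#' @rdname layers
#' @export
setMethod("layers", "DensityProfile", function(x) x@layers)

#' @rdname events
#' @export
setMethod("events", "EventTable", function(x) x@events)

#' @rdname voltage
#' @export
setMethod("voltage", "IonTrajectory", function(x) x@voltage)

#' @rdname voltage
#' @export
setMethod("voltage", "CurrentTrace", function(x) x@voltage)

#' @rdname voltage
#' @export
setMethod("voltage", "EventTable", function(x) x@voltage)

#' @rdname voltage
#' @export
setMethod("voltage", "CurrentEstimate", function(x) x@voltage)

#' @rdname currentValues
#' @export
setMethod("currentValues", "CurrentTrace", function(x) x@current)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "CurrentTrace", function(x) x@samplingRate)

#' @rdname openPoreCurrent
#' @export
setMethod("openPoreCurrent", "EventTable", function(x) x@I0)

#' @rdname tauHat
#' @export
setMethod("tauHat", "DwellFit", function(x) x@tau)

#' @rdname captureFrequency
#' @export
setMethod("captureFrequency", "CaptureRate", function(x) x@f)

#' Total and per-species currents of a `CurrentEstimate`
#'
#' @param x a `CurrentEstimate`.
#' @return named numeric: `I_total`, `I_K`, `I_Cl`, `sd` (all pA).
#' @export
currents <- function(x) {
  stopifnot(is(x, "CurrentEstimate"))
  c(I_total = x@ITotal, I_K = x@IK, I_Cl = x@ICl, sd = x@sdBlocks)
}
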