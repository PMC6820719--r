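## Blockade-event detection and event statistics: dwell-time exponential
## fits, capture rate f = 1/tau_on, translocation-vs-bumping classification.

#' Detect blockade events in a current trace
#'
#' The open-pore level I0 and the baseline noise sd are estimated from a
#' Gaussian fit of the dominant mode of the sample histogram
#' ([fitCurrentHistogram()] on the baseline-side samples).  An event opens
#' when the current magnitude drops below `|I0| - kSigma * sd` and closes
#' on re-crossing; events shorter than `minDwell` are discarded.  Traces at
#' negative voltage are rectified by sign before thresholding, so one code
#' path serves both polarities.
#'
#' @param trace a [CurrentTrace-class].
#' @param kSigma threshold multiplier (default 4).
#' @param minDwell minimum dwell in seconds (default 5e-5 s, i.e. 5 samples
#'   at 100 kHz).
#' @param i0 optional known open-pore current (pA, signed); when given, the
#'   baseline fit is skipped and only the noise sd is estimated.
#' @return an [EventTable-class]; each event carries dwell, mean blockade
#'   current and `I_res/I0`.
#' @export
detectEvents <- function(trace, kSigma = 4, minDwell = 5e-5, i0 = NULL) {
  stopifnot(is(trace, "CurrentTrace"))
  if (kSigma <= 0) stop("parameter error: kSigma must be > 0", call. = FALSE)
  fs <- trace@samplingRate
  x <- trace@current
  ## rectify polarity so one code path serves positive and negative biases
  sgn <- if (!is.null(i0)) sign(i0) else sign(median(x))
  if (sgn == 0) sgn <- 1
  y <- sgn * x

  ## baseline: robust init, then Gaussian fit of the dominant (upper) mode
  med <- median(y); s0 <- mad(y)
  if (!is.finite(s0) || s0 == 0)
    stop("baseline error: degenerate trace", call. = FALSE)
  base <- y[y > med - 3 * s0]
  if (length(base) < 100 || length(base) < 0.3 * length(y))
    stop("baseline error: no dominant baseline mode", call. = FALSE)
  gfit <- fitCurrentHistogram(base)
  I0mag <- if (is.null(i0)) gfit$mean else abs(i0)
  sdB <- gfit$sd
  if (!is.finite(sdB) || sdB <= 0) sdB <- s0

  thr <- I0mag - kSigma * sdB
  below <- y < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  evSel <- r$values & (r$lengths / fs >= minDwell)
  i0idx <- starts[evSel]; i1idx <- ends[evSel]
  if (length(i0idx)) {
    cs <- cumsum(y)
    sums <- cs[i1idx] - ifelse(i0idx > 1L, cs[i0idx - 1L], 0)
    meanMag <- sums / (i1idx - i0idx + 1L)
    ev <- data.frame(
      start = (i0idx - 1L) / fs,
      end = i1idx / fs,
      dwell = (i1idx - i0idx + 1L) / fs,
      mean_blockade_pA = sgn * meanMag,
      ires_over_i0 = meanMag / I0mag,
      merged = FALSE)
  } else ev <- data.frame()
  EventTable(ev, I0 = sgn * I0mag, baselineSd = sdB,
             voltage = trace@voltage,
             duration = length(y) / fs,
             params = list(k_sigma = kSigma, min_dwell = minDwell,
                           i0_supplied = !is.null(i0)))
}

.dwellsOf <- function(events) {
  if (is(events, "EventTable")) events@events$dwell
  else as.numeric(events)
}

#' Fit a falling exponential to dwell times
#'
#' MLE (default): tau is the sample mean of the dwells after subtracting
#' the detection dead time `minDwell` (the exponential is memoryless, so
#' left-truncation at `minDwell` shifts the mean by exactly `minDwell`);
#' CI by seeded bootstrap (percentile, 1000 resamples).  Histogram method:
#' least-squares fit of `A exp(-t/tau)` to the binned dwell distribution,
#' matching the falling-exponential presentation of recorded dwell
#' histograms; CI from the nls parameter standard error.
#'
#' @param events an [EventTable-class] or numeric vector of dwells (s).
#' @param method "mle" or "histogram".
#' @param minDwell dead time subtracted before averaging; defaults to the
#'   detection `min_dwell` recorded in the event table (0 otherwise).
#' @param nBoot bootstrap resamples for the MLE CI.
#' @param nBins histogram bins for the histogram method.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return a [DwellFit-class].  `details` carries the uncorrected mean and,
#'   for the histogram method, the fitted amplitude.
#' @export
fitDwellExponential <- function(events, method = c("mle", "histogram"),
                                minDwell = NULL, nBoot = 1000L,
                                nBins = 50L, seed = 1L, conf = 0.95) {
  method <- match.arg(method)
  d <- .dwellsOf(events)
  if (is.null(minDwell)) {
    minDwell <- if (is(events, "EventTable") &&
                    !is.null(events@params$min_dwell))
      events@params$min_dwell else 0
  }
  n <- length(d)
  if (method == "mle" && n < 2L)
    stop("need at least 2 events for the MLE fit", call. = FALSE)
  if (method == "histogram" && n < 30L)
    stop("need at least 30 events for the histogram fit", call. = FALSE)
  corr <- d - minDwell
  if (all(corr <= .Machine$double.eps))
    stop("degenerate: all dwells equal the dead time", call. = FALSE)
  a <- (1 - conf) / 2
  if (method == "mle") {
    tau <- mean(corr)
    ci <- withSeed(seed, {
      bm <- matrix(sample(corr, n * nBoot, replace = TRUE), nrow = nBoot)
      quantile(rowMeans(bm), c(a, 1 - a), names = FALSE)
    })
    ci <- range(ci, tau)  # percentile CI always brackets the point estimate
    details <- list(tau_uncorrected = mean(d), min_dwell = minDwell)
  } else {
    h <- graphics::hist(d, breaks = nBins, plot = FALSE)
    x <- h$mids; y <- h$counts
    start <- list(A = max(y), tau = max(mean(corr), .Machine$double.eps))
    fit <- minpack.lm::nlsLM(y ~ A * exp(-x / tau), start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    tau <- cf[["tau"]]
    se <- tryCatch(sqrt(vcov(fit)["tau", "tau"]), error = function(e) NA)
    ci <- if (is.na(se)) c(NA_real_, NA_real_)
          else tau + c(-1, 1) * qnorm(1 - a) * se
    details <- list(tau_uncorrected = mean(d), min_dwell = minDwell,
                    amplitude = cf[["A"]], se = se)
  }
  new("DwellFit", tau = tau, ci = as.numeric(ci), method = method,
      nEvents = as.integer(n), details = details)
}

#' Capture rate from inter-event intervals
#'
#' Inter-event intervals `start[i+1] - end[i]` are fitted as an exponential
#' (the MLE is the sample mean), giving tau_on; the capture frequency is
#' `f = 1/tau_on` exactly.  The CI is the exact chi-square interval for an
#' exponential mean.
#'
#' @param events an [EventTable-class] with at least 2 events.
#' @param conf confidence level.
#' @return a [CaptureRate-class].
#' @export
captureRate <- function(events, conf = 0.95) {
  stopifnot(is(events, "EventTable"))
  e <- events@events
  if (nrow(e) < 2L)
    stop("insufficient-data error: need at least 2 events", call. = FALSE)
  iv <- e$start[-1] - e$end[-nrow(e)]
  iv <- iv[iv > 0]
  if (length(iv) < 1L)
    stop("insufficient-data error: no positive inter-event intervals",
         call. = FALSE)
  tauOn <- mean(iv)
  n <- length(iv)
  a <- (1 - conf) / 2
  ci <- c(2 * n * tauOn / qchisq(1 - a, 2 * n),
          2 * n * tauOn / qchisq(a, 2 * n))
  new("CaptureRate", tauOn = tauOn, f = 1 / tauOn, ci = ci,
      nIntervals = as.integer(n))
}

#' Classify translocation vs bumping from voltage dependence of dwell time
#'
#' Regresses `ln(tau)` on `|V|`.  A significantly negative slope (95\% CI
#' excluding 0) indicates translocation (dwell decreases exponentially at
#' higher driving voltage); a CI containing 0 together with a relative tau
#' spread below 25\% indicates no translocation (bumping: dwell unvaried
#' across voltages); anything else is indeterminate.
#'
#' @param series either a data.frame with columns `voltage` and `tau`, or a
#'   list of `list(voltage =, fit = DwellFit)` / `list(voltage =, events =)`
#'   elements as produced by [genVoltageSeries()] (event tables are fitted
#'   by MLE on the fly).
#' @param conf confidence level of the slope test.
#' @param spreadTolerance relative tau spread below which a flat series is
#'   called non-translocating.
#' @return character: "translocation", "no_translocation" or
#'   "indeterminate", with attributes `slope` and `slope_ci`.
#' @export
classifyTranslocation <- function(series, conf = 0.95,
                                  spreadTolerance = 0.25) {
  if (is.data.frame(series)) {
    v <- series$voltage; tau <- series$tau
  } else {
    v <- vapply(series, function(s) s$voltage, 0)
    tau <- vapply(series, function(s) {
      if (!is.null(s$fit)) tauHat(s$fit)
      else tauHat(fitDwellExponential(s$events, method = "mle", nBoot = 50L))
    }, 0)
  }
  if (length(v) < 3L)
    stop("input error: need at least 3 voltages", call. = FALSE)
  if (diff(range(abs(v))) < 40)
    stop("input error: voltages must span at least 40 mV", call. = FALSE)
  fit <- lm(log(tau) ~ absV, data = data.frame(absV = abs(v), tau = tau))
  ci <- confint(fit, "absV", level = conf)
  spread <- sd(tau) / mean(tau)
  label <- if (ci[2] < 0) "translocation"
           else if (ci[1] <= 0 && ci[2] >= 0 && spread < spreadTolerance)
             "no_translocation"
           else "indeterminate"
  structure(label, slope = unname(coef(fit)["absV"]),
            slope_ci = as.numeric(ci))
}
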