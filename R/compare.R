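## Comparative quantities: percent change, fold change, per-base
## translocation time, diameter-dwell correlation, comparison tables.

#' Signed percent change of a mutant value relative to wild type
#'
#' `100 * (mutant - wt) / wt`, on signed values.  The narrative rendering
#' ("decreased by 21\%") is done by [renderChange()].
#'
#' @param mutant,wt numeric values in the same units; `wt` must be nonzero.
#' @return percent change (signed).
#' @export
percentChange <- function(mutant, wt) {
  if (any(wt == 0)) stop("undefined: wt must be nonzero", call. = FALSE)
  100 * (mutant - wt) / wt
}

#' Fold change mutant / wt
#'
#' @param mutant,wt numeric values; `wt` must be nonzero.
#' @return dimensionless ratio.
#' @export
foldChange <- function(mutant, wt) {
  if (any(wt == 0)) stop("undefined: wt must be nonzero", call. = FALSE)
  mutant / wt
}

#' Per-base translocation time
#'
#' @param dwell dwell time (ms).
#' @param nBases number of bases (>= 1).
#' @return ms per base.
#' @export
perBaseTime <- function(dwell, nBases) {
  if (any(nBases < 1)) stop("nBases must be >= 1", call. = FALSE)
  dwell / nBases
}

#' Render a percent change as narrative text
#'
#' Magnitudes are rounded half-away-from-zero to whole percent only in the
#' rendering; numeric columns keep full precision.
#'
#' @param pct signed percent change from [percentChange()].
#' @return character like "decreased by 21\%" / "increased by 10\%".
#' @export
renderChange <- function(pct) {
  word <- ifelse(pct < 0, "decreased", ifelse(pct > 0, "increased",
                                              "unchanged"))
  mag <- floor(abs(pct) + 0.5)  # half away from zero on the magnitude
  ifelse(pct == 0, "unchanged", sprintf("%s by %d%%", word, mag))
}

#' Correlation between pore diameter and dwell time
#'
#' Pearson correlation on the chosen transform plus Spearman rank
#' correlation, both with n.  Dwell times spanning decades against
#' diameters of a few Angstrom are usually better captured on log(dwell)
#' or by rank; Spearman is the headline statistic.
#'
#' @param pairs data.frame/matrix with columns diameter (Angstrom) and
#'   dwell (ms), at least 3 rows.
#' @param transform "log-dwell" (default) or "linear" for the Pearson
#'   coefficient.
#' @return list: `pearson_r`, `spearman_r`, `n`, `transform`,
#'   `constant_input` flag.
#' @export
diameterDwellCorrelation <- function(pairs,
                                     transform = c("log-dwell", "linear")) {
  transform <- match.arg(transform)
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("diameter", "dwell")
  pairs <- pairs[complete.cases(pairs[, 1:2]), ]
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  constant <- sd(pairs$diameter) == 0 || sd(pairs$dwell) == 0
  if (constant)
    return(list(pearson_r = NA_real_, spearman_r = NA_real_,
                n = nrow(pairs), transform = transform,
                constant_input = TRUE))
  y <- if (transform == "log-dwell") log(pairs$dwell) else pairs$dwell
  list(pearson_r = cor(pairs$diameter, y, method = "pearson"),
       spearman_r = cor(pairs$diameter, pairs$dwell, method = "spearman"),
       n = nrow(pairs), transform = transform, constant_input = FALSE)
}

#' Build a mutant-vs-wt comparison table
#'
#' Each row carries the signed percent change, the fold change, the
#' narrative rendering and the units.  The identity
#' `fold == 1 + percent/100` is asserted on every row.
#'
#' @param label character vector of row labels.
#' @param wt,mutant numeric vectors of values.
#' @param units character vector of units.
#' @return data.frame with class attribute preserved for
#'   [writeResultsTable()].
#' @export
compareTable <- function(label, wt, mutant, units = "") {
  pct <- percentChange(mutant, wt)
  fold <- foldChange(mutant, wt)
  stopifnot(all(abs(fold - (1 + pct / 100)) <=
                1e-9 * pmax(1, abs(fold))))
  data.frame(label = label, wt_value = wt, mutant_value = mutant,
             percent_change = pct, fold_change = fold,
             rendered = renderChange(pct), units = units,
             stringsAsFactors = FALSE)
}
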