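# REPA quantification: cleavage-protection fractions across a protein
# titration and an optional single-site occupancy summary fit.

#' Protected (uncleaved) fraction of a band pair
#'
#' `uncleaved / (uncleaved + cleaved)`. Lanes where both intensities are
#' zero are undefined and return `NA` with a warning.
#'
#' @param uncleaved,cleaved non-negative band intensities (vectorized).
#' @return fraction(s) in `[0, 1]`, `NA` where undefined.
#' @examples
#' protection_fraction(3, 1)  # 0.75
#' @export
protection_fraction <- function(uncleaved, cleaved) {
  if (any(uncleaved < 0, na.rm = TRUE) || any(cleaved < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  tot <- uncleaved + cleaved
  out <- ifelse(tot > 0, uncleaved / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE))
    warning("lane(s) with zero total intensity: fraction undefined")
  out
}

#' Cleavage-protection curve across a protein titration
#'
#' Computes per-lane protected fractions for the binding-site probe and the
#' control probe, and a normalized protection defined as the probe fraction
#' minus the control fraction, clipped to `[0, 1]`. Subtracting (rather than
#' dividing by) the control uses the control's cleaved fraction as a
#' per-lane estimate of enzyme activity: the control shares the reaction but
#' carries no binding site. Lanes are sorted by concentration; duplicate
#' concentrations are rejected.
#'
#' @param measurements data frame with columns `concentration_nM`,
#'   `probe_uncleaved`, `probe_cleaved`, `control_uncleaved`,
#'   `control_cleaved` (e.g. from [simulate_repa_bands()]).
#' @return object of class `protection_curve`: a data frame with columns
#'   `concentration_nM`, `probe_fraction`, `control_fraction`,
#'   `normalized_protection`.
#' @examples
#' protection_curve(simulate_repa_bands(100, c(62.5, 125, 250, 500, 1000)))
#' @export
protection_curve <- function(measurements) {
  need <- c("concentration_nM", "probe_uncleaved", "probe_cleaved",
            "control_uncleaved", "control_cleaved")
  stopifnot(is.data.frame(measurements), all(need %in% names(measurements)))
  if (anyDuplicated(measurements$concentration_nM))
    stop("duplicate concentrations")
  with_probe <- measurements$probe_uncleaved + measurements$probe_cleaved
  if (any(with_probe <= 0))
    stop("each lane needs at least one positive probe intensity")
  out <- data.frame(
    concentration_nM = measurements$concentration_nM,
    probe_fraction = protection_fraction(measurements$probe_uncleaved,
                                         measurements$probe_cleaved),
    control_fraction = protection_fraction(measurements$control_uncleaved,
                                           measurements$control_cleaved)
  )
  out$normalized_protection <- pmin(pmax(
    out$probe_fraction - out$control_fraction, 0), 1)
  out <- out[order(out$concentration_nM), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protection_curve", "data.frame")
  out
}

#' Summarize a protection curve with a single-site occupancy fit
#'
#' Fits `normalized_protection ~ a * C / (C + K)` by least squares and
#' returns the half-maximal concentration `K` (nM) and amplitude `a`. A
#' one-number summary of binding strength; it is an apparent affinity under
#' the assay's cleavage conditions, not a calibrated KD.
#'
#' @param curve a [protection_curve()] (>= 3 lanes with positive
#'   concentration recommended).
#' @return list with `k_half` (nM), `amplitude` and `sse`.
#' @export
fit_protection_kd <- function(curve) {
  stopifnot(inherits(curve, "protection_curve"))
  C <- curve$concentration_nM
  y <- curve$normalized_protection
  keep <- !is.na(y)
  C <- C[keep]; y <- y[keep]
  if (length(C) < 3L) stop("need at least 3 usable lanes")
  obj <- function(p) {
    k <- exp(p[1L]); a <- p[2L]
    sum((y - a * C / (C + k))^2)
  }
  best <- NULL
  for (k0 in exp(seq(log(max(min(C[C > 0], na.rm = TRUE), 1e-3)),
                     log(max(C) * 10), length.out = 7))) {
    o <- optim(c(log(k0), max(y)), obj)
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(k_half = exp(best$par[1L]), amplitude = best$par[2L],
       sse = best$value)
}
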