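#' Seven-point dose-response viability series
#'
#' @param concentrations strictly monotone positive concentrations (µM);
#'   screens typically use a seven-point 3-fold dilution from 10 µM down to
#'   0.0137 µM.
#' @param viability percent viability at each concentration; finite and
#'   non-negative, values above 100 (cells outgrowing controls) allowed and
#'   capped at 300.
#' @param sampleId,drugId identifiers.
#' @return An object of class `"DoseResponseCurve"`.
#' @export
doseResponseCurve <- function(concentrations, viability,
                              sampleId = "sample", drugId = "drug") {
  if (length(concentrations) != length(viability)) {
    stop("concentrations and viability must have equal length")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be positive and finite")
  }
  d <- diff(concentrations)
  if (!(all(d > 0) || all(d < 0))) {
    stop("concentrations must be strictly increasing or decreasing")
  }
  if (any(!is.finite(viability)) || any(viability < 0)) {
    stop("viability must be finite and >= 0")
  }
  structure(list(concentrations = as.numeric(concentrations),
                 viability = pmin(as.numeric(viability), 300),
                 sampleId = sampleId, drugId = drugId),
            class = "DoseResponseCurve")
}

#' Fit a probit dose-response curve
#'
#' Models viability/100 as `pnorm(intercept + slope * log10(conc))`, fitted by
#' least squares (the maximum-likelihood estimate under homoscedastic Gaussian
#' errors). A perfectly flat viability series is handled by a closed form:
#' slope 0 and the observed mean recorded as the flat level. Non-convergence
#' is reported in the returned object, never silently defaulted.
#'
#' @param curve a [doseResponseCurve()] with at least 4 distinct
#'   concentrations.
#' @return A [ProbitFit-class].
#' @export
fitProbitCurve <- function(curve) {
  stopifnot(inherits(curve, "DoseResponseCurve"))
  conc <- curve$concentrations
  v <- curve$viability
  if (length(unique(conc)) < 4L) {
    stop("at least 4 distinct concentrations are required")
  }
  x <- log10(conc)
  xLo <- min(x); xHi <- max(x)
  p <- v / 100

  if (diff(range(v)) < 1e-12) {
    vbar <- mean(v)
    pc <- clip(vbar / 100, 1e-8, 1 - 1e-8)
    return(new("ProbitFit", intercept = qnorm(pc), slope = 0,
               converged = TRUE, xLo = xLo, xHi = xHi, flatLevel = vbar))
  }

  sse <- function(par) sum((p - pnorm(par[1] + par[2] * x))^2)
  # probit-linearized start: exact for noiseless probit-generated data
  pc <- clip(p, 1e-3, 1 - 1e-3)
  z <- qnorm(pc)
  st <- tryCatch(coef(lm(z ~ x)), error = function(e) c(0, -1))
  starts <- list(c(st[[1]], st[[2]]), c(0, -1), c(0, 1))
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(
      optim(s0, sse, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(new("ProbitFit", intercept = NA_real_, slope = NA_real_,
               converged = FALSE, xLo = xLo, xHi = xHi,
               flatLevel = NA_real_))
  }
  new("ProbitFit", intercept = best$par[1], slope = best$par[2],
      converged = best$convergence == 0 &&
        all(is.finite(best$par)),
      xLo = xLo, xHi = xHi, flatLevel = NA_real_)
}

# fitted viability (percent) on the log10-concentration axis
probitViability <- function(fit, x) {
  if (is.finite(fit@flatLevel)) rep(fit@flatLevel, length(x))
  else 100 * pnorm(fit@intercept + fit@slope * x)
}

#' Normalized AUC of a fitted dose-response curve
#'
#' The mean fitted viability (percent) over the screened log10-concentration
#' range, computed by composite trapezoid integration (2048 panels), clipped
#' to the 0-300 scale. A completely non-responsive profile (flat 100 percent
#' viability) yields exactly 100; lower values indicate sensitivity; values
#' above 100 can only arise from flat series whose observed viability exceeds
#' controls.
#'
#' @param fit a [ProbitFit-class].
#' @param curve optional originating [doseResponseCurve()] (unused beyond
#'   provenance; the integration range is stored in `fit`).
#' @return numeric(1) AUC in `[0, 300]`.
#' @export
probitAuc <- function(fit, curve = NULL) {
  stopifnot(is(fit, "ProbitFit"))
  if (is.finite(fit@flatLevel)) return(clip(fit@flatLevel, 0, 300))
  if (!fit@converged) stop("probit fit did not converge; AUC undefined")
  x <- seq(fit@xLo, fit@xHi, length.out = 2049L)
  auc <- trapz(x, probitViability(fit, x)) / (fit@xHi - fit@xLo)
  clip(auc, 0, 300)
}

#' Sensitivity call from AUC
#'
#' `AUC < 100` is called `"sensitive"` (drug-induced viability reduction);
#' anything else -- including exactly 100 and growth-stimulated profiles
#' above 100 -- is `"resistant"`.
#'
#' @param auc numeric vector of AUC values on the 0-300 scale.
#' @return character vector of `"sensitive"`/`"resistant"`.
#' @export
labelByAuc <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0 | auc > 300)) {
    stop("auc must lie in [0, 300]")
  }
  ifelse(auc < 100, "sensitive", "resistant")
}

#' Drug Sensitivity Score (DSS) from precomputed inputs
#'
#' Computes, on the log10-concentration axis:
#' \deqn{DSS1 = (AUC_r - A_{min} (x_2 - x_1)) / ((100 - A_{min})(C_{max} - C_{min}))}
#' \deqn{DSS2 = DSS1 / \log_{10} R_{max}}
#' \deqn{DSS3 = DSS2 \cdot (x_2 - x_1) / (C_{max} - C_{min})}
#' where `aucResp` is the area under the inhibition (response) curve over
#' `[x1, x2]`, the window where inhibition exceeds the activity threshold
#' `aMin`, and `rMax` is the top asymptote of the inhibition curve in
#' percent. If the response never exceeds `aMin` (`x1 == x2`) the score is 0.
#'
#' @param aucResp area under the inhibition curve over `[x1, x2]`.
#' @param x1,x2 log10 concentrations where inhibition crosses `aMin`.
#' @param cMin,cMax log10 of the lowest/highest screened concentrations.
#' @param aMin activity threshold in percent (default 10).
#' @param rMax top asymptote of the inhibition curve in percent (required for
#'   versions 2 and 3; must exceed 1).
#' @param version DSS variant: 1, 2 or 3.
#' @return numeric(1).
#' @export
computeDss <- function(aucResp, x1, x2, cMin, cMax, aMin = 10,
                       rMax = NULL, version = 1) {
  version <- as.integer(version)
  if (!version %in% 1:3) stop("version must be 1, 2 or 3")
  if (!isTRUE(cMin < cMax)) stop("cMin must be < cMax")
  if (!isTRUE(x1 <= x2)) stop("x1 must be <= x2")
  if (x1 < cMin - 1e-9 || x2 > cMax + 1e-9) stop("[x1, x2] must lie within [cMin, cMax]")
  if (x2 - x1 <= 0) return(0)
  dss1 <- (aucResp - aMin * (x2 - x1)) / ((100 - aMin) * (cMax - cMin))
  if (version == 1L) return(dss1)
  if (is.null(rMax) || !is.finite(rMax) || rMax <= 1) {
    stop("versions 2 and 3 require rMax > 1 (log10 rMax must be positive)")
  }
  dss2 <- dss1 / log10(rMax)
  if (version == 2L) return(dss2)
  dss2 * (x2 - x1) / (cMax - cMin)
}

# locate the crossing of f(x) = target by bisection within [lo, hi]
bisectCross <- function(f, lo, hi, target, tol = 1e-8) {
  flo <- f(lo) - target; fhi <- f(hi) - target
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (flo * fhi > 0) stop("bisection interval does not bracket the crossing")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid) - target
    if (fm == 0) return(mid)
    if (flo * fm < 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' DSS from a fitted probit curve
#'
#' Builds the DSS inputs from the fitted inhibition curve
#' `r(x) = 100 - v(x)`: the top asymptote `rMax` over the screened range, the
#' crossing points of `r(x) = aMin` (bisection to 1e-8; the first up-crossing
#' and the last down-crossing, falling back to the range ends where the curve
#' starts or ends above threshold), and the trapezoid area of `r` over
#' `[x1, x2]` (2048 panels). Delegates to [computeDss()].
#'
#' @inheritParams probitAuc
#' @inheritParams computeDss
#' @param curve optional originating curve (provenance only).
#' @return numeric(1) DSS.
#' @export
dssFromFit <- function(fit, curve = NULL, aMin = 10, version = 1) {
  stopifnot(is(fit, "ProbitFit"))
  cMin <- fit@xLo; cMax <- fit@xHi
  r <- function(x) 100 - pmin(probitViability(fit, x), 100)
  grid <- seq(cMin, cMax, length.out = 4097L)
  rg <- r(grid)
  rMax <- max(rg)
  if (rMax <= aMin) return(0)

  above <- rg >= aMin
  # first up-crossing
  if (above[1L]) {
    x1 <- cMin
  } else {
    i <- which(above)[1L]
    x1 <- bisectCross(r, grid[i - 1L], grid[i], aMin)
  }
  # last down-crossing (or cMax if still above at the top concentration)
  if (above[length(above)]) {
    x2 <- cMax
  } else {
    j <- max(which(above))
    x2 <- bisectCross(r, grid[j], grid[j + 1L], aMin)
  }
  xx <- seq(x1, x2, length.out = 2049L)
  aucResp <- trapz(xx, r(xx))
  computeDss(aucResp, x1, x2, cMin, cMax, aMin = aMin, rMax = rMax,
             version = version)
}

#' Selective DSS
#'
#' The patient DSS minus the mean of the control DSS values:
#' `sDSS = DSS_patient - mean(DSS_controls)`. Higher values indicate
#' selectively greater sensitivity of the patient cells than healthy
#' controls.
#'
#' @param dssPatient numeric(1) patient DSS.
#' @param dssControls numeric vector of control DSS values (length >= 1).
#' @return numeric(1) sDSS.
#' @export
sdss <- function(dssPatient, dssControls) {
  stopifnot_scalar_number(dssPatient, "dssPatient")
  if (length(dssControls) < 1L) stop("at least one control DSS is required")
  dssPatient - mean(dssControls)
}

#' Label records by an sDSS percentile threshold
#'
#' The threshold is the given percentile (type-7 linear interpolation) of the
#' pooled sDSS values across all drugs and samples; a record is called
#' `"sensitive"` iff its sDSS is strictly above the threshold.
#'
#' @param records data.frame with columns `sample_id`, `drug_id`, `sdss`.
#' @param percentile percentile in `[0, 100)`, default 95 (0 thresholds at
#'   the pooled minimum).
#' @return `records` with columns `label` and attribute
#'   `"threshold"` giving the pooled cutoff.
#' @export
labelBySdssPercentile <- function(records, percentile = 95) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data.frame")
  }
  if (!"sdss" %in% names(records) || any(!is.finite(records$sdss))) {
    stop("all records must carry a finite sdss value")
  }
  if (!(percentile >= 0 && percentile < 100)) {
    stop("percentile must lie in [0, 100)")
  }
  thr <- unname(quantile(records$sdss, percentile / 100, type = 7))
  records$label <- ifelse(records$sdss > thr, "sensitive", "resistant")
  attr(records, "threshold") <- thr
  records
}
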