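## Luciferin/luciferase calibration, bulk release arithmetic, dose-response
## and regression summaries.

#' Fit an ATP standard calibration curve
#'
#' Ordinary least-squares fit of `log10(signal)` against `log10([ATP])` over
#' the supplied standards. The log-log linear form is the standard choice for
#' luciferase assays, which are close to power-law over several decades of
#' concentration. The valid range is set to the span of the standards;
#' conversions outside it are flagged as extrapolated by [signalToAtp()].
#'
#' @param atpUm standard concentrations, uM (> 0, >= 3 distinct values).
#' @param signal measured reporter signals (> 0), same length.
#' @return A [CalibrationCurve-class].
#' @examples
#' cal <- fitAtpCalibration(c(0.1, 1, 10, 100), 10 * c(0.1, 1, 10, 100))
#' signalToAtp(cal, 10)  # 1 uM
#' @export
fitAtpCalibration <- function(atpUm, signal) {
    if (length(atpUm) != length(signal))
        stop("'atpUm' and 'signal' must have equal length")
    if (length(unique(atpUm)) < 3L)
        stop("need at least 3 standards with distinct concentrations")
    if (any(atpUm <= 0) || any(signal <= 0))
        stop("standards must have positive concentrations and signals")
    fit <- stats::lm(log10(signal) ~ log10(atpUm))
    cf <- unname(stats::coef(fit))
    n <- length(atpUm)
    rsd <- if (n > 2L) sqrt(sum(stats::residuals(fit)^2) / (n - 2L)) else 0
    new("CalibrationCurve", model = "loglog-linear", slope = cf[2L],
        intercept = cf[1L], validRange = range(atpUm), residualSd = rsd)
}

#' Convert a reporter signal to an ATP concentration
#'
#' Inverts the log-log linear calibration:
#' `[ATP] = 10^((log10(signal) - intercept)/slope)`. Values outside the
#' calibrated range are returned unchanged but flagged through the
#' `extrapolated` attribute. Signals must be positive; background-subtracted
#' signals that went negative should be clamped upstream ([bulk workflows
#' treat them as zero ATP with a flag]).
#'
#' @param curve a [CalibrationCurve-class].
#' @param signal reporter signal(s), > 0.
#' @return Concentration(s) in uM with logical attribute `extrapolated`
#'   marking values outside the calibration range.
#' @export
signalToAtp <- function(curve, signal) {
    stopifnot(is(curve, "CalibrationCurve"))
    if (any(signal <= 0))
        stop("'signal' must be > 0; background-subtracted non-positive ",
             "signals carry no concentration information")
    conc <- 10^((log10(signal) - curve@intercept) / curve@slope)
    attr(conc, "extrapolated") <-
        conc < curve@validRange[1L] | conc > curve@validRange[2L]
    conc
}

#' Predicted reporter signal at a concentration
#'
#' Forward evaluation of the calibration model; the inverse of
#' [signalToAtp()].
#'
#' @param curve a [CalibrationCurve-class].
#' @param atpUm concentration(s), uM (> 0).
#' @return Signal(s) in the units of the calibration standards.
#' @export
atpToSignal <- function(curve, atpUm) {
    stopifnot(is(curve, "CalibrationCurve"))
    if (any(atpUm <= 0)) stop("'atpUm' must be > 0")
    10^(curve@intercept + curve@slope * log10(atpUm))
}

#' ATP released per cell from a bulk supernatant measurement
#'
#' Unit arithmetic: uM * uL = pmol, and 1 pmol = 1e6 amol, so
#' `amol/cell = concentration * volume * 1e6 / cellCount`.
#'
#' @param concentrationUm supernatant ATP concentration, uM (> 0).
#' @param volumeUl sampled volume, uL (> 0).
#' @param cellCount number of cells in the sampled compartment (> 0).
#' @return Released ATP in amol/cell.
#' @examples
#' bulkReleasePerCell(0.01, 2000, 1e5)  # 200 amol/cell
#' @export
bulkReleasePerCell <- function(concentrationUm, volumeUl, cellCount) {
    if (any(cellCount <= 0)) stop("'cellCount' must be > 0")
    if (any(concentrationUm < 0) || any(volumeUl <= 0))
        stop("'concentrationUm' must be >= 0 and 'volumeUl' > 0")
    concentrationUm * volumeUl * 1e6 / cellCount
}

#' Released ATP as a percentage of total cellular content
#'
#' @param releasedAmol released ATP, amol/cell (>= 0).
#' @param totalContentAmol total cellular ATP content, amol/cell (> 0).
#' @return Percentage; values above 100 are returned with a warning (they
#'   indicate inconsistent inputs upstream).
#' @export
percentOfContent <- function(releasedAmol, totalContentAmol) {
    if (any(totalContentAmol <= 0)) stop("'totalContentAmol' must be > 0")
    pct <- 100 * releasedAmol / totalContentAmol
    if (any(pct > 100))
        warning("released amount exceeds total content (> 100%); check the ",
                "content measurement or the release estimate")
    pct
}

#' Fit a saturating rational dose-response curve
#'
#' Nonlinear least-squares fit of `y = a x / (b + x)` with `a, b > 0`: a
#' first-order rational function, monotone increasing in the dose, with
#' horizontal asymptote `a`. Used for release against the number of media
#' displacements (turbulent fluid shear stress dose).
#'
#' @param doses stimulus doses (e.g. media displacement counts), >= 3
#'   distinct values.
#' @param responses measured responses (>= 0), same length.
#' @return A [RationalFit-class].
#' @examples
#' x <- 1:10
#' fitRationalDoseResponse(x, 400 * x / (3 + x))
#' @export
fitRationalDoseResponse <- function(doses, responses) {
    if (length(doses) != length(responses))
        stop("'doses' and 'responses' must have equal length")
    if (length(unique(doses)) < 3L)
        stop("need at least 3 distinct doses")
    if (any(responses < 0)) stop("'responses' must be >= 0")
    if (stats::sd(responses) == 0)
        stop("degenerate data: all responses equal, saturation is ",
             "unidentifiable")
    a0 <- max(responses) * 1.2
    ## b0 from the dose nearest half of the initial asymptote guess
    b0 <- doses[which.min(abs(responses - a0 / 2))]
    if (!is.finite(b0) || b0 <= 0) b0 <- stats::median(doses)
    fit <- minpack.lm::nlsLM(responses ~ a * doses / (b + doses),
        start = list(a = a0, b = b0),
        lower = c(1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    new("RationalFit", a = unname(cf["a"]), b = unname(cf["b"]),
        rss = sum(stats::residuals(fit)^2), asymptote = unname(cf["a"]))
}

#' Linear regression and correlation summary
#'
#' Ordinary least-squares line of `y` on `x` plus the Pearson correlation,
#' as used for the regression overlays relating e.g. pericellular ATP to
#' secondary responsiveness, or vesicular release to membrane disruption.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return A list with `slope`, `intercept`, `r`, `r2`, `n`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)
#' @export
correlate <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3L)
        stop("'x' and 'y' must have equal length >= 3")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("'x' and 'y' must be finite")
    if (stats::sd(x) == 0)
        stop("zero variance in 'x': regression slope undefined")
    fit <- stats::lm(y ~ x)
    cf <- unname(stats::coef(fit))
    r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
    list(slope = cf[2L], intercept = cf[1L], r = r, r2 = r^2,
         n = length(x))
}
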