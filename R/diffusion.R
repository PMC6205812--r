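## Instantaneous plane-source diffusion model and source-strength estimation.

#' Default ATP diffusion coefficient (um^2/s)
#'
#' 330 um^2/s, i.e. 3.3e-6 cm^2/s, the aqueous ATP diffusion coefficient at
#' 22 degrees C conventionally used for pericellular diffusion modelling.
#' Exposed as a constant so callers can see and override the assumption.
#'
#' @export
DEFAULT_D_ATP <- 330

#' Concentration from an instantaneous plane source
#'
#' Evaluates the one-dimensional diffusion solution for an amount released
#' instantaneously from a plane at `x = 0`, `t = 0`:
#' \deqn{c(x, t) = \frac{\sigma}{2\sqrt{\pi D t}} \exp\!\left(-\frac{x^2}{4 D t}\right)}
#' with areal source strength `sigma` in amol/um^2 and `D` in um^2/s, so the
#' raw result is in amol/um^3 = mM; the return value is converted to uM.
#' The solution integrates over the whole line to `sigma` (mass
#' conservation) and is undefined at `t = 0` (a delta function).
#'
#' @param sigma areal source strength, amol/um^2 (>= 0).
#' @param D diffusion coefficient, um^2/s (default [DEFAULT_D_ATP]).
#' @param x distance(s) from the source plane, um.
#' @param t time(s) since release, s (> 0). `x` and `t` are recycled.
#' @return Concentration(s) in uM.
#' @examples
#' planeSourceConcentration(1, 330, x = 0, t = 1)  # ~15.5 uM
#' @export
planeSourceConcentration <- function(sigma, D = DEFAULT_D_ATP, x, t) {
    stopifnot(length(sigma) == 1L, sigma >= 0, length(D) == 1L, D > 0)
    if (any(t <= 0))
        stop("the plane-source model is undefined at t <= 0 ",
             "(instantaneous release at t = 0)")
    1000 * sigma / (2 * sqrt(pi * D * t)) * exp(-x^2 / (4 * D * t))
}

#' Fit the released amount to a pericellular concentration profile
#'
#' Estimates the areal source strength sigma (amol/um^2) of an instantaneous
#' plane source from observed (distance, time, concentration) triples, and
#' converts it to a total released amount `M = sigma * effectiveArea` (amol)
#' when an effective release area is supplied. The plane-source model gives an
#' areal strength only; no default area is assumed, because the conversion
#' geometry (the membrane area acting as the source) is an experimental
#' quantity.
#'
#' With `fitT0 = FALSE` the model is linear in sigma and the estimate is the
#' closed-form least-squares solution
#' `sigma = sum(m_i * c_i) / sum(m_i^2)` where `m_i` is the model prediction
#' at unit sigma. With `fitT0 = TRUE`, (sigma, t0) are fitted jointly by
#' nonlinear least squares, absorbing a mismatch between the nominal stimulus
#' time and the actual moment of release; on non-convergence the function
#' falls back to the linear solution with `converged = FALSE`.
#'
#' @param profile a [ConcentrationProfile-class] with >= 3 observations.
#' @param D diffusion coefficient, um^2/s (default [DEFAULT_D_ATP]).
#' @param effectiveArea release area in um^2 used to report the total amount
#'   (default `NA`: only sigma is reported).
#' @param fitT0 also fit a release-time offset t0 (default FALSE).
#' @return A [SourceEstimate-class].
#' @examples
#' prof <- ConcentrationProfile(distances = c(0, 5, 10, 0, 5, 10),
#'                              times = c(1, 1, 1, 4, 4, 4),
#'                              concentrations = planeSourceConcentration(
#'                                  0.05, 330, c(0, 5, 10, 0, 5, 10),
#'                                  c(1, 1, 1, 4, 4, 4)))
#' fitSourceAmount(prof, effectiveArea = 400)
#' @export
fitSourceAmount <- function(profile, D = DEFAULT_D_ATP, effectiveArea = NA,
                            fitT0 = FALSE) {
    stopifnot(is(profile, "ConcentrationProfile"), D > 0)
    x <- profile@distances
    t <- profile@times
    cc <- profile@concentrations
    if (length(cc) < 3L)
        stop("need at least 3 (x, t, c) observations to fit the source")

    m <- planeSourceConcentration(1, D, x, t)
    if (all(m == 0))
        stop("model predictions are zero at every observation; the ",
             "observation grid cannot constrain sigma")

    sigmaLin <- sum(m * cc) / sum(m^2)
    sigmaLin <- max(sigmaLin, 0)
    method <- "linear"
    t0 <- 0
    sigma <- sigmaLin
    converged <- TRUE

    if (fitT0) {
        fit <- tryCatch(
            minpack.lm::nlsLM(
                cc ~ 1000 * s / (2 * sqrt(pi * D * (t - t0))) *
                     exp(-x^2 / (4 * D * (t - t0))),
                start = list(s = max(sigmaLin, 1e-12), t0 = 0),
                lower = c(0, -min(t) * 10),
                upper = c(Inf, min(t) * 0.99),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        if (!is.null(fit)) {
            cf <- stats::coef(fit)
            sigma <- unname(cf["s"])
            t0 <- unname(cf["t0"])
            method <- "nls"
        } else {
            converged <- FALSE
            warning("nonlinear (sigma, t0) fit did not converge; ",
                    "returning the closed-form linear solution")
        }
    }

    pred <- planeSourceConcentration(sigma, D, x, t - t0)
    rss <- sum((cc - pred)^2)
    tss <- sum((cc - mean(cc))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_

    new("SourceEstimate", sigma = sigma,
        MTotal = if (is.finite(effectiveArea)) sigma * effectiveArea
                 else NA_real_,
        effectiveArea = as.numeric(effectiveArea), D = D, t0Offset = t0,
        rss = rss, r2 = r2, method = method, converged = converged)
}

#' Time to peak of a release trace
#'
#' Time of the post-stimulus maximum relative to the stimulus. A peak that
#' falls on the final sample is reported with attribute
#' `truncated = TRUE`, since the true maximum may lie beyond the recording.
#'
#' @param trace a [FluorescenceTrace-class] (e.g. a pericellular luciferin
#'   signal).
#' @return Time to peak in seconds, with a logical attribute `truncated`.
#' @export
timeToPeak <- function(trace) {
    stopifnot(is(trace, "FluorescenceTrace"))
    post <- which(trace@times >= trace@stimulusTime)
    if (!length(post))
        stop("trace has no post-stimulus segment")
    ipk <- post[which.max(trace@values[post])]
    out <- trace@times[ipk] - trace@stimulusTime
    attr(out, "truncated") <- ipk == length(trace@values)
    out
}
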