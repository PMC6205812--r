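## Membrane injury classification from dye-leakage traces and lesion-size
## bracketing from tracer permeability.

#' Classify membrane injury from a dye-leakage trace
#'
#' Compares intracellular dye fluorescence before and after mechanical
#' stimulation. The baseline is the pre-stimulus median; the post-stimulus
#' plateau is the median of the final `plateauWindowS` seconds. The retained
#' fraction is referenced to a background floor (fluorescence of a cell-free
#' region, or 0 when absent):
#' `retained = clamp((plateau - floor) / (baseline - floor), 0, 1)`.
#' Classes follow the dye-leakage taxonomy: fluorescence returning to
#' baseline is minor injury (`mIn`, retained >= `thresholds["mIn"]`),
#' complete loss is severe injury (`sIn`, retained <= `thresholds["sIn"]`),
#' anything between is intermediate (`iIn`). The default cutoffs (0.8 / 0.1)
#' are configurable.
#'
#' @param trace a [FluorescenceTrace-class] intensity recording spanning the
#'   baseline window and at least `plateauWindowS` beyond the stimulus.
#' @param baselineWindowS pre-stimulus window (s, default 10).
#' @param plateauWindowS length of the terminal plateau window (s,
#'   default 10).
#' @param thresholds named numeric, `c(mIn = 0.8, sIn = 0.1)`.
#' @param floor background fluorescence floor (default 0).
#' @return An [InjuryCall-class].
#' @export
classifyInjuryTrace <- function(trace, baselineWindowS = 10,
                                plateauWindowS = 10,
                                thresholds = c(mIn = 0.8, sIn = 0.1),
                                floor = 0) {
    stopifnot(is(trace, "FluorescenceTrace"))
    if (thresholds["sIn"] >= thresholds["mIn"])
        stop("'thresholds' must satisfy sIn < mIn")
    tEnd <- trace@times[length(trace@times)]
    if (tEnd - plateauWindowS < trace@stimulusTime)
        stop("plateau window extends beyond the post-stimulus recording")
    bl <- estimateBaseline(trace, baselineWindowS)
    plateauIdx <- which(trace@times >= tEnd - plateauWindowS)
    plateau <- stats::median(trace@values[plateauIdx])
    if (bl <= floor)
        stop("baseline does not exceed the background floor; the retained ",
             "fraction is undefined")
    retained <- clamp((plateau - floor) / (bl - floor), 0, 1)
    klass <- if (retained >= thresholds["mIn"]) "mIn"
             else if (retained <= thresholds["sIn"]) "sIn"
             else "iIn"
    new("InjuryCall", roiId = trace@roiId, klass = klass, baseline = bl,
        postPlateau = plateau, retainedFraction = retained)
}

.classVector <- function(calls) {
    if (is.character(calls)) return(calls)
    if (is(calls, "InjuryCall")) return(calls@klass)
    vapply(calls, function(x) {
        if (is(x, "InjuryCall")) x@klass else as.character(x)
    }, character(1))
}

#' Relative frequency of injury classes
#'
#' @param calls list of [InjuryCall-class] objects (or a character vector of
#'   class labels).
#' @return Named numeric `c(mIn, iIn, sIn)` percentages of stimulated cells,
#'   summing to 100.
#' @examples
#' injuryFrequencies(c("mIn", "mIn", "iIn", "sIn"))  # 50, 25, 25
#' @export
injuryFrequencies <- function(calls) {
    kl <- .classVector(calls)
    if (!length(kl)) stop("no injury calls supplied")
    bad <- setdiff(unique(kl), c("mIn", "iIn", "sIn"))
    if (length(bad))
        stop("unknown injury class(es): ", paste(bad, collapse = ", "))
    counts <- vapply(c("mIn", "iIn", "sIn"), function(k) sum(kl == k),
                     numeric(1))
    100 * counts / length(kl)
}

#' Fura-2 leakage: percentage of severely injured cells
#'
#' By convention, "Fura-2 leakage" reports the percentage of stimulated cells
#' with complete loss of intracellular fluorescence (`sIn`).
#'
#' @inheritParams injuryFrequencies
#' @return Percentage of `sIn` calls.
#' @export
fura2LeakagePercent <- function(calls) {
    unname(injuryFrequencies(calls)["sIn"])
}

#' Dye-positive fraction of cells
#'
#' @param positive number of dye-positive cells (0 <= positive <= total).
#' @param total total cells assessed (> 0).
#' @return Percentage of dye-positive cells.
#' @export
dyeUptakeFraction <- function(positive, total) {
    if (any(total <= 0)) stop("'total' must be > 0")
    if (any(positive < 0) || any(positive > total))
        stop("'positive' must lie in [0, total]")
    100 * positive / total
}

#' LDH leakage as percent of total cellular LDH
#'
#' Blank-subtracted supernatant signal over blank-subtracted total-lysate
#' signal. A supernatant below blank yields 0\% with attribute
#' `clamped = TRUE`.
#'
#' @param supernatantSignal extracellular LDH signal.
#' @param totalLysateSignal total cellular LDH signal (> blank).
#' @param blank blank signal subtracted from both (default 0).
#' @return Percentage with logical attribute `clamped`.
#' @export
ldhLeakagePercent <- function(supernatantSignal, totalLysateSignal,
                              blank = 0) {
    tot <- totalLysateSignal - blank
    if (any(tot <= 0))
        stop("'totalLysateSignal' must exceed the blank")
    sup <- supernatantSignal - blank
    clamped <- sup < 0
    sup[clamped] <- 0
    out <- 100 * sup / tot
    attr(out, "clamped") <- clamped
    out
}

#' Minimal molecular radius from molecular weight
#'
#' Minimal compact-sphere radius `R(nm) = 0.066 * MW(Da)^(1/3)` (Erickson's
#' relation), the smallest radius a molecule of the given mass can have at
#' typical macromolecular density. Applied as a lower-bound convention to all
#' tracer species, including polymer coils such as dextran, whose
#' hydrodynamic radius is larger; per-dye radii can be overridden in the dye
#' table.
#'
#' @param molecularWeight molecular weight in Da (> 0).
#' @return Radius in nm.
#' @examples
#' molecularRadius(507)     # ATP, ~0.53 nm
#' molecularRadius(140000)  # LDH, ~3.4 nm
#' @export
molecularRadius <- function(molecularWeight) {
    if (any(molecularWeight <= 0)) stop("'molecularWeight' must be > 0")
    0.066 * molecularWeight^(1 / 3)
}

#' Default membrane-integrity tracer table
#'
#' The tracers of the standard injury panel with their nominal molecular
#' weights: ATP (507 Da), Fura-2 (832 Da, pentapotassium salt -- override
#' `mw_da` if a different form was used), trypan blue (~900 Da),
#' rhodamine-dextran (~10 kDa nominal) and LDH (~140 kDa). The `permeant`
#' flags encode the permeability pattern of a typical micropipette
#' experiment (small tracers cross the lesion; dextran and LDH largely do
#' not) and should be set from the experiment at hand.
#'
#' @return data.frame with columns `name`, `mw_da`, `radius_nm` (NA: compute
#'   from MW), `permeant`.
#' @export
defaultDyeTable <- function() {
    data.frame(
        name = c("ATP", "Fura-2", "TB", "R-dextran", "LDH"),
        mw_da = c(507, 832, 900, 10000, 140000),
        radius_nm = NA_real_,
        permeant = c(TRUE, TRUE, TRUE, FALSE, FALSE),
        stringsAsFactors = FALSE)
}

#' Bracket the membrane lesion radius from tracer permeability
#'
#' The minimum lesion radius compatible with an observed permeability pattern
#' is bounded below by the largest tracer that crossed the membrane and above
#' by the smallest tracer that was excluded (`Inf` when every tracer
#' crossed). Missing radii are computed from molecular weight via
#' [molecularRadius()]. A permeant tracer larger than an excluded one is a
#' physical inconsistency and raises an error naming the pair.
#'
#' @param dyes data.frame with columns `name`, `mw_da`, optional `radius_nm`,
#'   and logical `permeant`; see [defaultDyeTable()].
#' @return A [LesionBracket-class].
#' @examples
#' lesionRadiusBracket(defaultDyeTable())
#' @export
lesionRadiusBracket <- function(dyes) {
    req <- c("name", "permeant")
    if (!all(req %in% names(dyes)))
        stop("'dyes' must have columns name and permeant")
    if (!any(dyes$permeant))
        stop("at least one dye must be flagged permeant")
    if (is.null(dyes$radius_nm)) dyes$radius_nm <- NA_real_
    needs <- !is.finite(dyes$radius_nm)
    if (any(needs)) {
        if (is.null(dyes$mw_da) || any(!is.finite(dyes$mw_da[needs])))
            stop("dye radii missing and not computable: supply radius_nm ",
                 "or mw_da")
        dyes$radius_nm[needs] <- molecularRadius(dyes$mw_da[needs])
    }
    lower <- max(dyes$radius_nm[dyes$permeant])
    excluded <- dyes[!dyes$permeant, , drop = FALSE]
    upper <- if (nrow(excluded)) min(excluded$radius_nm) else Inf
    if (is.finite(upper) && lower >= upper) {
        iP <- which(dyes$permeant & dyes$radius_nm == lower)[1L]
        iE <- which(!dyes$permeant & dyes$radius_nm == upper)[1L]
        stop("inconsistent permeability pattern: permeant '",
             dyes$name[iP], "' (", signif(lower, 3),
             " nm) is at least as large as excluded '", dyes$name[iE],
             "' (", signif(upper, 3), " nm)")
    }
    new("LesionBracket", lowerNm = lower, upperNm = upper, dyes = dyes)
}
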