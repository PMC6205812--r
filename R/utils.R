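## Internal helpers.

## Evaluate expr with a locally set RNG seed, restoring the caller's RNG state.
## Generators are pure functions of (parameters, seed).
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number")
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Indices of the pre-stimulus baseline window [stimulus - window, stimulus).
baselineIndices <- function(trace, windowS) {
    t <- trace@times
    which(t >= trace@stimulusTime - windowS & t < trace@stimulusTime)
}

## Linear interpolation of the time at which a trace segment crosses `level`
## between samples i and i+1.
crossingTime <- function(times, values, i, level) {
    t0 <- times[i]; t1 <- times[i + 1L]
    v0 <- values[i]; v1 <- values[i + 1L]
    if (v1 == v0) return(t1)
    t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}
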