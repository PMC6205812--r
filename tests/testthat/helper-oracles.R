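# Shared helpers: trace constructors and the event-matching oracle used for
# detection metrics against generator ground truth.

makeTrace <- function(values, rate = 2, stim = 10, roi = "t") {
    FluorescenceTrace(roi, values = values, samplingRate = rate,
                      stimulusTime = stim)
}

# Match detected events to ground-truth events by punctum position and time.
# Greedy one-to-one matching; returns tp/fp/fn counts.
matchEvents <- function(events, truth, tolS = 1.5, tolUm = 1.5) {
    truePos <- truth$positions[truth$eventPuncta, , drop = FALSE]
    used <- rep(FALSE, length(truth$eventTimes))
    tp <- 0L
    for (r in seq_len(nrow(events))) {
        d <- sqrt((truePos[, 1L] - events$x_um[r])^2 +
                  (truePos[, 2L] - events$y_um[r])^2)
        ok <- which(!used & d < tolUm &
                    abs(truth$eventTimes - events$t_s[r]) <= tolS)
        if (length(ok)) {
            used[ok[1L]] <- TRUE
            tp <- tp + 1L
        }
    }
    c(tp = tp, fp = nrow(events) - tp, fn = sum(!used))
}

f1FromCounts <- function(m) {
    prec <- m[["tp"]] / max(m[["tp"]] + m[["fp"]], 1L)
    rec <- m[["tp"]] / max(m[["tp"]] + m[["fn"]], 1L)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Count detected events whose position matches a gradual-fade punctum.
fadesMiscalled <- function(events, truth, tolUm = 1) {
    if (!length(truth$fadePuncta) || !nrow(events)) return(0L)
    fadePos <- truth$positions[truth$fadePuncta, , drop = FALSE]
    sum(vapply(seq_len(nrow(events)), function(r) {
        min(sqrt((fadePos[, 1L] - events$x_um[r])^2 +
                 (fadePos[, 2L] - events$y_um[r])^2)) < tolUm
    }, logical(1)))
}
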