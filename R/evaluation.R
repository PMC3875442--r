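# Structure extraction from estimated parameters and scoring against a
# reference network: confusion counts over ordered gene pairs, recall /
# precision / specificity, and precision-recall curves over a
# hyper-parameter sweep.

#' Extract a signed network structure from model weights
#'
#' Thresholds the weight matrix: `w[i, j] > delta` becomes a positive
#' regulation of gene i by gene j, `w[i, j] < -delta` a negative one, and
#' anything in between no regulation.
#'
#' @param model a [VohradskyModel-class] (or a bare numeric weight
#'   matrix).
#' @param delta nonnegative magnitude threshold.
#' @param includeSelf keep the diagonal (self-regulations)?  Set `FALSE`
#'   when scoring benchmarks that exclude self-loops.
#' @return A [SignedNetwork-class].
#' @examples
#' extractStructure(smallScaleModel(), delta = 0.1)
#' @export
extractStructure <- function(model, delta = 0.1, includeSelf = TRUE) {
    stopifnot(delta >= 0)
    W <- if (is(model, "VohradskyModel")) regWeights(model) else as.matrix(model)
    A <- sign(W) * (abs(W) > delta)
    SignedNetwork(A, includeSelf = includeSelf)
}

#' Confusion counts between signed networks
#'
#' Compares ordered gene pairs (excluding the diagonal unless both
#' networks carry self-regulations).  In sign-agnostic mode any inferred
#' edge matching any true edge is a true positive.  In sign-aware mode a
#' true positive requires the matching sign; an inferred edge of the
#' wrong sign counts as a false positive *and* the missed true edge as a
#' false negative (so `TP+FP+FN+TN` exceeds the pair count by the number
#' of sign mismatches).
#'
#' @param inferred,truth [SignedNetwork-class] objects of equal size and
#'   equal `includeSelf`.
#' @param signAware compare regulation signs (`TRUE`) or only presence
#'   (`FALSE`)?
#' @return list of class `"ConfusionCounts"` with fields `TP`, `FP`,
#'   `FN`, `TN`, `pairs` and `signMismatches`.
#' @examples
#' truth <- SignedNetwork(matrix(c(0, 1, -1, 0), 2, 2), includeSelf = FALSE)
#' confusionCounts(truth, truth)
#' @export
confusionCounts <- function(inferred, truth, signAware = TRUE) {
    stopifnot(is(inferred, "SignedNetwork"), is(truth, "SignedNetwork"))
    if (nGenes(inferred) != nGenes(truth))
        stop("networks have different sizes")
    if (inferred@includeSelf != truth@includeSelf)
        stop("networks disagree on includeSelf")
    A <- adjacencySigns(inferred)
    B <- adjacencySigns(truth)
    keep <- matrix(TRUE, nrow(A), ncol(A))
    if (!inferred@includeSelf) diag(keep) <- FALSE
    a <- A[keep]
    b <- B[keep]
    if (signAware) {
        mism <- sum(a != 0 & b != 0 & a != b)
        TP <- sum(a != 0 & a == b)
        TN <- sum(a == 0 & b == 0)
        FP <- sum(a != 0 & b == 0) + mism
        FN <- sum(a == 0 & b != 0) + mism
    } else {
        mism <- 0L
        TP <- sum(a != 0 & b != 0)
        TN <- sum(a == 0 & b == 0)
        FP <- sum(a != 0 & b == 0)
        FN <- sum(a == 0 & b != 0)
    }
    structure(list(TP = TP, FP = FP, FN = FN, TN = TN, pairs = sum(keep),
                   signMismatches = mism),
              class = "ConfusionCounts")
}

#' Recall, precision and specificity from confusion counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `specificity = TN/(TN+FP)`; a 0/0 ratio is returned as `NA`
#' (undefined).
#'
#' @param cc a `"ConfusionCounts"` list (or any list with `TP`, `FP`,
#'   `FN`, `TN`).
#' @return named numeric vector `c(recall, precision, specificity)`.
#' @examples
#' networkMetrics(list(TP = 13, FP = 15, FN = 153, TN = 9719))
#' @export
networkMetrics <- function(cc) {
    rat <- function(num, den) if (den == 0) NA_real_ else num / den
    c(recall = rat(cc$TP, cc$TP + cc$FN),
      precision = rat(cc$TP, cc$TP + cc$FP),
      specificity = rat(cc$TN, cc$TN + cc$FP))
}

#' Precision-recall curve over a hyper-parameter sweep
#'
#' Turns a sweep of confusion counts (one per value of a hyper-parameter
#' such as the LP trade-off `theta` or the structure threshold `delta`)
#' into recall/precision pairs sorted by recall (ties kept).
#'
#' @param counts list of `"ConfusionCounts"`, length at least 2.
#' @param parameter optional numeric vector of the swept values, same
#'   length as `counts`.
#' @return `data.frame` with columns `parameter`, `recall`, `precision`,
#'   `specificity`, ordered by increasing recall.
#' @export
prCurve <- function(counts, parameter = seq_along(counts)) {
    if (length(counts) < 2L)
        stop("a curve needs at least 2 sweep points")
    stopifnot(length(parameter) == length(counts))
    mm <- t(vapply(counts, networkMetrics, numeric(3)))
    out <- data.frame(parameter = parameter, recall = mm[, "recall"],
                      precision = mm[, "precision"],
                      specificity = mm[, "specificity"])
    out[order(out$recall), , drop = FALSE]
}

#' Area under a precision-recall curve
#'
#' Trapezoidal area over the recall axis after dropping points with
#' undefined precision.  With fewer than two defined points the area is
#' `NA`.
#'
#' @param curve a `data.frame` from [prCurve()] (columns `recall`,
#'   `precision`).
#' @return scalar area, or `NA` if undefined.
#' @export
aucPR <- function(curve) {
    ok <- is.finite(curve$recall) & is.finite(curve$precision)
    r <- curve$recall[ok]
    p <- curve$precision[ok]
    o <- order(r)
    r <- r[o]
    p <- p[o]
    if (length(r) < 2L) return(NA_real_)
    sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Sweep the structure threshold and score against a reference
#'
#' Convenience wrapper: extracts structures from `model` at each `delta`,
#' scores each against `truth`, and returns the precision-recall curve.
#'
#' @param model a [VohradskyModel-class] (the estimated model).
#' @param truth the reference [SignedNetwork-class].
#' @param deltas numeric vector of thresholds (length >= 2).
#' @param signAware passed to [confusionCounts()].
#' @return A [prCurve()] data frame with `parameter = deltas`.
#' @export
structureSweep <- function(model, truth, deltas, signAware = TRUE) {
    counts <- lapply(deltas, function(d)
        confusionCounts(extractStructure(model, delta = d,
                                         includeSelf = truth@includeSelf),
                        truth, signAware = signAware))
    prCurve(counts, parameter = deltas)
}
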