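# Expression and derivative estimation from noisy series by local
# polynomial regression with tri-cube distance weights.  The derivative is
# the analytic slope of the local fit at the target time, never a finite
# difference of smoothed values (which would smooth twice).

# weighted local polynomial fit at one target time; returns c(value, slope)
.localPolyAt <- function(tt, xx, t0, span, degree) {
    L <- length(tt)
    q <- min(L, max(ceiling(span * L), degree + 2L))
    d <- abs(tt - t0)
    repeat {
        idx <- order(d)[seq_len(q)]
        h <- max(d[idx])
        w <- if (h == 0) rep(1, q) else pmax(1 - (d[idx] / h)^3, 0)^3
        if (sum(w > 0) >= degree + 1L || q >= L) break
        q <- q + 1L
    }
    if (sum(w > 0) < degree + 1L) w <- rep(1, q)  # degenerate tie layout
    X <- outer(tt[idx] - t0, 0:degree, `^`)
    fit <- lm.wfit(x = X, y = xx[idx], w = w)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    c(cf[1L], cf[2L])
}

#' Smooth time courses and estimate derivatives
#'
#' Fits a weighted local polynomial (tri-cube distance weights) around
#' every sample time of every series, independently per gene and per
#' series.  The smoothed level is the local fit value and the derivative
#' estimate is its analytic slope at that time.
#'
#' @param data an [ExpressionTimecourses-class].
#' @param span fraction of the series' points entering each local fit, in
#'   (0, 1]; the window size is `ceiling(span * length)` (at least
#'   `degree + 2`).
#' @param degree local polynomial degree, 1 (default) or 2.
#' @param floor minimum admissible smoothed expression level; fitted
#'   values below it are raised to `floor` (expression cannot be
#'   negative).
#' @return list with components `smoothed` (an
#'   [ExpressionTimecourses-class]) and `derivatives` (a
#'   [DerivativeTimecourses-class]).
#' @examples
#' tc <- ExpressionTimecourses(times = 0:10,
#'                             values = matrix((0:10)^2, ncol = 1))
#' smoothTimecourses(tc, span = 1, degree = 2)$derivatives
#' @export
smoothTimecourses <- function(data, span = 0.5, degree = 1L, floor = 0) {
    stopifnot(is(data, "Timecourses"), span > 0, span <= 1,
              degree %in% c(1L, 2L), floor >= 0)
    sm <- dv <- vector("list", nSeries(data))
    for (s in seq_len(nSeries(data))) {
        tt <- data@times[[s]]
        L <- length(tt)
        if (L < degree + 2L)
            stop(sprintf("series %d has %d points; at least %d are needed for degree %d",
                         s, L, degree + 2L, degree))
        if (ceiling(span * L) < degree + 1L)
            stop(sprintf("series %d: span %.3g leaves fewer than degree+1 points per fit",
                         s, span))
        v <- data@values[[s]]
        smv <- dvv <- v
        for (g in seq_len(ncol(v))) {
            for (r in seq_len(L)) {
                fs <- .localPolyAt(tt, v[, g], tt[r], span, degree)
                smv[r, g] <- fs[1L]
                dvv[r, g] <- fs[2L]
            }
        }
        sm[[s]] <- pmax(smv, floor)
        dv[[s]] <- dvv
    }
    list(smoothed = ExpressionTimecourses(data@times, sm, geneNames(data)),
         derivatives = DerivativeTimecourses(data@times, dv, geneNames(data)))
}

#' Per-gene maximum normalization
#'
#' Divides each gene's values by that gene's maximum across *all* series,
#' so every gene's normalized maximum is 1.  This is the normalization
#' applied to the SOS DNA repair expression data before inference.
#'
#' @param data an [ExpressionTimecourses-class].
#' @return The normalized [ExpressionTimecourses-class].
#' @export
normalizePerGeneMax <- function(data) {
    stopifnot(is(data, "ExpressionTimecourses"))
    mx <- apply(.stackValues(data), 2L, max)
    if (any(mx <= 0))
        stop("every gene needs a strictly positive maximum; offending gene(s): ",
             paste(geneNames(data)[mx <= 0], collapse = ", "))
    vals <- lapply(data@values, function(v) sweep(v, 2L, mx, `/`))
    ExpressionTimecourses(data@times, vals, geneNames(data))
}

#' Clamp low expression values to a floor
#'
#' Replaces every value below `floor` by `floor`; gene expression levels
#' must not be negative, and logit-based estimation needs strictly
#' positive levels.
#'
#' @param data a [Timecourses-class].
#' @param floor nonnegative replacement value.
#' @return Object of the same class with all values `>= floor`.
#' @export
floorLowValues <- function(data, floor = 0.001) {
    stopifnot(is(data, "Timecourses"), floor >= 0)
    vals <- lapply(data@values, function(v) pmax(v, floor))
    .makeTimecourses(class(data), data@times, vals, geneNames(data))
}

#' Drop the first samples of every series
#'
#' Removes the first `k` samples from each series (e.g. shared zero
#' initial concentrations, which a deterministic ODE cannot reconcile
#' across different series).
#'
#' @param data a [Timecourses-class].
#' @param k number of leading samples to drop from every series.
#' @return Object of the same class with `nSamples` reduced by
#'   `k * nSeries`.
#' @export
dropInitialPoints <- function(data, k) {
    stopifnot(is(data, "Timecourses"), k >= 0)
    if (k == 0) return(data)
    lens <- vapply(data@times, length, integer(1))
    if (any(lens <= k))
        stop(sprintf("series %d has only %d points; cannot drop %d",
                     which(lens <= k)[1], min(lens), k))
    keep <- lapply(lens, function(L) (k + 1L):L)
    .makeTimecourses(class(data),
                     Map(function(tt, idx) tt[idx], data@times, keep),
                     Map(function(v, idx) v[idx, , drop = FALSE],
                         data@values, keep),
                     geneNames(data))
}
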