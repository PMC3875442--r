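#' Sigmoid activation and its inverse
#'
#' `sigmoidActivation` evaluates the saturating activation
#' \eqn{\sigma(u) = 1/(1+e^{-u})} used in the synthesis term of the
#' Vohradsky model; `logit` is its inverse \eqn{\ln(y/(1-y))}, the
#' transformation that linearizes the model equations in the weights.
#' Both are vectorized and numerically stable over the full double range
#' (`sigmoidActivation` saturates at 0/1 for extreme arguments).
#'
#' @param u numeric vector of finite reals.
#' @param y numeric vector with all entries strictly inside (0, 1).
#' @return numeric vector of the same length.
#' @examples
#' sigmoidActivation(0)          # 0.5
#' logit(sigmoidActivation(1.3)) # 1.3
#' @export
sigmoidActivation <- function(u) {
    out <- u
    pos <- !is.na(u) & u >= 0
    out[pos] <- 1 / (1 + exp(-u[pos]))
    eu <- exp(u[!pos])
    out[!pos] <- eu / (1 + eu)
    out
}

#' @rdname sigmoidActivation
#' @export
logit <- function(y) {
    if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
        stop("logit is defined only for y strictly inside (0, 1)")
    log(y / (1 - y))
}

#' Right-hand side of the Vohradsky ODE
#'
#' Evaluates \eqn{k_{1,i}\sigma(\sum_j w_{ij} x_j + b_i) - k_{2,i} x_i}
#' for every gene at state `x`.
#'
#' @param model a [VohradskyModel-class].
#' @param x numeric state vector of length `nGenes(model)`.
#' @return numeric vector of time derivatives, one per gene.
#' @export
modelRHS <- function(model, x) {
    stopifnot(is(model, "VohradskyModel"))
    if (length(x) != nGenes(model))
        stop(sprintf("state has length %d but the model has %d genes",
                     length(x), nGenes(model)))
    if (any(!is.finite(x))) stop("state must be finite")
    drop(model@k1 * sigmoidActivation(model@W %*% x + model@b) - model@k2 * x)
}

#' Simulate a Vohradsky model
#'
#' Integrates the ODE system from `x0` and samples it at `times`, using
#' the adaptive Dormand-Prince Runge-Kutta 4(5) pair.
#'
#' @param model a [VohradskyModel-class].
#' @param x0 nonnegative initial state, one value per gene.
#' @param times strictly increasing sampling times (the first entry is the
#'   initial time).
#' @param rtol,atol relative/absolute local error tolerances of the
#'   integrator.
#' @return A single-series [ExpressionTimecourses-class].
#' @examples
#' m <- smallScaleModel()
#' tc <- simulateModel(m, rep(0.5, 4), seq(0, 10, by = 2))
#' seriesValues(tc)[[1]]
#' @export
simulateModel <- function(model, x0, times, rtol = 1e-8, atol = 1e-10) {
    stopifnot(is(model, "VohradskyModel"))
    if (length(x0) != nGenes(model)) stop("x0 has the wrong length")
    if (any(x0 < 0)) stop("x0 must be nonnegative")
    if (is.unsorted(times, strictly = TRUE))
        stop("times must be strictly increasing")
    deriv <- function(t, x, parms) list(modelRHS(model, x))
    sol <- deSolve::ode(y = as.numeric(x0), times = as.numeric(times),
                        func = deriv, parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    vals <- unname(sol[, -1, drop = FALSE])
    bad <- which(!apply(vals, 1L, function(r) all(is.finite(r))))
    if (nrow(vals) < length(times) || length(bad) > 0) {
        tFail <- if (length(bad) > 0) times[bad[1]] else
            times[nrow(vals) + 1L]
        stop(sprintf("integration failed at t = %g (non-finite state)", tFail))
    }
    vals[vals < 0 & vals > -1e-8] <- 0  # integrator round-off only
    ExpressionTimecourses(times = as.numeric(times), values = vals,
                          geneNames = geneNames(model))
}

#' Exact model derivatives at sampled states
#'
#' Evaluates the model right-hand side at every sample of `data`, giving
#' noise-free time derivatives.  This mirrors the noise-free benchmark
#' setting in which derivatives are computed directly from the generating
#' model rather than estimated by smoothing.
#'
#' @param model a [VohradskyModel-class].
#' @param data an [ExpressionTimecourses-class] over the same genes.
#' @return A [DerivativeTimecourses-class] aligned with `data`.
#' @export
exactDerivatives <- function(model, data) {
    stopifnot(is(model, "VohradskyModel"), is(data, "Timecourses"))
    if (nGenes(model) != nGenes(data))
        stop("model and data disagree on the number of genes")
    dv <- lapply(data@values, function(v) {
        out <- v
        for (r in seq_len(nrow(v))) out[r, ] <- modelRHS(model, v[r, ])
        out
    })
    DerivativeTimecourses(times = data@times, values = dv,
                          geneNames = geneNames(data))
}
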