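# Logit linearization of the per-gene model equations and the sparse
# weight-estimation linear program.
#
# For candidate rates (k1, k2) of gene i, every sample t yields
#   y_t = (x'_{i,t} + k2 x_{i,t}) / k1,
# which under the model equals sigmoid(sum_j w_ij x_{j,t} + b_i).  Rows
# with y_t within [eps, 1-eps] are linearized as
#   z_t = logit(y_t) = sum_j w_ij x_{j,t} + b_i
# and the weights are estimated by the linear program
#   min sum_j |w_j| + theta * sum_t c_t xi_t
#   s.t. |z_t - (sum_j w_j x_{j,t} + b)| <= xi_t,  xi_t >= 0.
# The L1 term encodes the sparsity of genetic networks; c_t down-weights
# equations whose y_t is near 0 or 1, where the logit transform amplifies
# measurement noise by a factor 1/(y(1-y)).

# default per-equation weights: proportional to y(1-y), the reciprocal of
# the logit's noise amplification, normalized to max 1
.defaultEquationWeights <- function(y) {
    s <- y * (1 - y)
    s / max(s)
}

#' Build the logit-linearized equation system for one gene
#'
#' @param gene gene index (row of the model being estimated).
#' @param k1,k2 candidate synthesis/degradation rate constants, both > 0.
#' @param data an [ExpressionTimecourses-class].
#' @param derivs the aligned [DerivativeTimecourses-class].
#' @param eps validity threshold in (0, 0.5): samples with
#'   `y < eps` or `y > 1 - eps` are excluded from the linear program.
#' @param weightFun function mapping the valid `y` values to positive
#'   per-equation weights; the default is `y(1-y)` scaled to maximum 1.
#' @return A list of class `"TransformedSystem"` with elements `y`
#'   (length M), `valid` (logical mask), `z` (logits on valid rows), `X`
#'   (M-by-n regressor matrix), `c` (weights on valid rows), `gene`,
#'   `k1`, `k2`, `eps` and `status` (`"ok"`, or `"uninformative"` when
#'   fewer than 2 rows are valid).
#' @examples
#' fx <- smallScaleFixture(seed = 1)
#' sys <- buildTransformedSystem(2, 0.2, 0.2, fx$data, fx$derivatives)
#' range(sys$y)   # all inside (0, 1) at the true rates on noise-free data
#' @export
buildTransformedSystem <- function(gene, k1, k2, data, derivs, eps = 1e-5,
                                   weightFun = NULL) {
    stopifnot(k1 > 0, k2 > 0, eps > 0, eps < 0.5)
    X <- .stackValues(data)
    D <- .stackValues(derivs)
    if (!all(dim(X) == dim(D)))
        stop("data and derivative estimates are not aligned")
    .buildSystem(gene, k1, k2, X, D[, gene], X[, gene], eps, weightFun)
}

.buildSystem <- function(gene, k1, k2, X, xp, xi, eps, weightFun = NULL) {
    y <- (xp + k2 * xi) / k1
    valid <- is.finite(y) & y >= eps & y <= 1 - eps
    z <- cvals <- numeric(0)
    if (any(valid)) {
        z <- logit(y[valid])
        wf <- if (is.null(weightFun)) .defaultEquationWeights else weightFun
        cvals <- wf(y[valid])
        if (any(cvals <= 0)) stop("equation weights must be positive")
    }
    structure(list(y = y, valid = valid, z = z, X = X, c = cvals,
                   gene = gene, k1 = k1, k2 = k2, eps = eps,
                   status = if (sum(valid) < 2L) "uninformative" else "ok"),
              class = "TransformedSystem")
}

#' Solve the sparse weight-estimation linear program
#'
#' Minimizes `sum(abs(w)) + theta * sum(c * xi)` subject to
#' `|z_t - (x_t %*% w + b)| <= xi_t` over the valid rows of a transformed
#' system, by a Mehrotra predictor-corrector interior-point method on the
#' split-variable equality form (with a simplex fallback on numerical
#' failure).
#'
#' @param sys a `"TransformedSystem"` from [buildTransformedSystem()].
#' @param theta positive trade-off between the L1 sparsity term and the
#'   weighted residual term (large `theta` favours data fit over
#'   sparsity).
#' @param debugDump optional path: writes the assembled LP (split-variable
#'   constraint matrix, right-hand side `z` and cost vector) as a dense
#'   TSV for inspection.
#' @return list of class `"LPResult"`: `w` (length-n weights), `b`
#'   (bias), `slacks` (per-valid-row residual bounds), `lpObjective`
#'   (`sum(abs(w)) + theta * sum(c * slacks)` at the returned point) and
#'   `status` (`"solved"` or `"failed"`).
#' @export
solveWeightLP <- function(sys, theta = 2000, debugDump = NULL) {
    stopifnot(inherits(sys, "TransformedSystem"), theta > 0)
    if (sum(sys$valid) < 1L)
        stop("the transformed system has no valid rows")
    Xv <- sys$X[sys$valid, , drop = FALSE]
    n <- ncol(Xv)
    B <- cbind(Xv, -Xv, 1, -1)
    costB <- c(rep(1, 2L * n), 0, 0)
    costR <- theta * sys$c
    if (!is.null(debugDump)) {
        m <- nrow(B)
        A <- cbind(B, diag(m), -diag(m))
        colnames(A) <- c(paste0("w", seq_len(n), "+"),
                         paste0("w", seq_len(n), "-"), "b+", "b-",
                         paste0("r", seq_len(m), "+"),
                         paste0("r", seq_len(m), "-"))
        utils::write.table(cbind(rbind(c(costB, costR, costR), A),
                                 z = c(NA, sys$z)),
                           debugDump, sep = "\t", quote = FALSE,
                           row.names = c("cost", paste0("eq", seq_len(m))))
    }
    res <- .ladL1LP(B, sys$z, costB, costR, 1e-9, 100L)
    if (!identical(res$status, "solved")) {
        # on small systems the exact simplex is cheap, so prefer it over a
        # merely "acceptable" interior-point iterate; on large systems an
        # acceptable iterate (KKT quality < 1e-7) is kept and the simplex
        # reserved for outright failures
        if (nrow(B) <= 40L || !identical(res$status, "acceptable")) {
            sx <- .simplexLadLP(B, sys$z, costB, costR)
            if (identical(sx$status, "solved")) res <- sx
            else if (identical(res$status, "acceptable"))
                res$status <- "solved"
        } else {
            res$status <- "solved"
        }
    }
    if (is.null(res) || !identical(res$status, "solved"))
        return(structure(list(w = rep(NA_real_, n), b = NA_real_,
                              slacks = NULL, lpObjective = NA_real_,
                              status = "failed"),
                         class = "LPResult"))
    beta <- res$beta
    w <- beta[seq_len(n)] - beta[n + seq_len(n)]
    b <- beta[2L * n + 1L] - beta[2L * n + 2L]
    slacks <- res$rplus + res$rminus
    structure(list(w = w, b = b, slacks = slacks,
                   lpObjective = sum(abs(w)) + theta * sum(sys$c * slacks),
                   status = "solved"),
              class = "LPResult")
}

# core of the outer objective, working on pre-extracted matrices so the
# evolutionary search avoids repeated S4 access
.outerObjectiveCore <- function(gene, k1, k2, X, xp, xi, eps, theta,
                                penalty, weightFun = NULL) {
    sys <- .buildSystem(gene, k1, k2, X, xp, xi, eps, weightFun)
    if (sys$status == "uninformative")
        return(list(value = penalty, lp = NULL, system = sys))
    lp <- solveWeightLP(sys, theta)
    if (lp$status != "solved")
        return(list(value = penalty, lp = lp, system = sys))
    pred <- k1 * sigmoidActivation(drop(X %*% lp$w) + lp$b) - k2 * xi
    list(value = sum((xp - pred)^2), lp = lp, system = sys)
}

#' Outer (least-squares) objective for one gene at fixed rates
#'
#' Solves the weight-estimation LP at the candidate `(k1, k2)` and returns
#' the sum over *all* M samples (valid or not) of the squared
#' original-scale residuals
#' \eqn{[x'_{i,t} - k_1\sigma(\hat w \cdot x_t + \hat b) + k_2 x_{i,t}]^2}.
#' Evaluating the residuals on every sample prevents the search from
#' gaming the objective by driving rows out of the valid set.
#'
#' @inheritParams buildTransformedSystem
#' @param theta LP trade-off parameter, see [solveWeightLP()].
#' @param penalty large finite value returned when the system is
#'   uninformative (fewer than 2 valid rows) or the LP fails, so the
#'   outer search can proceed.
#' @return list with `value` (the objective) and `lp` (the inner
#'   `"LPResult"`, or `NULL` on the penalty branch).
#' @examples
#' fx <- smallScaleFixture(seed = 1)
#' outerObjective(4, 0.2, 0.2, fx$data, fx$derivatives)$value  # ~ 0
#' @export
outerObjective <- function(gene, k1, k2, data, derivs, eps = 1e-5,
                           theta = 2000, penalty = 1e12, weightFun = NULL) {
    stopifnot(k1 > 0, k2 > 0)
    X <- .stackValues(data)
    D <- .stackValues(derivs)
    out <- .outerObjectiveCore(gene, k1, k2, X, D[, gene], X[, gene],
                               eps, theta, penalty, weightFun)
    out[c("value", "lp")]
}
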