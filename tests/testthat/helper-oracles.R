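# Independent oracles used to cross-check the estimation machinery.

# Brute-force LP oracle: enumerate all basic feasible solutions of
#   min c'x  s.t.  [B | I | -I] x = z,  x >= 0
# and return the best objective.  Exponential in size, usable only for
# tiny instances; it shares no code with the interior-point or simplex
# solvers it checks.
oracleLadLP <- function(B, z, costB, costR) {
    m <- nrow(B)
    A <- cbind(B, diag(m), -diag(m))
    cc <- c(costB, costR, costR)
    N <- ncol(A)
    best <- Inf
    for (cols in utils::combn(N, m, simplify = FALSE)) {
        Ab <- A[, cols, drop = FALSE]
        if (rcond(Ab) < 1e-8) next  # near-singular basis: unreliable
        xb <- tryCatch(solve(Ab, z), error = function(e) NULL)
        if (is.null(xb) || any(!is.finite(xb)) || any(xb < -1e-9)) next
        if (max(abs(Ab %*% pmax(xb, 0) - z)) > 1e-8) next
        obj <- sum(cc[cols] * pmax(xb, 0))
        if (obj < best) best <- obj
    }
    best
}

# random tiny transformed system with modest scales (keeps LP objective
# O(1), so absolute comparisons at 1e-8 are meaningful)
randomTinySystem <- function(n, m) {
    X <- matrix(runif(m * n), m, n)
    y <- runif(m, 0.05, 0.95)
    structure(list(y = y, valid = rep(TRUE, m), z = log(y / (1 - y)),
                   X = X, c = runif(m, 0.2, 1), gene = 1L,
                   k1 = 1, k2 = 1, eps = 1e-5, status = "ok"),
              class = "TransformedSystem")
}

# brute-force sorted-tail penalty (independent of the implementation)
oracleTailPenalty <- function(w, I) {
    a <- rev(sort(abs(w)))
    if (I >= length(a)) return(0)
    sum(a[seq.int(I + 1L, length(a))])
}

# an identifiable noise-free generated instance.  Random sparse networks
# often contain silent genes (sigmoid input saturated over every reachable
# state) or barely excited dynamics; no estimator can recover such genes
# from observational data.  The screen requires every gene's valid
# transformed design [X, 1] to be well conditioned at the true rates
# (persistent excitation): smallest singular value >= svMin.
screenedInstance <- function(baseSeed, n = 4L, nSeries = 5L, svMin = 0.3,
                             maxTries = 30L) {
    for (k in seq_len(maxTries)) {
        sd <- baseSeed + (k - 1L)
        m <- generateNetwork(n, indegreeCutoff = min(5L, n), seed = sd)
        tc <- generateTimecourses(m, nSeries = nSeries, nTimepoints = 11L,
                                  noiseFraction = 0, seed = sd + 50L)
        dv <- exactDerivatives(m, tc$clean)
        sv <- vapply(seq_len(n), function(g) {
            sys <- buildTransformedSystem(g, kSyn(m)[g], kDeg(m)[g],
                                          tc$clean, dv)
            Xv <- sys$X[sys$valid, , drop = FALSE]
            if (nrow(Xv) < n + 2L) return(0)
            min(svd(cbind(Xv, rep(1, nrow(Xv))))$d)
        }, 0)
        if (all(sv >= svMin))
            return(list(model = m, data = tc$clean, derivatives = dv,
                        seed = sd))
    }
    NULL
}
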