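# Least-squares comparison estimator: direct minimization of the per-gene
# sum of squared residuals plus a sorted-weight sparsity penalty, over all
# n+3 parameters (w row, bias, log k1, log k2) with the same REX/JGG
# optimizer.

# penalty on the weights ranked below the top-I magnitudes
.sortedTailPenalty <- function(w, maxIndegree) {
    a <- sort(abs(w), decreasing = TRUE)
    if (maxIndegree >= length(a)) 0
    else sum(a[(maxIndegree + 1L):length(a)])
}

#' Penalized least-squares objective for one gene
#'
#' Computes
#' \deqn{\sum_t [x'_{i,t} - k_1\sigma(w\cdot x_t + b) + k_2 x_{i,t}]^2
#'       + c \sum_{j > I} |w_{(j)}|,}
#' where \eqn{w_{(1)}, \dots, w_{(n)}} are the weights sorted by
#' descending absolute value and \eqn{I} is the maximum in-degree: only
#' the `maxIndegree` largest-magnitude weights escape the sparsity
#' penalty.
#'
#' @param gene gene index.
#' @param params numeric vector `c(w (length n), b, k1, k2)` with
#'   `k1, k2 > 0`.
#' @param data an [ExpressionTimecourses-class].
#' @param derivs the aligned [DerivativeTimecourses-class].
#' @param maxIndegree maximum number of unpenalized regulators, `0..n`.
#' @param penaltyWeight nonnegative penalty coefficient `c`.
#' @return nonnegative scalar objective value.
#' @export
lsObjective <- function(gene, params, data, derivs, maxIndegree = 5L,
                        penaltyWeight = 1) {
    X <- .stackValues(data)
    D <- .stackValues(derivs)
    n <- ncol(X)
    stopifnot(length(params) == n + 3L, penaltyWeight >= 0,
              maxIndegree >= 0, maxIndegree <= n)
    .lsObjectiveCore(params, X, D[, gene], X[, gene], maxIndegree,
                     penaltyWeight)
}

.lsObjectiveCore <- function(params, X, xp, xi, maxIndegree, penaltyWeight) {
    n <- ncol(X)
    w <- params[seq_len(n)]
    b <- params[n + 1L]
    k1 <- params[n + 2L]
    k2 <- params[n + 3L]
    if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be positive")
    pred <- k1 * sigmoidActivation(drop(X %*% w) + b) - k2 * xi
    sum((xp - pred)^2) + penaltyWeight * .sortedTailPenalty(w, maxIndegree)
}

#' Default REX/JGG settings for the (n+3)-dimensional least-squares search
#'
#' Scales the optimizer with the search dimension `D = n + 3`: population
#' `15 D`, `D + 1` parents, `8 D` children, step `1/sqrt(D)`, stall window
#' 150 generations.
#'
#' @param n number of genes.
#' @param seed optional integer seed.
#' @param maxGenerations generation cap.
#' @return A [rexControl()] list.
#' @export
lsControl <- function(n, seed = NULL, maxGenerations = 1000L) {
    D <- n + 3L
    rexControl(populationSize = 15L * D, nParents = D + 1L,
               nChildren = 8L * D, stepSize = 1 / sqrt(D),
               maxGenerations = maxGenerations, stallGenerations = 150L,
               seed = seed)
}

#' Least-squares estimation of one gene's parameters
#'
#' Minimizes [lsObjective()] by REX/JGG over all `n + 3` parameters of
#' gene `gene`: the weight row and bias in linear space (bounds
#' `weightBounds`), the rate constants in log10 space (bounds
#' `rateBounds`).
#'
#' @inheritParams lsObjective
#' @param weightBounds linear-space search interval for every weight and
#'   the bias.
#' @param rateBounds log10-space search interval for `k1` and `k2`.
#' @param control a [rexControl()]; defaults to [lsControl()] for the
#'   problem dimension.
#' @param successThreshold objective value below which `success` is set.
#' @return list of class `"SubproblemResult"` (same contract as
#'   [solveGene()]).
#' @export
solveGeneLS <- function(gene, data, derivs, maxIndegree = 5L,
                        penaltyWeight = 1, weightBounds = c(-30, 30),
                        rateBounds = c(-2, 2), control = NULL,
                        successThreshold = 1e-6) {
    X <- .stackValues(data)
    D <- .stackValues(derivs)
    n <- ncol(X)
    stopifnot(maxIndegree >= 0, maxIndegree <= n, penaltyWeight >= 0)
    if (is.null(control)) control <- lsControl(n)
    if (is.null(control$targetValue))
        control$targetValue <- successThreshold / 100
    xp <- D[, gene]
    xi <- X[, gene]
    lower <- c(rep(weightBounds[1L], n + 1L), rep(rateBounds[1L], 2L))
    upper <- c(rep(weightBounds[2L], n + 1L), rep(rateBounds[2L], 2L))

    f <- function(u)
        .lsObjectiveCore(c(u[seq_len(n + 1L)], 10^u[n + 2L], 10^u[n + 3L]),
                         X, xp, xi, maxIndegree, penaltyWeight)
    opt <- rexJGGMinimize(f, lower, upper, control)
    structure(list(gene = gene, w = opt$par[seq_len(n)],
                   b = opt$par[n + 1L],
                   k1 = 10^opt$par[n + 2L], k2 = 10^opt$par[n + 3L],
                   objective = opt$value,
                   generationsUsed = opt$generations,
                   evaluations = opt$evaluations,
                   success = is.finite(opt$value) &&
                       opt$value < successThreshold,
                   lpStatus = NA_character_),
              class = "SubproblemResult")
}

#' Infer a network with the least-squares estimator
#'
#' Runs [solveGeneLS()] per gene with derived seeds and assembles a
#' [VohradskyModel-class]; the comparison baseline for [inferNetwork()].
#'
#' @inheritParams solveGeneLS
#' @param seed integer base seed (gene `i` uses `seed + i`).
#' @return list of class `"NetworkInference"`.
#' @export
inferNetworkLS <- function(data, derivs, maxIndegree = 5L, penaltyWeight = 1,
                           weightBounds = c(-30, 30), rateBounds = c(-2, 2),
                           control = NULL, successThreshold = 1e-6,
                           seed = NULL) {
    n <- nGenes(data)
    if (is.null(seed)) seed <- sample.int(2^30, 1L)
    if (is.null(control)) control <- lsControl(n)
    results <- vector("list", n)
    for (g in seq_len(n)) {
        ctl <- control
        ctl$seed <- seed + g
        results[[g]] <- solveGeneLS(g, data, derivs,
                                    maxIndegree = maxIndegree,
                                    penaltyWeight = penaltyWeight,
                                    weightBounds = weightBounds,
                                    rateBounds = rateBounds, control = ctl,
                                    successThreshold = successThreshold)
    }
    model <- VohradskyModel(W = do.call(rbind, lapply(results, `[[`, "w")),
                            b = vapply(results, `[[`, numeric(1), "b"),
                            k1 = vapply(results, `[[`, numeric(1), "k1"),
                            k2 = vapply(results, `[[`, numeric(1), "k2"),
                            geneNames = geneNames(data))
    structure(list(model = model, results = results, seed = seed),
              class = "NetworkInference")
}
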