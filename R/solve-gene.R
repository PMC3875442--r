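# Per-gene two-dimensional estimation: REX/JGG search over
# (log10 k1, log10 k2) with the weight-estimation LP solved inside every
# objective evaluation, and assembly of the full network model.

.expandBounds <- function(bounds) {
    if (is.matrix(bounds)) {
        stopifnot(nrow(bounds) == 2L, ncol(bounds) == 2L)
        return(bounds)
    }
    stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
    rbind(bounds, bounds)
}

#' Estimate the model parameters of one gene
#'
#' Minimizes the outer least-squares objective over
#' \eqn{(\log_{10} k_1, \log_{10} k_2)} with [rexJGGMinimize()], solving
#' the sparse-weight LP inside every evaluation, then re-solves the LP at
#' the optimum to produce the final weight row and bias.
#'
#' @inheritParams outerObjective
#' @param bounds search box in log10 space: either `c(low, high)` applied
#'   to both rates or a 2-by-2 matrix with one row per dimension.
#' @param control a [rexControl()]; the defaults (population 30, 3
#'   parents, 10 children, step `1/sqrt(2)`, 200 generations, stall 50)
#'   suit the 2-D search.
#' @param successThreshold objective value below which the subproblem is
#'   flagged successful (`1e-6` suits noise-free data; noisy fits reach
#'   values on the scale of `M` times the noise variance).
#' @return list of class `"SubproblemResult"`: `gene`, `w`, `b`, `k1`,
#'   `k2`, `objective`, `generationsUsed`, `evaluations`, `success`,
#'   `lpStatus`.
#' @examples
#' fx <- smallScaleFixture(seed = 1)
#' res <- solveGene(2, fx$data, fx$derivatives,
#'                  control = rexControl(seed = 7))
#' round(c(res$w, res$b, res$k1, res$k2), 3)
#' @export
solveGene <- function(gene, data, derivs, eps = 1e-5, theta = 2000,
                      bounds = c(-2, 2), control = rexControl(),
                      successThreshold = 1e-6, penalty = 1e12,
                      weightFun = NULL) {
    stopifnot(is(data, "Timecourses"), is(derivs, "Timecourses"))
    X <- .stackValues(data)
    D <- .stackValues(derivs)
    if (!all(dim(X) == dim(D)))
        stop("data and derivative estimates are not aligned")
    xp <- D[, gene]
    xi <- X[, gene]
    bd <- .expandBounds(bounds)

    if (is.null(control$targetValue))
        control$targetValue <- successThreshold / 100
    f <- function(u)
        .outerObjectiveCore(gene, 10^u[1L], 10^u[2L], X, xp, xi, eps,
                            theta, penalty, weightFun)$value
    opt <- rexJGGMinimize(f, bd[, 1L], bd[, 2L], control)

    k1 <- 10^opt$par[1L]
    k2 <- 10^opt$par[2L]
    fin <- .outerObjectiveCore(gene, k1, k2, X, xp, xi, eps, theta,
                               penalty, weightFun)
    w <- if (is.null(fin$lp)) rep(NA_real_, ncol(X)) else fin$lp$w
    b <- if (is.null(fin$lp)) NA_real_ else fin$lp$b
    structure(list(gene = gene, w = w, b = b, k1 = k1, k2 = k2,
                   objective = fin$value,
                   generationsUsed = opt$generations,
                   evaluations = opt$evaluations,
                   success = is.finite(fin$value) &&
                       fin$value < successThreshold,
                   lpStatus = if (is.null(fin$lp)) "uninformative"
                              else fin$lp$status),
              class = "SubproblemResult")
}

#' @export
print.SubproblemResult <- function(x, ...) {
    cat(sprintf("Gene %d subproblem: objective %.3e (%s) after %d generations\n",
                x$gene, x$objective,
                if (x$success) "success" else "not converged",
                x$generationsUsed))
    cat(sprintf("  k1 = %.4g, k2 = %.4g, b = %.4g\n", x$k1, x$k2, x$b))
    cat("  w =", paste(sprintf("%.4g", x$w), collapse = ", "), "\n")
    invisible(x)
}

#' Infer a full Vohradsky network model
#'
#' Runs [solveGene()] independently for every gene (each with its own
#' seed derived from `seed`, so results do not depend on execution order)
#' and assembles the estimated rows into a [VohradskyModel-class].
#'
#' @inheritParams solveGene
#' @param seed integer base seed; gene `i` uses `seed + i`.  Drawn from
#'   the session RNG when `NULL`.
#' @return list of class `"NetworkInference"` with elements `model` (the
#'   assembled [VohradskyModel-class]) and `results` (per-gene
#'   `"SubproblemResult"` lists).
#' @examples
#' \donttest{
#' fx <- smallScaleFixture(seed = 1)
#' fit <- inferNetwork(fx$data, fx$derivatives, seed = 1)
#' regWeights(fit$model)
#' }
#' @export
inferNetwork <- function(data, derivs, eps = 1e-5, theta = 2000,
                         bounds = c(-2, 2), control = rexControl(),
                         successThreshold = 1e-6, penalty = 1e12,
                         weightFun = NULL, seed = NULL) {
    n <- nGenes(data)
    if (is.null(seed)) seed <- sample.int(2^30, 1L)
    results <- vector("list", n)
    for (g in seq_len(n)) {
        ctl <- control
        ctl$seed <- seed + g
        results[[g]] <- solveGene(g, data, derivs, eps = eps, theta = theta,
                                  bounds = bounds, control = ctl,
                                  successThreshold = successThreshold,
                                  penalty = penalty, weightFun = weightFun)
    }
    W <- do.call(rbind, lapply(results, `[[`, "w"))
    W[!is.finite(W)] <- 0  # genes whose LP never solved contribute no edges
    b <- vapply(results, `[[`, numeric(1), "b")
    b[!is.finite(b)] <- 0
    model <- VohradskyModel(W = W, b = b,
                            k1 = vapply(results, `[[`, numeric(1), "k1"),
                            k2 = vapply(results, `[[`, numeric(1), "k2"),
                            geneNames = geneNames(data))
    structure(list(model = model, results = results, seed = seed),
              class = "NetworkInference")
}

#' @export
print.NetworkInference <- function(x, ...) {
    ok <- vapply(x$results, `[[`, logical(1), "success")
    cat(sprintf("NetworkInference: %d genes, %d subproblems below the success threshold\n",
                length(ok), sum(ok)))
    show(x$model)
    invisible(x)
}
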