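# Real-coded ensemble crossover (REX) within the Just Generation Gap (JGG)
# generational scheme: a derivative-free evolutionary minimizer.  Each
# generation draws parents uniformly from the population, generates
# children around the parent centroid with normally distributed ensemble
# coefficients, and writes the best children back over the parents.
#
# A JGG population eventually collapses around an incumbent, which on
# narrow curved valleys (exactly the shape of the outer rate-estimation
# objective) can happen short of the optimum.  The minimizer therefore
# restarts on stall, alternating two moves: a zoom round re-initializes
# the population in a box around the best point whose width shrinks by a
# fixed factor, and an exploration round re-initializes over the full
# search box (in case the incumbent sits in a spurious basin).  The
# incumbent is always injected into the new population.  This keeps the
# plain REX/JGG generation loop intact while recovering the deep
# convergence the original algorithm's elitist variants aim for.

#' Optimizer settings for the REX/JGG minimizer
#'
#' @param populationSize number of individuals kept in the population.
#' @param nParents parents drawn (without replacement) per generation;
#'   must be at least `dimension + 1` for the crossover to span the
#'   search space.
#' @param nChildren children generated per generation.
#' @param stepSize standard deviation of the ensemble coefficients; the
#'   standard REX scaling is `1/sqrt(nParents - 1)`.
#' @param maxGenerations generation cap per restart round.
#' @param stallGenerations a round ends when the best-ever value has not
#'   improved for this many consecutive generations.
#' @param restarts stall-triggered restarts after the first round,
#'   alternating between re-exploration over the full bounds and a zoom
#'   into a box around the incumbent.
#' @param shrink factor by which the zoom box width shrinks per zoom
#'   restart (relative to the previous box).
#' @param targetValue stop as soon as the best value falls below this
#'   (`NULL`: never stop early).
#' @param seed optional integer seed making the run reproducible.
#' @return list of class `"rexControl"`.
#' @export
rexControl <- function(populationSize = 30L, nParents = 3L, nChildren = 10L,
                       stepSize = 1 / sqrt(2), maxGenerations = 200L,
                       stallGenerations = 50L, restarts = 10L, shrink = 0.2,
                       targetValue = NULL, seed = NULL) {
    ctl <- list(populationSize = as.integer(populationSize),
                nParents = as.integer(nParents),
                nChildren = as.integer(nChildren),
                stepSize = stepSize,
                maxGenerations = as.integer(maxGenerations),
                stallGenerations = as.integer(stallGenerations),
                restarts = as.integer(restarts),
                shrink = shrink,
                targetValue = targetValue,
                seed = seed)
    stopifnot(ctl$populationSize >= ctl$nParents, ctl$nParents >= 2L,
              ctl$nChildren >= 1L, ctl$stepSize > 0,
              ctl$maxGenerations >= 1L, ctl$stallGenerations >= 1L,
              ctl$restarts >= 0L, ctl$shrink > 0, ctl$shrink < 1)
    class(ctl) <- "rexControl"
    ctl
}

#' Minimize a function with REX crossover under JGG selection
#'
#' @param f objective taking a numeric vector and returning a scalar;
#'   non-finite returns are treated as `+Inf` (penalty convention).
#' @param lower,upper per-dimension search bounds.
#' @param control a [rexControl()] list; `nParents` must exceed the
#'   dimension.
#' @return list with `par` (best point found), `value` (its objective),
#'   `trace` (per-generation best-ever value across all restart rounds,
#'   non-increasing), `generations` (total), `restartsUsed` and
#'   `evaluations`.
#' @examples
#' sphere <- function(u) sum(u^2)
#' rexJGGMinimize(sphere, c(-5, -5), c(5, 5),
#'                rexControl(seed = 1))$value
#' @export
rexJGGMinimize <- function(f, lower, upper, control = rexControl()) {
    d <- length(lower)
    stopifnot(length(upper) == d, all(lower < upper),
              inherits(control, "rexControl"))
    if (control$nParents < d + 1L)
        stop("nParents must be at least dimension + 1")
    if (!is.null(control$seed)) set.seed(control$seed)
    target <- if (is.null(control$targetValue)) -Inf else control$targetValue

    evalSafe <- function(x) {
        v <- f(x)
        if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
    }
    P <- control$populationSize
    np <- control$nParents
    bestPar <- NULL
    bestVal <- Inf
    trace <- numeric(0)
    nEval <- 0L
    totGen <- 0L
    lo <- lower
    hi <- upper
    zoomWidth <- upper - lower  # compounds across zoom rounds only
    restartsUsed <- 0L

    for (round in 0:control$restarts) {
        pop <- matrix(runif(P * d, rep(lo, each = P), rep(hi, each = P)),
                      nrow = P)
        if (!is.null(bestPar)) pop[1L, ] <- bestPar  # keep the incumbent
        popVal <- apply(pop, 1L, evalSafe)
        nEval <- nEval + P
        if (min(popVal) < bestVal) {
            bestVal <- min(popVal)
            bestPar <- pop[which.min(popVal), ]
        }
        stall <- 0L
        for (gen in seq_len(control$maxGenerations)) {
            totGen <- totGen + 1L
            idx <- sample.int(P, np)
            parents <- pop[idx, , drop = FALSE]
            centroid <- colMeans(parents)
            dev <- sweep(parents, 2L, centroid)

            children <- matrix(0, control$nChildren, d)
            for (k in seq_len(control$nChildren)) {
                for (try in seq_len(10L)) {
                    xi <- rnorm(np, 0, control$stepSize)
                    child <- centroid + drop(crossprod(dev, xi))
                    if (all(child >= lower & child <= upper)) break
                }
                children[k, ] <- pmin(pmax(child, lower), upper)
            }
            childVal <- apply(children, 1L, evalSafe)
            nEval <- nEval + control$nChildren

            ord <- order(childVal)[seq_len(np)]
            pop[idx, ] <- children[ord, , drop = FALSE]
            popVal[idx] <- childVal[ord]

            if (childVal[ord[1L]] < bestVal) {
                bestVal <- childVal[ord[1L]]
                bestPar <- children[ord[1L], ]
                stall <- 0L
            } else {
                stall <- stall + 1L
            }
            trace <- c(trace, bestVal)
            if (stall >= control$stallGenerations || bestVal < target) break
        }
        if (bestVal < target || round == control$restarts) break
        restartsUsed <- restartsUsed + 1L
        if (round %% 2L == 0L) {
            # zoom: polish the incumbent in a box that keeps shrinking
            # geometrically across zoom rounds
            zoomWidth <- zoomWidth * control$shrink
            lo <- pmax(lower, bestPar - zoomWidth / 2)
            hi <- pmin(upper, bestPar + zoomWidth / 2)
        } else {
            # re-explore: fresh population over the full search box, in
            # case the incumbent sits in a spurious basin
            lo <- lower
            hi <- upper
        }
    }
    list(par = bestPar, value = bestVal, trace = trace,
         generations = totGen, restartsUsed = restartsUsed,
         evaluations = nEval)
}
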