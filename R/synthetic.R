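# Synthetic benchmark generator: random sparse Vohradsky networks with
# power-law in-degrees, multi-series time courses from random initial
# states, and multiplicative Gaussian measurement noise.

#' Sample in-degrees from a truncated power law
#'
#' Draws from `P(k) proportional to k^(-exponent)` on `1..cutoff`.
#'
#' @param nDraws number of draws.
#' @param cutoff maximum in-degree (the benchmark uses 5).
#' @param exponent power-law exponent (> 0).
#' @return integer vector of in-degrees in `1..cutoff`.
#' @export
sampleIndegree <- function(nDraws = 1L, cutoff = 5L, exponent = 2) {
    stopifnot(cutoff >= 1L, exponent > 0)
    if (cutoff == 1L) return(rep(1L, nDraws))
    sample.int(cutoff, nDraws, replace = TRUE,
               prob = (seq_len(cutoff))^(-exponent))
}

#' Generate a random sparse Vohradsky network
#'
#' Per gene, an in-degree is drawn from the truncated power law, that
#' many distinct regulators are chosen uniformly, and their weights get
#' magnitudes uniform in `weightRange` with random signs; all other
#' weights are zero.  Biases are uniform in `biasRange` and synthesis
#' rates uniform in `rateRange`.  By default `k2 = k1` per gene, which
#' keeps every steady state at or below 1 so trajectories stay on the
#' normalized expression scale.
#'
#' @param n number of genes.
#' @param indegreeCutoff maximum in-degree (benchmark: 5).
#' @param exponent power-law exponent for the in-degree distribution.
#' @param weightRange magnitude range for nonzero weights.
#' @param biasRange range of the bias terms.
#' @param rateRange range of the synthesis rates `k1`.
#' @param k2Mode `"equal"` sets `k2 = k1`; `"independent"` draws `k2`
#'   from `rateRange` as well.
#' @param seed optional integer seed.
#' @return A [VohradskyModel-class].
#' @examples
#' m <- generateNetwork(10, seed = 1)
#' rowSums(regWeights(m) != 0)   # in-degrees, all within 1..5
#' @export
generateNetwork <- function(n, indegreeCutoff = 5L, exponent = 2,
                            weightRange = c(5, 20), biasRange = c(-10, 10),
                            rateRange = c(0.1, 1.0),
                            k2Mode = c("equal", "independent"),
                            seed = NULL) {
    stopifnot(n >= 1L, indegreeCutoff <= n)
    k2Mode <- match.arg(k2Mode)
    if (!is.null(seed)) set.seed(seed)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
        k <- sampleIndegree(1L, indegreeCutoff, exponent)
        reg <- sample.int(n, k)
        W[i, reg] <- runif(k, weightRange[1], weightRange[2]) *
            sample(c(-1, 1), k, replace = TRUE)
    }
    k1 <- runif(n, rateRange[1], rateRange[2])
    k2 <- if (k2Mode == "equal") k1 else runif(n, rateRange[1], rateRange[2])
    VohradskyModel(W = W, b = runif(n, biasRange[1], biasRange[2]),
                   k1 = k1, k2 = k2)
}

#' Generate clean and noisy benchmark time courses
#'
#' Simulates `nSeries` trajectories from initial states uniform in
#' `x0Range`, sampled at `nTimepoints` equally spaced times on
#' `[0, tMax]`, and adds relative Gaussian measurement noise: the noisy
#' value is `clean * (1 + rnorm(0, noiseFraction))`, floored at 0.
#'
#' @param model a [VohradskyModel-class].
#' @param nSeries number of time series (experimental conditions).
#' @param nTimepoints samples per series (benchmark: 11).
#' @param tMax time horizon.
#' @param noiseFraction relative noise level (benchmark: 0.10 for "10%
#'   Gaussian noise"); 0 gives noisy identical to clean.
#' @param x0Range range of the uniform initial states.
#' @param seed optional integer seed.
#' @return list with `clean` and `noisy` [ExpressionTimecourses-class]
#'   objects (each with `nSeries * nTimepoints` samples).
#' @export
generateTimecourses <- function(model, nSeries = 10L, nTimepoints = 11L,
                                tMax = 10, noiseFraction = 0.1,
                                x0Range = c(0, 1), seed = NULL) {
    stopifnot(nTimepoints >= 2L, noiseFraction >= 0, tMax > 0)
    if (!is.null(seed)) set.seed(seed)
    n <- nGenes(model)
    times <- seq(0, tMax, length.out = nTimepoints)
    clean <- vector("list", nSeries)
    for (s in seq_len(nSeries)) {
        x0 <- runif(n, x0Range[1], x0Range[2])
        clean[[s]] <- simulateModel(model, x0, times)
    }
    clean <- .combineTimecourses(clean)
    noisy <- lapply(clean@values, function(v)
        pmax(v * (1 + matrix(rnorm(length(v), 0, noiseFraction),
                             nrow(v), ncol(v))), 0))
    list(clean = clean,
         noisy = ExpressionTimecourses(clean@times, noisy,
                                       geneNames(model)))
}

#' The 4-gene small-scale reference model
#'
#' The classic 4-gene Vohradsky system used as the small-scale inference
#' benchmark.  Row i of the weight matrix lists the regulations acting on
#' gene i; the bias vector and the two rate-constant vectors complete the
#' parameter set.  A copy in the tabular parameter format ships as
#' `system.file("extdata", "small_scale_model.tsv", package = "sigmoidGRN")`.
#'
#' @return A [VohradskyModel-class] with 4 genes.
#' @examples
#' regWeights(smallScaleModel())
#' @export
smallScaleModel <- function() {
    W <- rbind(c(20, -20, 0, 0),
               c(15, -10, 0, 0),
               c(0, -8, 12, 0),
               c(0, 0, 8, -12))
    VohradskyModel(W = W, b = c(0, -5, 0, 0),
                   k1 = c(0.1, 0.2, 0.2, 0.2),
                   k2 = c(0.1, 0.2, 0.2, 0.2))
}

#' Noise-free small-scale benchmark instance
#'
#' Builds the [smallScaleModel()], simulates `nSeries` noise-free series
#' from initial states uniform in `[0, 1]`, and computes exact
#' derivatives from the model right-hand side — the noise-free setting in
#' which parameter recovery is judged.
#'
#' @param pointsPerSeries samples per series (equally spaced on
#'   `[0, tMax]`).
#' @param nSeries number of series.
#' @param tMax time horizon of each series.
#' @param seed optional integer seed for the random initial states.
#' @return list with `model`, `data` (an
#'   [ExpressionTimecourses-class] with `nSeries * pointsPerSeries`
#'   samples) and `derivatives` (exact [DerivativeTimecourses-class]).
#' @export
smallScaleFixture <- function(pointsPerSeries = 5L, nSeries = 3L, tMax = 10,
                              seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    model <- smallScaleModel()
    times <- seq(0, tMax, length.out = pointsPerSeries)
    series <- lapply(seq_len(nSeries), function(s)
        simulateModel(model, runif(4), times))
    data <- .combineTimecourses(series)
    list(model = model, data = data,
         derivatives = exactDerivatives(model, data))
}
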