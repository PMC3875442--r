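#' Vohradsky sigmoid ODE model of a genetic network
#'
#' Holds the full parameter set of an \eqn{n}-gene network under the model
#' \eqn{dx_i/dt = k_{1,i}\sigma(\sum_j w_{ij} x_j + b_i) - k_{2,i} x_i}.
#' Row \eqn{i} of the weight matrix collects the regulations acting on gene
#' \eqn{i}; \eqn{w_{ij} > 0} is activation of gene \eqn{i} by gene \eqn{j},
#' \eqn{w_{ij} < 0} repression, and \eqn{w_{ij} = 0} no regulation.
#'
#' @slot W n-by-n numeric matrix of regulatory weights (unitless).
#' @slot b length-n numeric vector of bias terms.
#' @slot k1 length-n vector of maximal synthesis rates (expression/time,
#'   strictly positive).
#' @slot k2 length-n vector of first-order degradation rate constants
#'   (1/time, strictly positive).
#' @slot geneNames length-n character vector of gene identifiers.
#'
#' @seealso [simulateModel()], [inferNetwork()], [readModelTable()]
#' @export
setClass("VohradskyModel",
    representation(W = "matrix", b = "numeric", k1 = "numeric",
                   k2 = "numeric", geneNames = "character"),
    validity = function(object) {
        n <- nrow(object@W)
        if (n < 1L) return("model must contain at least one gene")
        if (ncol(object@W) != n) return("W must be square")
        if (length(object@b) != n) return("length(b) must equal nrow(W)")
        if (length(object@k1) != n || length(object@k2) != n)
            return("k1 and k2 must have one entry per gene")
        if (length(object@geneNames) != n)
            return("geneNames must have one entry per gene")
        if (!all(is.finite(object@W)) || !all(is.finite(object@b)))
            return("W and b must be finite")
        if (!all(is.finite(object@k1)) || any(object@k1 <= 0))
            return("k1 must be finite and > 0")
        if (!all(is.finite(object@k2)) || any(object@k2 <= 0))
            return("k2 must be finite and > 0")
        TRUE
    })

#' Construct a VohradskyModel
#'
#' @param W n-by-n matrix of regulatory weights (row i: regulations of gene
#'   i by each gene j).
#' @param b length-n bias vector.
#' @param k1,k2 length-n vectors of synthesis and degradation rate
#'   constants; both must be strictly positive.
#' @param geneNames optional gene identifiers; defaults to `G1..Gn`.
#' @return A [VohradskyModel-class] object.
#' @examples
#' m <- VohradskyModel(W = matrix(c(2, -1, 0, 1), 2, 2, byrow = TRUE),
#'                     b = c(0, -1), k1 = c(0.5, 0.2), k2 = c(0.5, 0.2))
#' modelRHS(m, c(0.3, 0.7))
#' @export
VohradskyModel <- function(W, b, k1, k2,
                           geneNames = paste0("G", seq_len(nrow(W)))) {
    W <- as.matrix(W)
    dimnames(W) <- list(geneNames, geneNames)
    new("VohradskyModel", W = W, b = as.numeric(b), k1 = as.numeric(k1),
        k2 = as.numeric(k2), geneNames = as.character(geneNames))
}

.validTimecourses <- function(object) {
    ns <- length(object@times)
    if (length(object@values) != ns)
        return("times and values must have one entry per series")
    if (ns < 1L) return("at least one series is required")
    ngene <- length(object@geneNames)
    for (s in seq_len(ns)) {
        tt <- object@times[[s]]
        vv <- object@values[[s]]
        if (!is.matrix(vv) || ncol(vv) != ngene)
            return(sprintf("series %d: values must be a matrix with %d gene columns",
                           s, ngene))
        if (nrow(vv) != length(tt))
            return(sprintf("series %d: one row of values per time point required", s))
        if (!all(is.finite(tt)) || is.unsorted(tt, strictly = TRUE))
            return(sprintf("series %d: times must be finite and strictly increasing", s))
        if (!all(is.finite(vv)))
            return(sprintf("series %d: values must be finite", s))
    }
    TRUE
}

#' Multi-series time-course container
#'
#' Base class holding one or more sampled time series over a common gene
#' set.  [ExpressionTimecourses-class] adds the nonnegativity constraint of
#' expression levels; [DerivativeTimecourses-class] holds per-gene
#' time-derivative estimates aligned sample-by-sample with its source
#' expression object.
#'
#' @slot times list of strictly increasing numeric time vectors, one per
#'   series.
#' @slot values list of time-by-gene numeric matrices, one per series.
#' @slot geneNames character vector naming the gene columns (shared by all
#'   series).
#' @export
setClass("Timecourses",
    representation(times = "list", values = "list", geneNames = "character"),
    validity = .validTimecourses)

#' @rdname Timecourses-class
#' @export
setClass("ExpressionTimecourses", contains = "Timecourses",
    validity = function(object) {
        for (s in seq_along(object@values))
            if (any(object@values[[s]] < 0))
                return(sprintf("series %d: expression levels must be >= 0", s))
        TRUE
    })

#' @rdname Timecourses-class
#' @export
setClass("DerivativeTimecourses", contains = "Timecourses")

.makeTimecourses <- function(class, times, values, geneNames) {
    if (is.numeric(times)) times <- list(times)
    if (is.matrix(values)) values <- list(values)
    values <- lapply(values, function(v) {
        v <- as.matrix(v)
        dimnames(v) <- list(NULL, geneNames)
        v
    })
    new(class, times = lapply(times, as.numeric), values = values,
        geneNames = as.character(geneNames))
}

#' Construct expression / derivative time-course objects
#'
#' @param times a numeric time vector (single series) or a list of them.
#' @param values a time-by-gene matrix (single series) or a list of them.
#' @param geneNames gene identifiers for the value columns.
#' @return An [ExpressionTimecourses-class] or
#'   [DerivativeTimecourses-class] object.
#' @examples
#' tc <- ExpressionTimecourses(times = 0:3,
#'                             values = matrix(runif(8), 4, 2),
#'                             geneNames = c("A", "B"))
#' nSamples(tc)
#' @export
ExpressionTimecourses <- function(times, values, geneNames = NULL) {
    .makeTimecourses("ExpressionTimecourses", times, values,
                     geneNames %||% .defaultGeneNames(values))
}

#' @rdname ExpressionTimecourses
#' @export
DerivativeTimecourses <- function(times, values, geneNames = NULL) {
    .makeTimecourses("DerivativeTimecourses", times, values,
                     geneNames %||% .defaultGeneNames(values))
}

.defaultGeneNames <- function(values) {
    v <- as.matrix(if (is.list(values)) values[[1]] else values)
    colnames(v) %||% paste0("G", seq_len(ncol(v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed regulation network
#'
#' An n-by-n matrix over \{-1, 0, +1\}: entry (i, j) is the sign of the
#' inferred (or true) regulation of gene i by gene j.  When `includeSelf`
#' is `FALSE` the diagonal is forced to zero and self-regulations are not
#' scored.
#'
#' @slot signs integer matrix with entries in \{-1, 0, 1\}.
#' @slot includeSelf logical; whether the diagonal carries information.
#' @export
setClass("SignedNetwork",
    representation(signs = "matrix", includeSelf = "logical"),
    validity = function(object) {
        A <- object@signs
        if (nrow(A) != ncol(A)) return("signs must be square")
        if (!all(A %in% c(-1, 0, 1))) return("entries must be in {-1, 0, 1}")
        if (!object@includeSelf && any(diag(A) != 0))
            return("diagonal must be zero when includeSelf is FALSE")
        TRUE
    })

#' Construct a SignedNetwork
#'
#' @param signs square matrix with entries in \{-1, 0, 1\}.
#' @param includeSelf whether self-regulations (the diagonal) are
#'   meaningful; when `FALSE` the diagonal is zeroed.
#' @return A [SignedNetwork-class] object.
#' @export
SignedNetwork <- function(signs, includeSelf = TRUE) {
    signs <- as.matrix(signs)
    storage.mode(signs) <- "double"
    if (!includeSelf) diag(signs) <- 0
    new("SignedNetwork", signs = signs, includeSelf = includeSelf)
}
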