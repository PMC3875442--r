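#' @name accessors
#' @title Accessors for sigmoidGRN data classes
#' @param object a [VohradskyModel-class], [Timecourses-class] or
#'   [SignedNetwork-class] object.
#' @return `nGenes`, `nSeries`, `nSamples` return integer counts;
#'   `geneNames` a character vector; `regWeights` the weight matrix;
#'   `bias`, `kSyn`, `kDeg` numeric vectors; `seriesTimes`, `seriesValues`
#'   lists with one element per series; `adjacencySigns` the \{-1,0,1\}
#'   matrix of a signed network.
NULL

#' @rdname accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("regWeights", function(object) standardGeneric("regWeights"))
#' @rdname accessors
#' @export
setGeneric("bias", function(object) standardGeneric("bias"))
#' @rdname accessors
#' @export
setGeneric("kSyn", function(object) standardGeneric("kSyn"))
#' @rdname accessors
#' @export
setGeneric("kDeg", function(object) standardGeneric("kDeg"))
#' @rdname accessors
#' @export
setGeneric("nSeries", function(object) standardGeneric("nSeries"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("seriesTimes", function(object) standardGeneric("seriesTimes"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("adjacencySigns", function(object) standardGeneric("adjacencySigns"))

#' @rdname accessors
setMethod("nGenes", "VohradskyModel", function(object) nrow(object@W))
#' @rdname accessors
setMethod("geneNames", "VohradskyModel", function(object) object@geneNames)
#' @rdname accessors
setMethod("regWeights", "VohradskyModel", function(object) object@W)
#' @rdname accessors
setMethod("bias", "VohradskyModel", function(object) object@b)
#' @rdname accessors
setMethod("kSyn", "VohradskyModel", function(object) object@k1)
#' @rdname accessors
setMethod("kDeg", "VohradskyModel", function(object) object@k2)

#' @rdname accessors
setMethod("nGenes", "Timecourses", function(object) length(object@geneNames))
#' @rdname accessors
setMethod("geneNames", "Timecourses", function(object) object@geneNames)
#' @rdname accessors
setMethod("nSeries", "Timecourses", function(object) length(object@times))
#' @rdname accessors
setMethod("nSamples", "Timecourses",
    function(object) sum(vapply(object@times, length, integer(1))))
#' @rdname accessors
setMethod("seriesTimes", "Timecourses", function(object) object@times)
#' @rdname accessors
setMethod("seriesValues", "Timecourses", function(object) object@values)

#' @rdname accessors
setMethod("nGenes", "SignedNetwork", function(object) nrow(object@signs))
#' @rdname accessors
setMethod("adjacencySigns", "SignedNetwork", function(object) object@signs)

setMethod("show", "VohradskyModel", function(object) {
    n <- nGenes(object)
    cat(sprintf("VohradskyModel with %d gene%s\n", n, if (n == 1) "" else "s"))
    cat(sprintf("  nonzero weights: %d of %d\n", sum(object@W != 0), n * n))
    cat(sprintf("  k1 in [%.3g, %.3g], k2 in [%.3g, %.3g]\n",
                min(object@k1), max(object@k1), min(object@k2), max(object@k2)))
    cat("  genes:", paste(utils::head(object@geneNames, 6), collapse = ", "),
        if (n > 6) "..." else "", "\n")
})

setMethod("show", "Timecourses", function(object) {
    cat(sprintf("%s: %d series, %d genes, %d samples in total\n",
                class(object), nSeries(object), nGenes(object),
                nSamples(object)))
    lens <- vapply(object@times, length, integer(1))
    cat("  series lengths:", paste(lens, collapse = ", "), "\n")
})

setMethod("show", "SignedNetwork", function(object) {
    A <- object@signs
    cat(sprintf("SignedNetwork: %d genes, %d activations, %d repressions%s\n",
                nrow(A), sum(A > 0), sum(A < 0),
                if (object@includeSelf) "" else " (self-loops excluded)"))
})

# concatenate series of compatible time-course objects (same class & genes)
.combineTimecourses <- function(tcs) {
    stopifnot(length(tcs) >= 1L)
    cls <- class(tcs[[1]])
    gn <- tcs[[1]]@geneNames
    for (tc in tcs) stopifnot(identical(tc@geneNames, gn), is(tc, cls))
    new(cls,
        times = unlist(lapply(tcs, slot, "times"), recursive = FALSE),
        values = unlist(lapply(tcs, slot, "values"), recursive = FALSE),
        geneNames = gn)
}

# stack all series values into one M x n matrix (file/series order)
.stackValues <- function(tc) do.call(rbind, tc@values)
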