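# Tab-separated formats: time-series tables (series_id, time, one column
# per gene), model parameter tables (one row per gene: w_1..w_n, b, k1,
# k2) and signed edge lists.  '.' decimal, LF line endings; gene order is
# defined by the time-series header everywhere.

.fmtNum <- function(x) sprintf("%.15g", x)

#' Read and write time-series tables
#'
#' The format is TSV with a header `series_id  time  <gene names>` and
#' one row per sample; rows are grouped into series by `series_id` in
#' file order, and times must be strictly increasing within each series.
#'
#' @param path file path.
#' @param derivatives read the table as derivative estimates (allows
#'   negative values) instead of expression levels?
#' @return `readTimecourses` returns an [ExpressionTimecourses-class]
#'   (or [DerivativeTimecourses-class]); `writeTimecourses` returns
#'   `path` invisibly.
#' @examples
#' fx <- smallScaleFixture(seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeTimecourses(fx$data, f)
#' nSamples(readTimecourses(f))
#' @export
readTimecourses <- function(path, derivatives = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, check.names = FALSE)
    if (ncol(df) < 3L || !identical(colnames(df)[1:2], c("series_id", "time")))
        stop("expected header 'series_id\ttime\t<gene names>' in ", path)
    genes <- colnames(df)[-(1:2)]
    num <- df[, -1L, drop = FALSE]
    bad <- which(!vapply(num, is.numeric, logical(1)))
    if (length(bad) > 0)
        stop(sprintf("non-numeric values in column '%s' of %s",
                     colnames(num)[bad[1]], path))
    sids <- unique(df$series_id)
    times <- values <- vector("list", length(sids))
    for (s in seq_along(sids)) {
        rows <- which(df$series_id == sids[s])
        tt <- df$time[rows]
        if (is.unsorted(tt, strictly = TRUE)) {
            off <- rows[which(diff(tt) <= 0)[1] + 1L]
            stop(sprintf("times not strictly increasing in series '%s' at data row %d of %s",
                         sids[s], off, path))
        }
        times[[s]] <- tt
        values[[s]] <- as.matrix(df[rows, genes, drop = FALSE])
    }
    cls <- if (derivatives) "DerivativeTimecourses" else "ExpressionTimecourses"
    .makeTimecourses(cls, times, values, genes)
}

#' @rdname readTimecourses
#' @param data a [Timecourses-class] to write.
#' @export
writeTimecourses <- function(data, path) {
    stopifnot(is(data, "Timecourses"))
    rows <- character(0)
    for (s in seq_len(nSeries(data))) {
        v <- data@values[[s]]
        for (r in seq_len(nrow(v)))
            rows <- c(rows, paste(c(paste0("S", s),
                                    .fmtNum(data@times[[s]][r]),
                                    .fmtNum(v[r, ])), collapse = "\t"))
    }
    writeLines(c(paste(c("series_id", "time", geneNames(data)),
                       collapse = "\t"), rows), path)
    invisible(path)
}

#' Read and write model parameter tables
#'
#' One row per gene `i` with columns `w_1 .. w_n`, `b`, `k1`, `k2`
#' (header required): the weights of the regulations acting on gene `i`,
#' its bias, and its two rate constants.  Writing uses a canonical
#' numeric format, so `writeModelTable(readModelTable(f), f2)` is
#' byte-stable for canonically formatted files.
#'
#' @param path file path.
#' @param requirePositiveRates reject tables with `k1` or `k2 <= 0`
#'   (required for a model meant to be simulated)?
#' @return `readModelTable` returns a [VohradskyModel-class];
#'   `writeModelTable` returns `path` invisibly.
#' @examples
#' f <- system.file("extdata", "small_scale_model.tsv", package = "sigmoidGRN")
#' regWeights(readModelTable(f))
#' @export
readModelTable <- function(path, requirePositiveRates = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, check.names = FALSE)
    n <- nrow(df)
    if (ncol(df) != n + 3L)
        stop(sprintf("%s has %d columns but a %d-gene model table needs %d (w_1..w_%d, b, k1, k2)",
                     path, ncol(df), n, n + 3L, n))
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    k1 <- m[, n + 2L]
    k2 <- m[, n + 3L]
    if (requirePositiveRates && (any(k1 <= 0) || any(k2 <= 0)))
        stop("k1 and k2 must be > 0 for a simulatable model (", path, ")")
    VohradskyModel(W = m[, seq_len(n), drop = FALSE], b = m[, n + 1L],
                   k1 = k1, k2 = k2)
}

#' @rdname readModelTable
#' @param model a [VohradskyModel-class] to write.
#' @export
writeModelTable <- function(model, path) {
    stopifnot(is(model, "VohradskyModel"))
    n <- nGenes(model)
    header <- paste(c(paste0("w_", seq_len(n)), "b", "k1", "k2"),
                    collapse = "\t")
    tab <- cbind(regWeights(model), bias(model), kSyn(model), kDeg(model))
    rows <- apply(tab, 1L, function(r) paste(.fmtNum(r), collapse = "\t"))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Write a signed edge list
#'
#' Three-column TSV `regulator  target  sign` listing the nonzero entries
#' of a signed network; `A[i, j] != 0` is written as regulator `j`,
#' target `i`.
#'
#' @param network a [SignedNetwork-class].
#' @param path file path.
#' @param geneNames optional identifiers; defaults to 1-based indices.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path, geneNames = NULL) {
    stopifnot(is(network, "SignedNetwork"))
    A <- adjacencySigns(network)
    n <- nrow(A)
    if (is.null(geneNames)) geneNames <- as.character(seq_len(n))
    nz <- which(A != 0, arr.ind = TRUE)
    rows <- if (nrow(nz) == 0) character(0) else
        apply(nz, 1L, function(ij)
            paste(geneNames[ij[2]], geneNames[ij[1]], A[ij[1], ij[2]],
                  sep = "\t"))
    writeLines(c("regulator\ttarget\tsign", rows), path)
    invisible(path)
}
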