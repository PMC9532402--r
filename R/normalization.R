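#' Normalized expression/intensity matrix
#'
#' A genes x samples matrix of non-negative reals carrying its unit tag
#' (RPKM, CPM or TMM-scaled) and the provenance of its computation.
#'
#' @slot values numeric matrix, genes x samples.
#' @slot unit one of "RPKM", "CPM", "TMM-scaled".
#' @slot provenance list: method and parameters used.
#' @export
setClass("NormalizedMatrix", slots = c(
    values = "matrix", unit = "character", provenance = "list"))

setValidity("NormalizedMatrix", function(object) {
    msg <- character()
    if (length(object@unit) != 1L ||
        !object@unit %in% c("RPKM", "CPM", "TMM-scaled"))
        msg <- c(msg, "unit must be one of RPKM, CPM, TMM-scaled")
    if (any(object@values < 0)) msg <- c(msg, "values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @describeIn NormalizedMatrix-class the numeric matrix.
#' @param x a NormalizedMatrix.
#' @export
normValues <- function(x) x@values

#' @describeIn NormalizedMatrix-class the unit tag.
#' @export
normUnit <- function(x) x@unit

setMethod("show", "NormalizedMatrix", function(object) {
    cat(sprintf("NormalizedMatrix (%s): %d x %d\n", object@unit,
                nrow(object@values), ncol(object@values)))
})

.countsMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
}

.geneLengths <- function(x, lengths) {
    if (!is.null(lengths)) {
        m <- .countsMatrix(x)
        miss <- setdiff(rownames(m), names(lengths))
        if (length(miss))
            stop("missing gene lengths for: ",
                 paste(utils::head(miss, 10), collapse = ", "))
        return(lengths[rownames(m)])
    }
    if (is(x, "SummarizedExperiment")) {
        l <- rowData(x)$length_bp
        names(l) <- rownames(x)
        return(l)
    }
    stop("gene lengths are required for RPKM")
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM(g, s) = count * 1e9 / (library_size(s) * length_bp(g)); the unit used
#' for expression reporting.
#'
#' @param counts a \linkS4class{CountExperiment} or counts matrix.
#' @param lengths named gene lengths in bp; taken from \code{rowData()} when
#'   \code{counts} is a CountExperiment.
#' @return A \linkS4class{NormalizedMatrix} with unit "RPKM".
#' @examples
#' m <- matrix(10L, 1, 1, dimnames = list("g1", "s1"))
#' # a lone count of 10 over a 1 kb gene in a library of 10 reads:
#' normValues(computeRpkm(m, c(g1 = 1000)))  # 10 * 1e9 / (10 * 1000) = 1e6
#' @export
computeRpkm <- function(counts, lengths = NULL) {
    m <- .countsMatrix(counts)
    len <- .geneLengths(counts, lengths)
    if (any(len <= 0))
        stop("non-positive gene length for: ",
             paste(utils::head(rownames(m)[len <= 0], 10), collapse = ", "))
    lib <- colSums(m)
    if (any(lib == 0))
        stop("zero library size for sample(s): ",
             paste(colnames(m)[lib == 0], collapse = ", "))
    vals <- sweep(m * 1e9 / as.numeric(len), 2, lib, "/")
    new("NormalizedMatrix", values = vals, unit = "RPKM",
        provenance = list(method = "RPKM"))
}

#' Counts per million
#'
#' CPM(g, s) = count * 1e6 / (library_size(s) * factor(s)); supply TMM factors
#' to obtain TMM-scaled CPM.
#'
#' @param counts a \linkS4class{CountExperiment} or counts matrix.
#' @param factors optional per-sample scaling factors (default 1), e.g. from
#'   \code{\link{tmmFactors}}; must be positive.
#' @return A \linkS4class{NormalizedMatrix} with unit "CPM" (or "TMM-scaled"
#'   when factors are supplied).
#' @export
computeCpm <- function(counts, factors = NULL) {
    m <- .countsMatrix(counts)
    lib <- colSums(m)
    if (any(lib == 0))
        stop("zero library size for sample(s): ",
             paste(colnames(m)[lib == 0], collapse = ", "))
    f <- if (is.null(factors)) rep(1, ncol(m)) else {
        if (!is.null(names(factors))) factors <- factors[colnames(m)]
        as.numeric(factors)
    }
    if (any(!is.finite(f)) || any(f <= 0))
        stop("scaling factors must be positive and finite")
    vals <- sweep(m * 1e6, 2, lib * f, "/")
    new("NormalizedMatrix", values = vals,
        unit = if (is.null(factors)) "CPM" else "TMM-scaled",
        provenance = list(method = "CPM", tmm = !is.null(factors)))
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling factors by the trimmed mean of M-values (TMM)
#' method with its canonical parameters: 30 percent two-sided trim on the
#' log-ratios (M), 5 percent on absolute intensity (A), inverse
#' asymptotic-variance weights, and automatic reference selection (the sample
#' whose upper-quartile count fraction is closest to the mean).  Genes with a
#' zero count in either compared sample are excluded pairwise; the returned
#' factors are renormalized to geometric mean 1.
#'
#' @param counts a \linkS4class{CountExperiment}, counts matrix, or
#'   \linkS4class{LipidSpeciesTable} (the intensity matrix is used; the
#'   method applies unchanged to lipid intensity tables).
#' @param reference optional sample id to use as the reference column.
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean 1 (to 1e-12).
#' @export
tmmFactors <- function(counts, reference = NULL) {
    m <- if (is(counts, "LipidSpeciesTable")) assay(counts, "intensity")
         else .countsMatrix(counts)
    if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
    zero <- colSums(m > 0) == 0
    if (any(zero))
        stop("sample(s) with no positive values: ",
             paste(colnames(m)[zero], collapse = ", "))
    refcol <- NULL
    if (!is.null(reference)) {
        refcol <- match(reference, colnames(m))
        if (is.na(refcol)) stop("unknown reference sample: ", reference)
    }
    f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = refcol)
    names(f) <- colnames(m)
    f
}

#' Write a normalized matrix as TSV with a provenance header
#'
#' The first lines are '#'-prefixed provenance (method, unit, parameters,
#' date), followed by a gene_id column and one column per sample.
#'
#' @param x a \linkS4class{NormalizedMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNormalizedMatrix <- function(x, path) {
    stopifnot(is(x, "NormalizedMatrix"))
    hdr <- c(sprintf("# unit: %s", x@unit),
             sprintf("# method: %s", x@provenance$method),
             "# generated-by: mesea")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    df <- data.frame(gene_id = rownames(x@values), x@values,
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
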