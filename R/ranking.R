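#' @importFrom stats pt var
NULL

#' The four canonical contrasts of the 2x2 design
#'
#' Sex contrasts within each maternal-diet arm and diet contrasts within each
#' sex: (M vs F | moC), (M vs F | moHF), (moHF vs moC | F), (moHF vs moC | M).
#' Positive log2FC means higher in the first-named level (M, resp. moHF).
#'
#' @param x a \linkS4class{CountExperiment} (its \code{colData()} is used) or
#'   a data.frame with columns \code{sample_id}, \code{sex},
#'   \code{maternal_diet}.
#' @return Named list of four \linkS4class{Contrast} objects.
#' @export
canonicalContrasts <- function(x) {
    md <- if (is(x, "SummarizedExperiment")) {
        data.frame(sample_id = colnames(x),
                   sex = as.character(colData(x)$sex),
                   maternal_diet = as.character(colData(x)$maternal_diet),
                   stringsAsFactors = FALSE)
    } else as.data.frame(x)
    pick <- function(sex, diet)
        md$sample_id[md$sex %in% sex & md$maternal_diet %in% diet]
    list(
        M_vs_F_moC = contrast("M_vs_F_moC",
                              pick("M", "moC"), pick("F", "moC")),
        M_vs_F_moHF = contrast("M_vs_F_moHF",
                               pick("M", "moHF"), pick("F", "moHF")),
        moHF_vs_moC_F = contrast("moHF_vs_moC_F",
                                 pick("F", "moHF"), pick("F", "moC")),
        moHF_vs_moC_M = contrast("moHF_vs_moC_M",
                                 pick("M", "moHF"), pick("M", "moC")))
}

#' Expression filter (with duplicate-id collapse)
#'
#' Collapses duplicate gene ids to a single summed row, then retains genes
#' with count >= \code{min_count} in at least \code{min_samples} samples.
#' Defaults are permissive: >= 1 read in >= 2 samples.
#'
#' @param counts a \linkS4class{CountExperiment} or counts matrix (matrices
#'   may carry duplicated rownames; a CountExperiment cannot).
#' @param min_count,min_samples non-negative integer thresholds.
#' @return Object of the same type, restricted to the retained genes.
#' @export
geneFilter <- function(counts, min_count = 1L, min_samples = 2L) {
    stopifnot(min_count >= 0, min_samples >= 0)
    m <- .countsMatrix(counts)
    if (anyDuplicated(rownames(m))) {
        m <- rowsum(m, group = rownames(m))
        m <- m[unique(rownames(.countsMatrix(counts))), , drop = FALSE]
    }
    keep <- rowSums(m >= min_count) >= min_samples
    if (is(counts, "SummarizedExperiment"))
        counts[names(keep)[keep], ]
    else m[keep, , drop = FALSE]
}

.normMatrix <- function(x) {
    if (is(x, "NormalizedMatrix")) x@values
    else if (is(x, "SummarizedExperiment")) assay(x)
    else as.matrix(x)
}

.contrastColumns <- function(m, contrast) {
    missA <- setdiff(contrast@groupA, colnames(m))
    missB <- setdiff(contrast@groupB, colnames(m))
    if (length(missA) || length(missB))
        stop("contrast samples absent from matrix: ",
             paste(c(missA, missB), collapse = ", "))
}

#' Per-gene log2 fold change between contrast groups
#'
#' log2FC(g) = log2(mean_A(g) + pseudocount) - log2(mean_B(g) + pseudocount);
#' the pseudocount keeps the value finite for genes at zero in one arm.
#'
#' @param norm a \linkS4class{NormalizedMatrix} (or plain matrix).
#' @param contrast a \linkS4class{Contrast}.
#' @param pseudocount positive real added to both group means (default 1).
#' @return Named numeric vector of log2 fold changes (positive = higher in
#'   group A).
#' @export
log2FoldChange <- function(norm, contrast, pseudocount = 1) {
    stopifnot(is(contrast, "Contrast"), pseudocount > 0)
    m <- .normMatrix(norm)
    .contrastColumns(m, contrast)
    ma <- rowMeans(m[, contrast@groupA, drop = FALSE])
    mb <- rowMeans(m[, contrast@groupB, drop = FALSE])
    log2(ma + pseudocount) - log2(mb + pseudocount)
}

#' Per-gene Welch differential-expression table
#'
#' A simplified differential stage: Welch's unequal-variance t-test per gene
#' on log2(value + pseudocount), Benjamini-Hochberg adjustment across all
#' tested genes, and a DE flag at q < \code{fdr}.  The reported log2FC is the
#' same pseudocount-stabilized mean-ratio estimate that drives the ranking.
#' Genes with zero variance in both groups and equal means get p = 1.
#'
#' @param norm a \linkS4class{NormalizedMatrix} (or matrix) of normalized
#'   values.
#' @param contrast a \linkS4class{Contrast}; both groups need >= 2 samples.
#' @param pseudocount positive real (default 1).
#' @param fdr DE-flag threshold on BH q (default 0.1).
#' @return data.frame: gene_id, log2FC, t, df, p, q, de.
#' @export
welchDETable <- function(norm, contrast, pseudocount = 1, fdr = 0.1) {
    stopifnot(is(contrast, "Contrast"))
    m <- .normMatrix(norm)
    .contrastColumns(m, contrast)
    la <- log2(m[, contrast@groupA, drop = FALSE] + pseudocount)
    lb <- log2(m[, contrast@groupB, drop = FALSE] + pseudocount)
    na <- ncol(la); nb <- ncol(lb)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- apply(la, 1, var); vb <- apply(lb, 1, var)
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(tt), df)
    degen <- se2 == 0
    if (any(degen)) {
        samemean <- degen & (ma == mb)
        p[samemean] <- 1; tt[samemean] <- 0
        p[degen & !samemean] <- 0
        tt[degen & !samemean] <- sign(ma - mb)[degen & !samemean] * Inf
        df[degen] <- NA_real_
    }
    q <- bhFdr(p)
    data.frame(gene_id = rownames(m),
               log2FC = unname(log2FoldChange(norm, contrast, pseudocount)),
               t = unname(tt), df = unname(df), p = unname(p),
               q = unname(q), de = unname(q < fdr),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank genes by descending log2 fold change
#'
#' Produces the ranked list the MES running sum is computed over: genes in
#' descending log2FC order, ties broken by gene id ascending (C-locale radix
#' order) so the ranking is deterministic across platforms.
#'
#' @param fc named numeric of log2 fold changes (e.g. from
#'   \code{\link{log2FoldChange}}), or a data.frame with columns
#'   \code{gene_id} and \code{log2FC}.
#' @param contrastName optional provenance label.
#' @return A \linkS4class{RankedGeneList}.
#' @examples
#' rankGenes(c(g1 = 2, g2 = -1, g3 = 0.5))  # order g1, g3, g2
#' @export
rankGenes <- function(fc, contrastName = "") {
    if (is.data.frame(fc)) {
        v <- fc$log2FC
        names(v) <- fc$gene_id
        fc <- v
    }
    if (!length(fc)) stop("empty fold-change table")
    bad <- names(fc)[is.na(fc)]
    if (length(bad))
        stop("NaN/NA log2FC for gene(s): ",
             paste(utils::head(bad, 10), collapse = ", "))
    o <- order(-fc, names(fc), method = "radix")
    new("RankedGeneList", geneIds = names(fc)[o],
        log2FC = unname(fc[o]), contrastName = contrastName)
}

#' Write a ranked gene list as 2-column TSV
#' @param ranked a \linkS4class{RankedGeneList}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRankedList <- function(ranked, path) {
    utils::write.table(
        data.frame(gene_id = ranked@geneIds, log2FC = ranked@log2FC),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a ranked gene list written by \code{\link{writeRankedList}}
#' @param path TSV with columns gene_id, log2FC.
#' @param contrastName optional provenance label.
#' @return A \linkS4class{RankedGeneList}.
#' @export
readRankedList <- function(path, contrastName = "") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    rankGenes(df, contrastName = contrastName)
}
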