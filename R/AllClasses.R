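#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
NULL

GROUP_LABELS <- c("F-moC", "M-moC", "F-moHF", "M-moHF")
SEX_LEVELS <- c("F", "M")
DIET_LEVELS <- c("moC", "moHF")

LIPID_CLASSES <- c("TG", "PC", "PE", "LPC", "LPE", "PS", "PG", "CL",
                   "PI", "LPI", "Cer", "GlcCer", "SM")

#' Two-by-two study design (sex x maternal diet)
#'
#' Describes the factorial layout of the study: four groups, one per
#' combination of offspring sex (F/M) and maternal diet (moC = control-fed
#' mother, moHF = high-fat-fed mother), each with its number of animals.
#'
#' @slot groups data.frame with columns \code{label}, \code{sex},
#'   \code{maternal_diet}, \code{n}; exactly one row per design cell.
#' @export
setClass("StudyDesign", slots = c(groups = "data.frame"))

setValidity("StudyDesign", function(object) {
    g <- object@groups
    msg <- character()
    need <- c("label", "sex", "maternal_diet", "n")
    if (!all(need %in% colnames(g)))
        return(paste("groups must have columns:", paste(need, collapse = ", ")))
    if (nrow(g) != 4L)
        msg <- c(msg, "exactly four groups are required (one per sex x diet cell)")
    cells <- paste(g$sex, g$maternal_diet)
    if (anyDuplicated(cells))
        msg <- c(msg, "each sex x diet cell must appear exactly once")
    if (!all(g$sex %in% SEX_LEVELS))
        msg <- c(msg, "sex must be one of F, M")
    if (!all(g$maternal_diet %in% DIET_LEVELS))
        msg <- c(msg, "maternal_diet must be one of moC, moHF")
    if (anyDuplicated(g$label))
        msg <- c(msg, "group labels must be unique")
    if (!all(g$n >= 1) || !all(g$n == round(g$n)))
        msg <- c(msg, "all group sizes must be positive integers")
    if (length(msg)) msg else TRUE
})

#' Construct a StudyDesign
#'
#' Defaults reproduce the liver RNA-seq cohort sizes of the study design this
#' package emulates: F-moC n = 5, M-moC n = 5, F-moHF n = 6, M-moHF n = 3.
#'
#' @param n named integer vector of group sizes; names must be the four group
#'   labels \code{F-moC}, \code{M-moC}, \code{F-moHF}, \code{M-moHF}.
#' @return A \linkS4class{StudyDesign}.
#' @examples
#' studyDesign()
#' studyDesign(c("F-moC" = 10, "M-moC" = 10, "F-moHF" = 10, "M-moHF" = 10))
#' @export
studyDesign <- function(n = c("F-moC" = 5, "M-moC" = 5, "F-moHF" = 6, "M-moHF" = 3)) {
    if (is.null(names(n)) || !setequal(names(n), GROUP_LABELS))
        stop("'n' must be named with the four group labels: ",
             paste(GROUP_LABELS, collapse = ", "))
    n <- n[GROUP_LABELS]
    g <- data.frame(
        label = GROUP_LABELS,
        sex = c("F", "M", "F", "M"),
        maternal_diet = c("moC", "moC", "moHF", "moHF"),
        n = as.integer(n),
        stringsAsFactors = FALSE
    )
    new("StudyDesign", groups = g)
}

#' Per-sample table of a StudyDesign
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return data.frame with columns \code{sample_id}, \code{group}, \code{sex},
#'   \code{maternal_diet}; one row per animal, ids unique across groups.
#' @export
sampleTable <- function(design) {
    stopifnot(is(design, "StudyDesign"))
    g <- design@groups
    out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
        data.frame(
            sample_id = sprintf("%s.%d", g$label[i], seq_len(g$n[i])),
            group = g$label[i],
            sex = g$sex[i],
            maternal_diet = g$maternal_diet[i],
            stringsAsFactors = FALSE
        )
    }))
    rownames(out) <- NULL
    out
}

setMethod("show", "StudyDesign", function(object) {
    g <- object@groups
    cat("StudyDesign: 2x2 sex x maternal diet,", sum(g$n), "samples\n")
    for (i in seq_len(nrow(g)))
        cat(sprintf("  %-7s sex=%s diet=%-4s n=%d\n",
                    g$label[i], g$sex[i], g$maternal_diet[i], g$n[i]))
})

#' Planted ground truth for the synthetic-data generator
#'
#' Holds, per gene, the negative-binomial baseline mean and dispersion and the
#' planted per-group log2 shifts in expression; and the registry of gene sets
#' whose members were given coordinated shifts (the planted enrichments).
#'
#' @slot baselineMean named numeric, per-gene baseline mean (> 0).
#' @slot dispersion named numeric, per-gene NB dispersion (> 0).
#' @slot groupLog2FC numeric matrix genes x 4 group labels; planted additive
#'   log2 shifts relative to baseline (0 = no effect in that group).
#' @slot enrichedSets data.frame (set_id, direction, strength, contrast)
#'   recording planted set-level enrichments.
#' @export
setClass("PlantedTruth", slots = c(
    baselineMean = "numeric",
    dispersion = "numeric",
    groupLog2FC = "matrix",
    enrichedSets = "data.frame"
))

setValidity("PlantedTruth", function(object) {
    msg <- character()
    genes <- names(object@baselineMean)
    if (is.null(genes) || anyDuplicated(genes))
        msg <- c(msg, "baselineMean must be named by unique gene ids")
    if (any(object@baselineMean <= 0))
        msg <- c(msg, "baseline means must be > 0")
    if (any(object@dispersion <= 0))
        msg <- c(msg, "dispersions must be > 0")
    if (!identical(names(object@dispersion), genes))
        msg <- c(msg, "dispersion must be named identically to baselineMean")
    m <- object@groupLog2FC
    if (!identical(rownames(m), genes) || !identical(colnames(m), GROUP_LABELS))
        msg <- c(msg, "groupLog2FC must be genes x the four group labels")
    if (any(!is.finite(m)))
        msg <- c(msg, "planted log2FC values must be finite")
    if (length(msg)) msg else TRUE
})

#' Two-group contrast (A versus B)
#'
#' Positive log2 fold change means higher expression in group A.  The four
#' canonical contrasts of the design are (M vs F | moC), (M vs F | moHF),
#' (moHF vs moC | F) and (moHF vs moC | M); see \code{\link{canonicalContrasts}}.
#'
#' @slot name character scalar.
#' @slot groupA,groupB character vectors of sample ids; disjoint, each >= 2.
#' @export
setClass("Contrast", slots = c(
    name = "character", groupA = "character", groupB = "character"))

setValidity("Contrast", function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "name must be a scalar")
    if (length(object@groupA) < 2L || length(object@groupB) < 2L)
        msg <- c(msg, "each contrast group needs at least 2 samples")
    if (length(intersect(object@groupA, object@groupB)))
        msg <- c(msg, "contrast groups must be disjoint")
    if (anyDuplicated(object@groupA) || anyDuplicated(object@groupB))
        msg <- c(msg, "duplicate sample ids within a contrast group")
    if (length(msg)) msg else TRUE
})

#' @rdname Contrast-class
#' @param name contrast label.
#' @param groupA,groupB sample ids of the two arms ("A versus B").
#' @export
contrast <- function(name, groupA, groupB)
    new("Contrast", name = name, groupA = as.character(groupA),
        groupB = as.character(groupB))

setMethod("show", "Contrast", function(object) {
    cat(sprintf("Contrast '%s': %d vs %d samples\n", object@name,
                length(object@groupA), length(object@groupB)))
})

#' Ranked gene list
#'
#' All analyzed genes ordered by contrast log2 fold change, descending, with
#' ties broken by gene id (ascending) so the ordering is deterministic.  This
#' is the object the MES running sum is computed over; its length is N.
#'
#' @slot geneIds character, the genes in rank order (rank 1 = largest log2FC).
#' @slot log2FC numeric, the corresponding log2 fold changes.
#' @slot contrastName character scalar, provenance.
#' @export
setClass("RankedGeneList", slots = c(
    geneIds = "character", log2FC = "numeric", contrastName = "character"))

setValidity("RankedGeneList", function(object) {
    msg <- character()
    n <- length(object@geneIds)
    if (n != length(object@log2FC))
        msg <- c(msg, "geneIds and log2FC lengths differ")
    if (n < 2L) msg <- c(msg, "a ranked list needs at least 2 genes")
    if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate gene ids")
    if (any(!is.finite(object@log2FC))) msg <- c(msg, "non-finite log2FC")
    if (n >= 2L) {
        o <- order(-object@log2FC, object@geneIds, method = "radix")
        if (!identical(o, seq_len(n)))
            msg <- c(msg,
                "genes must be ordered by log2FC descending, ties by id ascending")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn RankedGeneList-class number of ranked genes (N).
#' @param x a RankedGeneList.
#' @export
setMethod("length", "RankedGeneList", function(x) length(x@geneIds))

setMethod("show", "RankedGeneList", function(object) {
    n <- length(object)
    cat(sprintf("RankedGeneList (%s): N = %d genes, log2FC in [%.3g, %.3g]\n",
                object@contrastName, n,
                min(object@log2FC), max(object@log2FC)))
    k <- min(5L, n)
    cat("  top:", paste(sprintf("%s (%.3g)", object@geneIds[seq_len(k)],
                                object@log2FC[seq_len(k)]), collapse = ", "),
        "\n")
})

#' Named collection of gene sets
#'
#' A lightweight container for GMT-style gene-set collections: a named list of
#' character vectors of member gene ids, plus one description per set.
#'
#' @slot sets named list of character vectors (unique members within a set).
#' @slot description named character, one per set.
#' @export
setClass("GeneSetCollection", slots = c(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msg <- c(msg, "sets must be uniquely named")
        if (!all(vapply(object@sets, is.character, logical(1))))
            msg <- c(msg, "each set must be a character vector of gene ids")
        if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0))
            msg <- c(msg, "duplicate members within a set")
    }
    if (!identical(names(object@description), names(object@sets)))
        msg <- c(msg, "descriptions must be named in step with sets")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors.
#' @param description optional named character of set descriptions.
#' @export
geneSetCollection <- function(sets = list(), description = NULL) {
    sets <- lapply(sets, as.character)
    if (is.null(description)) {
        description <- rep("", length(sets))
        names(description) <- names(sets)
    }
    new("GeneSetCollection", sets = sets, description = description[names(sets)])
}

#' @describeIn GeneSetCollection-class number of sets.
#' @param x a GeneSetCollection.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set identifiers.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class extract one set's member gene ids.
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets", length(object)))
    if (length(object)) {
        sz <- lengths(object@sets)
        cat(sprintf(", sizes %d..%d", min(sz), max(sz)))
    }
    cat("\n")
})

#' Gene-count experiment for the sex x maternal-diet design
#'
#' A \linkS4class{SummarizedExperiment} holding a genes x samples matrix of
#' non-negative integer read counts (assay \code{"counts"}), per-gene lengths
#' in bp (\code{rowData()$length_bp}, used by RPKM), and per-sample metadata
#' (\code{colData()} columns \code{sex} and \code{maternal_diet}).
#'
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    m <- assay(object, "counts")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be non-negative integers")
    cd <- colData(object)
    if (!all(c("sex", "maternal_diet") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'sex' and 'maternal_diet'")
    else {
        if (!all(as.character(cd$sex) %in% SEX_LEVELS))
            msg <- c(msg, "sex must be F or M")
        if (!all(as.character(cd$maternal_diet) %in% DIET_LEVELS))
            msg <- c(msg, "maternal_diet must be moC or moHF")
    }
    if (!"length_bp" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'length_bp'")
    else if (any(is.na(rowData(object)$length_bp)) ||
             any(rowData(object)$length_bp <= 0))
        msg <- c(msg, "gene lengths must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a CountExperiment
#'
#' @param counts genes x samples integer matrix with dimnames.
#' @param lengths named numeric of gene lengths in bp (every gene in
#'   \code{counts} must be present).
#' @param metadata data.frame with columns \code{sample_id}, \code{sex},
#'   \code{maternal_diet} (and optionally \code{group}); every sample in
#'   \code{counts} must be present.
#' @return A \linkS4class{CountExperiment}.
#' @export
countExperiment <- function(counts, lengths, metadata) {
    counts <- as.matrix(counts)
    missing_len <- setdiff(rownames(counts), names(lengths))
    if (length(missing_len))
        stop("missing gene lengths for: ",
             paste(utils::head(missing_len, 10), collapse = ", "))
    orphan <- setdiff(colnames(counts), metadata$sample_id)
    if (length(orphan))
        stop("samples absent from metadata: ", paste(orphan, collapse = ", "))
    md <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
    cd <- DataFrame(md[setdiff(colnames(md), "sample_id")],
                    row.names = colnames(counts))
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(length_bp = unname(lengths[rownames(counts)]),
                            row.names = rownames(counts)),
        colData = cd)
    new("CountExperiment", se)
}

setMethod("show", "CountExperiment", function(object) {
    cd <- colData(object)
    tab <- table(paste(cd$sex, cd$maternal_diet, sep = "-"))
    cat(sprintf("CountExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    cat("  groups:", paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
})

#' Lipid species intensity table
#'
#' A \linkS4class{SummarizedExperiment} of per-species LC-MS intensities
#' (assay \code{"intensity"}) whose \code{rowData()} carries the parsed
#' species annotation: \code{lipid_class}, \code{total_carbons},
#' \code{double_bonds} (NA for class-level labels like "TG54") and
#' \code{sphingoid} (TRUE for "d"-prefixed sphingoid backbones).
#'
#' @export
setClass("LipidSpeciesTable", contains = "SummarizedExperiment")

setValidity("LipidSpeciesTable", function(object) {
    msg <- character()
    if (!"intensity" %in% assayNames(object))
        return("assay 'intensity' is required")
    rd <- rowData(object)
    need <- c("lipid_class", "total_carbons", "double_bonds", "sphingoid")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    if (any(assay(object, "intensity") < 0))
        msg <- c(msg, "intensities must be non-negative")
    if (!all(rd$lipid_class %in% LIPID_CLASSES))
        msg <- c(msg, "unknown lipid class in rowData")
    if (any(rd$total_carbons <= 0))
        msg <- c(msg, "total_carbons must be positive")
    db <- rd$double_bonds
    if (any(!is.na(db) & (db < 0 | db > rd$total_carbons)))
        msg <- c(msg, "double_bonds must be in [0, total_carbons]")
    if (length(msg)) msg else TRUE
})

#' Construct a LipidSpeciesTable from species names and intensities
#'
#' Species names are parsed with \code{\link{parseLipidSpecies}}.
#'
#' @param intensities species x samples numeric matrix; rownames are species
#'   names in the CLASS(C:DB) / CLASS(dC:DB) grammar.
#' @param sampleData optional data.frame of per-sample metadata (rownames =
#'   sample ids).
#' @return A \linkS4class{LipidSpeciesTable}.
#' @export
lipidSpeciesTable <- function(intensities, sampleData = NULL) {
    intensities <- as.matrix(intensities)
    if (is.null(rownames(intensities)))
        stop("intensity matrix must have species names as rownames")
    ann <- parseLipidSpecies(rownames(intensities))
    cd <- if (is.null(sampleData)) {
        DataFrame(row.names = colnames(intensities))
    } else DataFrame(sampleData)
    se <- SummarizedExperiment(
        assays = list(intensity = intensities),
        rowData = DataFrame(ann, row.names = rownames(intensities)),
        colData = cd)
    new("LipidSpeciesTable", se)
}

setMethod("show", "LipidSpeciesTable", function(object) {
    rd <- rowData(object)
    cat(sprintf("LipidSpeciesTable: %d species (%d classes) x %d samples\n",
                nrow(object), length(unique(rd$lipid_class)), ncol(object)))
})
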