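#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated -- set name, description,
#' then member gene ids.
#'
#' @param path GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
    desc <- vapply(parts, `[[`, character(1), 2L)
    names(desc) <- names(sets)
    geneSetCollection(sets, desc)
}

#' Write a gene-set collection as GMT
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(collection, path) {
    stopifnot(is(collection, "GeneSetCollection"))
    lines <- vapply(names(collection), function(id) {
        paste(c(id, collection@description[[id]], collection@sets[[id]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a CountExperiment to plain-text files
#'
#' Emits the exchange formats of the pipeline: counts TSV (gene_id +
#' one column per sample), gene-lengths TSV (gene_id, length_bp) and sample
#' metadata CSV (sample_id, sex, maternal_diet).
#'
#' @param se a \linkS4class{CountExperiment}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
writeCountExperiment <- function(se, dir) {
    stopifnot(is(se, "CountExperiment"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- c(counts = file.path(dir, "counts.tsv"),
           lengths = file.path(dir, "gene_lengths.tsv"),
           metadata = file.path(dir, "sample_metadata.csv"))
    utils::write.table(
        data.frame(gene_id = rownames(se), assay(se, "counts"),
                   check.names = FALSE),
        p[["counts"]], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(gene_id = rownames(se),
                   length_bp = rowData(se)$length_bp),
        p[["lengths"]], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(
        data.frame(sample_id = colnames(se),
                   sex = as.character(colData(se)$sex),
                   maternal_diet = as.character(colData(se)$maternal_diet)),
        p[["metadata"]], quote = FALSE, row.names = FALSE)
    invisible(p)
}

#' Read a CountExperiment from plain-text files
#'
#' @param counts_tsv counts TSV (gene_id + sample columns).
#' @param lengths_tsv gene-lengths TSV (gene_id, length_bp).
#' @param metadata_csv metadata CSV (sample_id, sex, maternal_diet).
#' @return A \linkS4class{CountExperiment}.
#' @export
readCountExperiment <- function(counts_tsv, lengths_tsv, metadata_csv) {
    cm <- utils::read.delim(counts_tsv, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(cm[, -1, drop = FALSE])
    rownames(m) <- cm[[1]]
    storage.mode(m) <- "integer"
    lt <- utils::read.delim(lengths_tsv, stringsAsFactors = FALSE)
    lengths <- stats::setNames(lt$length_bp, lt$gene_id)
    md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
    countExperiment(m, lengths, md)
}

#' Write a lipid species table as CSV (species, then one column per sample)
#' @param table a \linkS4class{LipidSpeciesTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLipidTable <- function(table, path) {
    stopifnot(is(table, "LipidSpeciesTable"))
    utils::write.csv(
        data.frame(species = rownames(table), assay(table, "intensity"),
                   check.names = FALSE),
        path, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a lipid species table written by \code{\link{writeLipidTable}}
#' @param path CSV with a species column then per-sample intensities.
#' @param sampleData optional per-sample metadata data.frame.
#' @return A \linkS4class{LipidSpeciesTable}.
#' @export
readLipidTable <- function(path, sampleData = NULL) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    lipidSpeciesTable(m, sampleData = sampleData)
}
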