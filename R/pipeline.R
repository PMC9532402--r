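#' Pipeline configuration
#'
#' Assembles and validates every knob of the end-to-end analysis.  In
#' simulate mode all inputs come from the synthetic-data generators; in
#' ingest mode paths to counts / lengths / metadata TSVs and a GMT collection
#' are required (lipid and phenotype CSVs optional).
#'
#' @param simulate generate inputs synthetically (default TRUE).
#' @param counts_tsv,lengths_tsv,metadata_csv,gmt_file,lipids_csv,phenotypes_csv
#'   input paths for ingest mode.
#' @param n_genes,n_sets,n_enriched,enriched_size,strength,target_contrast
#'   synthetic-scenario parameters (see \code{\link{simulateStudy}}).
#' @param design a \linkS4class{StudyDesign} for simulate mode.
#' @param B permutations per set (default 1000).
#' @param min_size minimum tested set size (default 5).
#' @param p_threshold,fdr_threshold significance thresholds (defaults 0.05,
#'   0.1), both in (0, 1).
#' @param pseudocount log2FC pseudocount on RPKM values (default 1).
#' @param min_count,min_samples expression-filter thresholds (defaults 1, 2).
#' @param mode MES mode (see \code{\link{mesStatistic}}).
#' @param seed integer seed for every stochastic stage.
#' @param outdir output directory.
#' @return A validated config (list with class "mesea_config").
#' @export
pipelineConfig <- function(simulate = TRUE, counts_tsv = NULL,
                           lengths_tsv = NULL, metadata_csv = NULL,
                           gmt_file = NULL, lipids_csv = NULL,
                           phenotypes_csv = NULL,
                           n_genes = 2000L, n_sets = 20L, n_enriched = 1L,
                           enriched_size = 50L, strength = 2,
                           target_contrast = "M_vs_F_moC",
                           design = studyDesign(), B = 1000L, min_size = 5L,
                           p_threshold = 0.05, fdr_threshold = 0.1,
                           pseudocount = 1, min_count = 1L, min_samples = 2L,
                           mode = "signed_extremum", seed = 1L,
                           outdir = tempfile("mesea_run_")) {
    stopifnot(B >= 1, min_size >= 1,
              p_threshold > 0, p_threshold < 1,
              fdr_threshold > 0, fdr_threshold < 1,
              pseudocount > 0)
    if (!simulate) {
        need <- list(counts_tsv = counts_tsv, lengths_tsv = lengths_tsv,
                     metadata_csv = metadata_csv, gmt_file = gmt_file)
        missing <- names(need)[vapply(need, is.null, logical(1))]
        if (length(missing))
            stop("ingest mode requires: ", paste(missing, collapse = ", "))
        gone <- unlist(need)[!file.exists(unlist(need))]
        if (length(gone))
            stop("input file(s) not found: ", paste(gone, collapse = ", "))
    }
    cfg <- list(simulate = simulate, counts_tsv = counts_tsv,
                lengths_tsv = lengths_tsv, metadata_csv = metadata_csv,
                gmt_file = gmt_file, lipids_csv = lipids_csv,
                phenotypes_csv = phenotypes_csv, n_genes = n_genes,
                n_sets = n_sets, n_enriched = n_enriched,
                enriched_size = enriched_size, strength = strength,
                target_contrast = target_contrast, design = design, B = B,
                min_size = min_size, p_threshold = p_threshold,
                fdr_threshold = fdr_threshold, pseudocount = pseudocount,
                min_count = min_count, min_samples = min_samples,
                mode = mode, seed = as.integer(seed), outdir = outdir)
    class(cfg) <- "mesea_config"
    cfg
}

.tsvOut <- function(df, path, provenance) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", provenance), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) the study inputs, filters and RPKM-normalizes the
#' counts, ranks genes by log2 fold change for each of the four canonical
#' contrasts, runs MES enrichment with the permutation null and BH-FDR per
#' contrast, computes the lipidomics panels (TMM factors, class relative
#' abundance, saturation profiles, per-contrast fold changes) and the
#' per-animal phenotype indices, and writes everything as '#'-provenance TSVs
#' plus a JSON run manifest.  Identical config and seed give byte-identical
#' result tables.
#'
#' @param config a config from \code{\link{pipelineConfig}}.
#' @return The manifest (list), invisibly; also written as
#'   \code{manifest.json} in the output directory.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "mesea_config"))
    outdir <- config$outdir
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    manifest <- list(
        package = "mesea",
        version = as.character(utils::packageVersion("mesea")),
        seed = config$seed,
        parameters = config[c("n_genes", "n_sets", "n_enriched",
                              "enriched_size", "strength", "target_contrast",
                              "B", "min_size", "p_threshold", "fdr_threshold",
                              "pseudocount", "min_count", "min_samples",
                              "mode", "simulate")],
        stages = list(), files = character())
    writeManifest <- function()
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    on.exit(writeManifest())
    done <- function(stage, files = character()) {
        manifest$stages[[stage]] <<- "completed"
        manifest$files <<- c(manifest$files, files)
    }
    prov <- sprintf("mesea seed=%d B=%d min_size=%d mode=%s",
                    config$seed, config$B, config$min_size, config$mode)

    ## --- inputs ---
    if (config$simulate) {
        study <- simulateStudy(
            n_genes = config$n_genes, n_sets = config$n_sets,
            n_enriched = config$n_enriched,
            enriched_size = config$enriched_size,
            strength = config$strength,
            target_contrast = config$target_contrast,
            design = config$design, seed = config$seed)
        se <- study$counts; sets <- study$sets
        lipids <- study$lipids; phen <- study$phenotypes
        writeCountExperiment(se, file.path(outdir, "inputs"))
        writeGMT(sets, file.path(outdir, "inputs", "gene_sets.gmt"))
        writeLipidTable(lipids, file.path(outdir, "inputs", "lipids.csv"))
        utils::write.csv(phen, file.path(outdir, "inputs", "phenotypes.csv"),
                         quote = FALSE, row.names = FALSE)
    } else {
        se <- readCountExperiment(config$counts_tsv, config$lengths_tsv,
                                  config$metadata_csv)
        sets <- readGMT(config$gmt_file)
        lipids <- if (!is.null(config$lipids_csv))
            readLipidTable(config$lipids_csv) else NULL
        phen <- if (!is.null(config$phenotypes_csv))
            utils::read.csv(config$phenotypes_csv,
                            stringsAsFactors = FALSE) else NULL
    }
    done("inputs")

    ## --- normalize + rank + enrich, per contrast ---
    filtered <- geneFilter(se, config$min_count, config$min_samples)
    rpkm <- computeRpkm(filtered)
    done("normalize")
    contrasts <- canonicalContrasts(filtered)
    for (cn in names(contrasts)) {
        ct <- contrasts[[cn]]
        fc <- log2FoldChange(rpkm, ct, config$pseudocount)
        ranked <- rankGenes(fc, contrastName = cn)
        f1 <- .tsvOut(data.frame(gene_id = ranked@geneIds,
                                 log2FC = ranked@log2FC),
                      file.path(outdir, sprintf("ranked_%s.tsv", cn)), prov)
        de <- welchDETable(rpkm, ct, config$pseudocount,
                           fdr = config$fdr_threshold)
        f2 <- .tsvOut(de, file.path(outdir, sprintf("de_%s.tsv", cn)), prov)
        enr <- enrichCollection(ranked, sets, B = config$B,
                                min_size = config$min_size,
                                seed = config$seed, mode = config$mode,
                                p_threshold = config$p_threshold,
                                fdr_threshold = config$fdr_threshold)
        f3 <- .tsvOut(enr,
                      file.path(outdir, sprintf("enrichment_%s.tsv", cn)),
                      prov)
        done(paste0("contrast_", cn), c(f1, f2, f3))
    }

    ## --- lipidomics panels ---
    if (!is.null(lipids)) {
        tmm <- tmmFactors(lipids)
        f <- .tsvOut(data.frame(sample_id = names(tmm), tmm_factor = tmm),
                     file.path(outdir, "lipid_tmm_factors.tsv"), prov)
        ab <- classRelativeAbundance(lipids, "class")
        f2 <- .tsvOut(data.frame(feature = rownames(ab), ab,
                                 check.names = FALSE),
                      file.path(outdir, "lipid_class_abundance.tsv"), prov)
        sat <- saturationProfile(lipids, by_class = TRUE)
        f3 <- .tsvOut(sat, file.path(outdir, "lipid_saturation.tsv"), prov)
        lip_contrasts <- canonicalContrasts(
            data.frame(sample_id = colnames(lipids),
                       sex = as.character(colData(lipids)$sex),
                       maternal_diet = as.character(
                           colData(lipids)$maternal_diet)))
        fcs <- lapply(names(lip_contrasts), function(cn) {
            d <- groupFoldChanges(lipids, lip_contrasts[[cn]])
            d$contrast <- cn
            d
        })
        f4 <- .tsvOut(do.call(rbind, fcs),
                      file.path(outdir, "lipid_fold_changes.tsv"), prov)
        done("lipidomics", c(f, f2, f3, f4))
    }

    ## --- phenotyping ---
    if (!is.null(phen)) {
        idx <- phenotypeIndices(phen)
        f <- .tsvOut(idx, file.path(outdir, "phenotype_indices.tsv"), prov)
        done("phenotyping", f)
    }

    manifest$contrasts <- names(contrasts)
    manifest$outdir <- outdir
    invisible(manifest)
}

#' Cross-contrast summary of a pipeline run
#'
#' From a completed run directory: the per-set MES and significance across
#' the four contrasts (sex contrasts side by side with diet contrasts), and
#' the exact Venn partition of DE genes across contrasts (one count per
#' membership pattern; the counts sum to the union size).
#'
#' @param outdir the pipeline output directory (containing manifest.json).
#' @return list: \code{mes_summary} (data.frame set_id x per-contrast MES /
#'   significant columns), \code{venn} (data.frame pattern, contrasts,
#'   count), \code{de_counts} (named integer, DE genes per contrast).
#' @export
summarizeResults <- function(outdir) {
    mpath <- file.path(outdir, "manifest.json")
    if (!file.exists(mpath)) stop("no manifest.json in ", outdir)
    manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    contrasts <- manifest$contrasts
    if (is.null(contrasts)) stop("manifest has no contrasts (run incomplete)")
    readStage <- function(prefix, cn) {
        path <- file.path(outdir, sprintf("%s_%s.tsv", prefix, cn))
        if (!file.exists(path)) stop("missing stage output: ", path)
        utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    }
    enr <- lapply(contrasts, readStage, prefix = "enrichment")
    names(enr) <- contrasts
    ids <- sort(unique(unlist(lapply(enr, `[[`, "set_id"))))
    mes_summary <- data.frame(set_id = ids, stringsAsFactors = FALSE)
    for (cn in contrasts) {
        e <- enr[[cn]]
        i <- match(ids, e$set_id)
        mes_summary[[paste0("MES_", cn)]] <- e$MES[i]
        mes_summary[[paste0("sig_", cn)]] <- e$significant[i]
    }
    de <- lapply(contrasts, function(cn) {
        d <- readStage("de", cn)
        d$gene_id[d$de]
    })
    names(de) <- contrasts
    union_genes <- unique(unlist(de))
    venn <- if (length(union_genes)) {
        member <- vapply(de, function(g) union_genes %in% g,
                         logical(length(union_genes)))
        member <- matrix(member, nrow = length(union_genes),
                         dimnames = list(union_genes, contrasts))
        pattern <- apply(member, 1, function(r)
            paste(contrasts[r], collapse = "&"))
        tab <- table(pattern)
        data.frame(contrasts = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE, row.names = NULL)
    } else data.frame(contrasts = character(), count = integer())
    list(mes_summary = mes_summary, venn = venn,
         de_counts = vapply(de, length, integer(1)))
}
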