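#' @importFrom stats rnbinom rlnorm rnorm runif
NULL

## Derive an independent, reproducible substream seed from a top-level seed
## and a generator tag, so adding one generator never perturbs the others.
.substreamSeed <- function(seed, tag) {
    v <- utf8ToInt(tag)
    h <- sum(v * seq_along(v)) %% 100003
    as.integer((abs(as.double(seed)) * 31 + h) %% 2147483587)
}

## Evaluate expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    force(expr)
}

#' Create a planted truth with no effects
#'
#' Baseline per-gene negative-binomial parameters: means drawn log-normally
#' (meanlog 4, sdlog 1.5 by default, i.e. typical RNA-seq-like skew) and a
#' common dispersion.  All planted group shifts start at zero; add effects
#' with \code{\link{plantEffect}}.
#'
#' @param n_genes number of genes.
#' @param seed integer seed (generator substream derived from it).
#' @param dispersion NB dispersion (> 0), recycled per gene.
#' @param meanlog,sdlog log-normal parameters of the baseline means.
#' @param gene_ids optional explicit gene ids (default \code{g00001...}).
#' @return A \linkS4class{PlantedTruth}.
#' @export
simulateTruth <- function(n_genes, seed, dispersion = 0.1,
                          meanlog = 4, sdlog = 1.5, gene_ids = NULL) {
    stopifnot(n_genes >= 1)
    if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n_genes))
    stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
    mu <- .withSeed(.substreamSeed(seed, "truth"),
                    rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog))
    names(mu) <- gene_ids
    disp <- rep_len(dispersion, n_genes)
    names(disp) <- gene_ids
    lfc <- matrix(0, n_genes, 4, dimnames = list(gene_ids, GROUP_LABELS))
    new("PlantedTruth", baselineMean = mu, dispersion = disp,
        groupLog2FC = lfc,
        enrichedSets = data.frame(set_id = character(),
                                  direction = character(),
                                  strength = numeric(),
                                  contrast = character(),
                                  stringsAsFactors = FALSE))
}

#' Plant a per-gene expression shift in selected design groups
#'
#' Adds \code{log2fc} to the planted log2 shift of the given genes in the
#' given groups (additive, so repeated planting accumulates).
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param genes gene ids; must all exist in the truth.
#' @param groups group labels among \code{F-moC, M-moC, F-moHF, M-moHF}.
#' @param log2fc finite numeric scalar or one value per gene.
#' @return The updated truth.
#' @export
plantEffect <- function(truth, genes, groups, log2fc) {
    unknown <- setdiff(genes, names(truth@baselineMean))
    if (length(unknown))
        stop("unknown gene id(s) in truth: ",
             paste(utils::head(unknown, 10), collapse = ", "))
    stopifnot(all(groups %in% GROUP_LABELS), all(is.finite(log2fc)))
    for (g in groups)
        truth@groupLog2FC[genes, g] <- truth@groupLog2FC[genes, g] + log2fc
    validObject(truth)
    truth
}

#' Simulate a count experiment under the 2x2 design
#'
#' Counts are drawn negative-binomially per gene and sample with mean
#' \code{baseline * 2^planted_shift(group)} and the truth's dispersion
#' (variance mu + phi mu^2).  Library depth is held constant across samples so
#' planted fold changes appear directly in the raw counts.  Gene lengths are
#' uniform integers in [500, 10000] bp (used only by RPKM).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param truth a \linkS4class{PlantedTruth}; its genes define the matrix rows.
#' @param seed integer seed; identical (design, truth, seed) give bit-identical
#'   output.
#' @return A \linkS4class{CountExperiment}.
#' @examples
#' truth <- simulateTruth(50, seed = 1)
#' se <- simulateCounts(studyDesign(), truth, seed = 1)
#' dim(se)  # 50 genes x 19 samples
#' @export
simulateCounts <- function(design, truth, seed) {
    stopifnot(is(design, "StudyDesign"), is(truth, "PlantedTruth"))
    st <- sampleTable(design)
    genes <- names(truth@baselineMean)
    n_genes <- length(genes)
    mu_group <- truth@baselineMean * 2^truth@groupLog2FC  # genes x 4
    counts <- .withSeed(.substreamSeed(seed, "counts"), {
        m <- matrix(0L, n_genes, nrow(st),
                    dimnames = list(genes, st$sample_id))
        for (j in seq_len(nrow(st))) {
            mu <- mu_group[, st$group[j]]
            m[, j] <- rnbinom(n_genes, mu = mu,
                              size = 1 / truth@dispersion)
        }
        m
    })
    lengths <- .withSeed(.substreamSeed(seed, "lengths"), {
        l <- sample(500:10000, n_genes, replace = TRUE)
        names(l) <- genes
        l
    })
    countExperiment(counts, lengths, st)
}

## group whose expression is shifted to make a set enriched ("up" = higher in
## the A arm) in each canonical contrast
.CONTRAST_TARGET_GROUP <- c(
    "M_vs_F_moC" = "M-moC", "M_vs_F_moHF" = "M-moHF",
    "moHF_vs_moC_F" = "F-moHF", "moHF_vs_moC_M" = "M-moHF")

#' Simulate a gene-set collection with optional planted enrichments
#'
#' Sets are sampled uniformly from the gene universe.  Planted-enriched sets
#' additionally receive an additive log2 shift on all their members in the
#' design group matching the target contrast, so the enrichment emerges through
#' the real ranking stage rather than by rank surgery.
#'
#' @param n_sets total number of sets (>= 0).
#' @param size_range integer (min, max) member count; min >= 1, max <= universe.
#' @param truth a \linkS4class{PlantedTruth}; updated and returned.
#' @param universe character vector of candidate gene ids.
#' @param seed integer seed.
#' @param n_enriched how many of the sets carry a planted enrichment.
#' @param direction "up" or "down" (sign of the planted shift in the contrast).
#' @param strength absolute planted log2FC given to members (default 2).
#' @param target_contrast one of the canonical contrast names (default
#'   \code{"M_vs_F_moC"}).
#' @param enriched_size optional fixed size for planted sets (default: drawn
#'   like the others).
#' @return list with elements \code{collection} (a
#'   \linkS4class{GeneSetCollection}; planted sets are named
#'   \code{set_enriched_*}) and \code{truth} (updated).
#' @export
simulateGeneSets <- function(n_sets, size_range = c(10L, 50L), truth, universe,
                             seed, n_enriched = 0L, direction = "up",
                             strength = 2, target_contrast = "M_vs_F_moC",
                             enriched_size = NULL) {
    if (size_range[1] > size_range[2])
        stop("size_range is inverted: min > max")
    stopifnot(size_range[1] >= 1, size_range[2] <= length(universe),
              n_enriched <= n_sets,
              direction %in% c("up", "down"),
              target_contrast %in% names(.CONTRAST_TARGET_GROUP))
    if (n_sets == 0L)
        return(list(collection = geneSetCollection(), truth = truth))
    sets <- .withSeed(.substreamSeed(seed, "genesets"), {
        lapply(seq_len(n_sets), function(i) {
            sz <- if (i <= n_enriched && !is.null(enriched_size))
                as.integer(enriched_size)
            else sample(seq(size_range[1], size_range[2]), 1L)
            sort(sample(universe, sz))
        })
    })
    names(sets) <- c(
        sprintf("set_enriched_%02d", seq_len(n_enriched)),
        sprintf("set_null_%02d", seq_len(n_sets - n_enriched))
    )[seq_len(n_sets)]
    desc <- rep("synthetic", n_sets)
    names(desc) <- names(sets)
    if (n_enriched > 0) {
        shift <- if (direction == "up") strength else -strength
        grp <- .CONTRAST_TARGET_GROUP[[target_contrast]]
        for (i in seq_len(n_enriched))
            truth <- plantEffect(truth, sets[[i]], grp, shift)
        truth@enrichedSets <- rbind(truth@enrichedSets, data.frame(
            set_id = names(sets)[seq_len(n_enriched)],
            direction = direction, strength = strength,
            contrast = target_contrast, stringsAsFactors = FALSE))
    }
    list(collection = geneSetCollection(sets, desc), truth = truth)
}

## plausible total-carbon / double-bond ranges per lipid class
.LIPID_CLASS_RANGES <- list(
    TG = list(carbons = seq(46, 60, 2), db = 0:6, sphingoid = FALSE),
    PC = list(carbons = seq(30, 40, 2), db = 0:6, sphingoid = FALSE),
    PE = list(carbons = seq(32, 40, 2), db = 0:6, sphingoid = FALSE),
    LPC = list(carbons = seq(14, 22, 2), db = 0:2, sphingoid = FALSE),
    LPE = list(carbons = seq(16, 22, 2), db = 0:2, sphingoid = FALSE),
    PS = list(carbons = seq(34, 40, 2), db = 0:6, sphingoid = FALSE),
    PG = list(carbons = seq(32, 38, 2), db = 0:4, sphingoid = FALSE),
    CL = list(carbons = seq(64, 72, 2), db = 2:8, sphingoid = FALSE),
    PI = list(carbons = seq(34, 40, 2), db = 0:6, sphingoid = FALSE),
    LPI = list(carbons = seq(16, 20, 2), db = 0:2, sphingoid = FALSE),
    Cer = list(carbons = seq(34, 42, 2), db = 0:2, sphingoid = TRUE),
    SM = list(carbons = seq(34, 42, 2), db = 0:3, sphingoid = TRUE),
    GlcCer = list(carbons = seq(34, 42, 2), db = 0:2, sphingoid = TRUE)
)

#' Simulate a lipid species intensity table
#'
#' Emits species whose names follow the CLASS(C:DB) grammar (CLASS(dC:DB) for
#' sphingoid classes), with carbons and double bonds drawn from class-plausible
#' ranges, and strictly positive log-normal intensities (per-species baseline
#' around 1e6 with per-sample biological noise).
#'
#' @param classes lipid classes to emit (subset of the supported grammar).
#' @param species_per_class species per class (capped at the number of
#'   distinct carbon:DB combinations of the class).
#' @param design a \linkS4class{StudyDesign}.
#' @param seed integer seed.
#' @param class_ranges optional override of the carbon/double-bond ranges.
#' @return A \linkS4class{LipidSpeciesTable}.
#' @export
simulateLipidTable <- function(classes = c("TG", "PC", "PE", "Cer", "SM", "PI"),
                               species_per_class = 8L, design = studyDesign(),
                               seed = 1L, class_ranges = .LIPID_CLASS_RANGES) {
    bad <- setdiff(classes, names(class_ranges))
    if (length(bad))
        stop("unsupported lipid class label(s): ", paste(bad, collapse = ", "))
    st <- sampleTable(design)
    .withSeed(.substreamSeed(seed, "lipids"), {
        species <- unlist(lapply(classes, function(cl) {
            rng <- class_ranges[[cl]]
            combos <- expand.grid(c = rng$carbons, d = rng$db)
            combos <- combos[combos$d <= combos$c, , drop = FALSE]
            pick <- combos[sample(nrow(combos),
                                  min(species_per_class, nrow(combos))), ]
            sprintf("%s(%s%d:%d)", cl, if (rng$sphingoid) "d" else "",
                    pick$c, pick$d)
        }))
        base <- rlnorm(length(species), meanlog = log(1e6), sdlog = 1)
        noise <- matrix(rlnorm(length(species) * nrow(st), 0, 0.3),
                        length(species), nrow(st))
        intens <- base * noise
        dimnames(intens) <- list(species, st$sample_id)
        lipidSpeciesTable(intens,
                          sampleData = data.frame(
                              sex = st$sex, maternal_diet = st$maternal_diet,
                              row.names = st$sample_id))
    })
}

#' Simulate metabolic phenotyping measurements
#'
#' Emulates an oral-glucose-tolerance-test campaign: per animal, glucose and
#' insulin at exactly T0, T15, T30, T60 and T120 min (rise to a peak around
#' 15-30 min, then decay), plus MRI-style body composition (body weight,
#' total / subcutaneous / visceral fat with SAT + VAT = TF by construction).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param seed integer seed.
#' @return Long-format data.frame with columns \code{sample_id},
#'   \code{variable}, \code{time_min} (NA for non-timecourse variables) and
#'   \code{value}.
#' @export
simulatePhenotypes <- function(design = studyDesign(), seed = 1L) {
    st <- sampleTable(design)
    times <- c(0, 15, 30, 60, 120)
    glc_shape <- c(1, 2.2, 2.0, 1.5, 1.1)
    ins_shape <- c(1, 2.6, 2.2, 1.6, 1.2)
    .withSeed(.substreamSeed(seed, "phenotypes"), {
        rows <- lapply(seq_len(nrow(st)), function(i) {
            male <- st$sex[i] == "M"
            glc0 <- max(3, rnorm(1, 8, 1))
            ins0 <- rlnorm(1, log(1.2), 0.3)
            glc <- glc0 * glc_shape * rlnorm(5, 0, 0.06)
            ins <- ins0 * ins_shape * rlnorm(5, 0, 0.10)
            bw <- max(15, rnorm(1, if (male) 35 else 28, if (male) 3 else 2))
            tf <- bw * runif(1, 0.15, 0.35)
            sat <- tf * min(0.9, max(0.1,
                rnorm(1, if (male) 0.45 else 0.55, 0.05)))
            vat <- tf - sat
            rbind(
                data.frame(sample_id = st$sample_id[i], variable = "glucose",
                           time_min = times, value = glc),
                data.frame(sample_id = st$sample_id[i], variable = "insulin",
                           time_min = times, value = ins),
                data.frame(sample_id = st$sample_id[i],
                           variable = c("body_weight", "total_fat",
                                        "sat_fat", "vat_fat"),
                           time_min = NA_real_,
                           value = c(bw, tf, sat, vat)))
        })
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    })
}

#' Simulate a complete synthetic study
#'
#' One call producing every pipeline input with consistent planted truth:
#' counts (with a planted-enriched gene set whose members are shifted in the
#' target contrast), gene sets, lipid table and phenotypes.  All generators
#' draw from independent substreams of \code{seed}.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_sets number of gene sets (default 20).
#' @param n_enriched number of planted-enriched sets (default 1).
#' @param enriched_size members per planted set (default 50).
#' @param strength planted absolute log2FC on planted members (default 2).
#' @param direction "up" or "down".
#' @param target_contrast canonical contrast carrying the planted enrichment.
#' @param design a \linkS4class{StudyDesign}.
#' @param seed integer seed.
#' @return list: \code{counts} (\linkS4class{CountExperiment}), \code{sets}
#'   (\linkS4class{GeneSetCollection}), \code{truth}
#'   (\linkS4class{PlantedTruth}), \code{lipids}
#'   (\linkS4class{LipidSpeciesTable}), \code{phenotypes} (data.frame).
#' @examples
#' study <- simulateStudy(n_genes = 200, n_sets = 5, seed = 7)
#' study$counts
#' @export
simulateStudy <- function(n_genes = 2000L, n_sets = 20L, n_enriched = 1L,
                          enriched_size = 50L, strength = 2, direction = "up",
                          target_contrast = "M_vs_F_moC",
                          design = studyDesign(), seed = 1L) {
    truth <- simulateTruth(n_genes, seed = seed)
    gs <- simulateGeneSets(n_sets, size_range = c(10L, 50L), truth = truth,
                           universe = names(truth@baselineMean), seed = seed,
                           n_enriched = n_enriched, direction = direction,
                           strength = strength,
                           target_contrast = target_contrast,
                           enriched_size = enriched_size)
    counts <- simulateCounts(design, gs$truth, seed = seed)
    lipids <- simulateLipidTable(design = design, seed = seed)
    phen <- simulatePhenotypes(design = design, seed = seed)
    list(counts = counts, sets = gs$collection, truth = gs$truth,
         lipids = lipids, phenotypes = phen)
}
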