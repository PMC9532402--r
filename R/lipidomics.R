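#' Parse lipid species names
#'
#' Accepts the CLASS(C:DB) grammar ("TG(54:3)"), the sphingoid variant
#' CLASS(dC:DB) ("Cer(d34:1)"), and class-level labels like "TG54" (total
#' carbons only, double bonds unset).  Supported classes: TG, PC, PE, LPC,
#' LPE, PS, PG, CL, PI, LPI, Cer, GlcCer, SM.
#'
#' @param names character vector of species names.
#' @return data.frame: name, lipid_class, total_carbons, double_bonds (NA for
#'   class-level labels), sphingoid.
#' @examples
#' parseLipidSpecies(c("TG(54:3)", "Cer(d34:1)", "TG54"))
#' @export
parseLipidSpecies <- function(names) {
    if (!length(names) || any(!nzchar(names)))
        stop("species names must be non-empty strings")
    full <- "^([A-Za-z]+)\\((d?)([0-9]+):([0-9]+)\\)$"
    classlevel <- "^([A-Za-z]+)([0-9]+)$"
    parse1 <- function(nm) {
        if (grepl(full, nm)) {
            cl <- sub(full, "\\1", nm)
            if (!cl %in% LIPID_CLASSES)
                stop(sprintf("unknown lipid class '%s' in '%s' (position 1)",
                             cl, nm))
            sph <- sub(full, "\\2", nm) == "d"
            c_tot <- as.integer(sub(full, "\\3", nm))
            db <- as.integer(sub(full, "\\4", nm))
            if (db > c_tot)
                stop(sprintf("'%s': double bonds exceed carbons", nm))
            return(data.frame(name = nm, lipid_class = cl,
                              total_carbons = c_tot, double_bonds = db,
                              sphingoid = sph, stringsAsFactors = FALSE))
        }
        if (grepl(classlevel, nm)) {
            cl <- sub(classlevel, "\\1", nm)
            if (!cl %in% LIPID_CLASSES)
                stop(sprintf("unknown lipid class '%s' in '%s' (position 1)",
                             cl, nm))
            return(data.frame(name = nm, lipid_class = cl,
                              total_carbons = as.integer(sub(classlevel, "\\2", nm)),
                              double_bonds = NA_integer_,
                              sphingoid = FALSE, stringsAsFactors = FALSE))
        }
        stop(sprintf(
            "malformed species name '%s' (expected CLASS(C:DB), CLASS(dC:DB) or CLASSnn; failed at position %d)",
            nm, attr(regexpr("^[A-Za-z]+", nm), "match.length") + 1L))
    }
    out <- do.call(rbind, lapply(names, parse1))
    rownames(out) <- NULL
    out
}

#' Canonical species name from parsed fields
#'
#' Inverse of \code{\link{parseLipidSpecies}} on canonical names.
#'
#' @param parsed data.frame with columns lipid_class, total_carbons,
#'   double_bonds, sphingoid.
#' @return Character vector of canonical names.
#' @export
formatLipidSpecies <- function(parsed) {
    ifelse(is.na(parsed$double_bonds),
           sprintf("%s%d", parsed$lipid_class, parsed$total_carbons),
           sprintf("%s(%s%d:%d)", parsed$lipid_class,
                   ifelse(parsed$sphingoid, "d", ""),
                   parsed$total_carbons, parsed$double_bonds))
}

#' Intensity / mass-accuracy peak filter
#'
#' Retains peaks with raw intensity strictly greater than
#' \code{min_intensity} ("higher than 1e4") and absolute mass error within
#' \code{max_ppm} ppm inclusive ("within 5 ppm").  Row order is preserved;
#' the filter is idempotent.
#'
#' @param peaks data.frame with columns \code{raw_intensity} (> 0) and
#'   \code{mass_error_ppm}.
#' @param min_intensity strict lower intensity bound (default 1e4).
#' @param max_ppm inclusive absolute mass-error bound (default 5).
#' @return The retained rows of \code{peaks}.
#' @export
filterPeaks <- function(peaks, min_intensity = 1e4, max_ppm = 5) {
    stopifnot(min_intensity > 0, max_ppm > 0)
    need <- c("raw_intensity", "mass_error_ppm")
    if (!all(need %in% colnames(peaks)))
        stop("peaks need columns: ", paste(need, collapse = ", "))
    if (!nrow(peaks)) return(peaks)
    if (any(peaks$raw_intensity <= 0))
        stop("raw intensities must be positive")
    keep <- peaks$raw_intensity > min_intensity &
        abs(peaks$mass_error_ppm) <= max_ppm
    peaks[keep, , drop = FALSE]
}

.lipidIntensity <- function(table) {
    stopifnot(is(table, "LipidSpeciesTable"))
    if (!nrow(table)) stop("empty lipid table")
    assay(table, "intensity")
}

#' Relative abundance per lipid class / carbon-class / species
#'
#' Aggregates intensities at the chosen level and converts each sample to
#' fractions of its total (simplex vectors summing to 1).  "carbon-class"
#' groups species by class and total carbons ("TG54" pools TG(54:1),
#' TG(54:3), ...), matching class-level reporting of triacylglycerols.
#'
#' @param table a \linkS4class{LipidSpeciesTable}.
#' @param level "class", "carbon-class" or "species".
#' @return Features x samples matrix of fractions; columns sum to 1.
#' @export
classRelativeAbundance <- function(table,
                                   level = c("class", "carbon-class", "species")) {
    level <- match.arg(level)
    m <- .lipidIntensity(table)
    rd <- rowData(table)
    key <- switch(level,
                  class = as.character(rd$lipid_class),
                  `carbon-class` = sprintf("%s%d", rd$lipid_class,
                                           rd$total_carbons),
                  species = rownames(m))
    agg <- rowsum(m, group = key)
    tot <- colSums(agg)
    if (any(tot == 0))
        stop("all-zero sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    sweep(agg, 2, tot, "/")
}

#' Double-bond saturation profile
#'
#' For each sample (and each lipid class when \code{by_class}), the fraction
#' of summed intensity carried by each double-bond count; fractions sum to 1
#' within each sample (and class).
#'
#' @param table a \linkS4class{LipidSpeciesTable}; every species must have
#'   double bonds set.
#' @param by_class stratify by lipid class (default FALSE).
#' @return Long data.frame: lipid_class ("all" when not stratified),
#'   double_bonds, sample_id, fraction.
#' @export
saturationProfile <- function(table, by_class = FALSE) {
    m <- .lipidIntensity(table)
    rd <- rowData(table)
    unset <- rownames(m)[is.na(rd$double_bonds)]
    if (length(unset))
        stop("species without double-bond count: ",
             paste(unset, collapse = ", "))
    cls <- if (by_class) as.character(rd$lipid_class)
           else rep("all", nrow(m))
    out <- do.call(rbind, lapply(unique(cls), function(cl) {
        sel <- cls == cl
        agg <- rowsum(m[sel, , drop = FALSE], group = rd$double_bonds[sel])
        tot <- colSums(agg)
        if (any(tot == 0))
            stop("all-zero sample(s) in class ", cl, ": ",
                 paste(colnames(m)[tot == 0], collapse = ", "))
        frac <- sweep(agg, 2, tot, "/")
        data.frame(lipid_class = cl,
                   double_bonds = rep(as.integer(rownames(agg)), ncol(frac)),
                   sample_id = rep(colnames(frac), each = nrow(frac)),
                   fraction = as.vector(frac), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Per-feature group fold changes with Holm-Sidak correction
#'
#' Log fold change of group mean intensities (zero means floored at half the
#' smallest positive value in the table so every feature stays defined),
#' unpaired two-tailed Welch t-test per feature, and Holm-Sidak adjustment
#' across all features of the panel.
#'
#' @param table a \linkS4class{LipidSpeciesTable}.
#' @param contrast a \linkS4class{Contrast} over the table's samples.
#' @param base "log10" (heatmap convention) or "log2".
#' @param alpha Holm-Sidak level (default 0.05).
#' @return data.frame: species, logFC, p, p_adj, reject.
#' @export
groupFoldChanges <- function(table, contrast, base = c("log10", "log2"),
                             alpha = 0.05) {
    base <- match.arg(base)
    m <- .lipidIntensity(table)
    .contrastColumns(m, contrast)
    a <- m[, contrast@groupA, drop = FALSE]
    b <- m[, contrast@groupB, drop = FALSE]
    floor_eps <- min(m[m > 0]) / 2
    ma <- pmax(rowMeans(a), floor_eps)
    mb <- pmax(rowMeans(b), floor_eps)
    lfc <- if (base == "log10") log10(ma / mb) else log2(ma / mb)
    va <- apply(a, 1, var); vb <- apply(b, 1, var)
    na <- ncol(a); nb <- ncol(b)
    se2 <- va / na + vb / nb
    tt <- (rowMeans(a) - rowMeans(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(tt), df)
    degen <- se2 == 0
    p[degen & rowMeans(a) == rowMeans(b)] <- 1
    p[degen & rowMeans(a) != rowMeans(b)] <- 0
    hs <- holmSidak(p, alpha = alpha)
    data.frame(species = rownames(m), logFC = unname(lfc), p = unname(p),
               p_adj = hs$adjusted, reject = hs$reject,
               stringsAsFactors = FALSE, row.names = NULL)
}

## default product/precursor pairs for desaturase activity indices
.DESATURASE_PAIRS <- list(
    delta9_C18 = c(product = "C18:1n-9", precursor = "C18:0"),
    delta9_C16 = c(product = "C16:1n-7", precursor = "C16:0"),
    delta5 = c(product = "C20:4n-6", precursor = "C20:3n-6"),
    delta6 = c(product = "C18:3n-6", precursor = "C18:2n-6"))

#' Desaturase activity indices from fatty-acid abundances
#'
#' Estimated product/precursor ratios: Delta-9 = C18:1n-9 / C18:0 (switchable
#' to C16:1n-7 / C16:0), Delta-5 = C20:4n-6 / C20:3n-6, and optionally
#' Delta-6 = C18:3n-6 / C18:2n-6.  These are abundance-ratio indices, not
#' measured enzyme activities.  A missing precursor or product yields an
#' undefined-flagged NA, not an error.
#'
#' @param fa named numeric vector of fatty-acid relative abundances for one
#'   sample, or a fatty-acid x samples matrix (rownames like "C18:0",
#'   "C20:4n-6").
#' @param delta9 which Delta-9 pair to use: "C18" (default) or "C16".
#' @param include_delta6 also report Delta-6 (default FALSE).
#' @return data.frame: index, sample_id, value, defined.
#' @export
desaturaseIndices <- function(fa, delta9 = c("C18", "C16"),
                              include_delta6 = FALSE) {
    delta9 <- match.arg(delta9)
    m <- if (is.matrix(fa)) fa else
        matrix(fa, ncol = 1, dimnames = list(names(fa), "sample1"))
    if (any(m < 0)) stop("fatty-acid abundances must be non-negative")
    pairs <- c(.DESATURASE_PAIRS[paste0("delta9_", delta9)],
               .DESATURASE_PAIRS["delta5"],
               if (include_delta6) .DESATURASE_PAIRS["delta6"])
    names(pairs)[1] <- "delta9"
    out <- do.call(rbind, lapply(names(pairs), function(ix) {
        pr <- pairs[[ix]]
        ok <- all(pr %in% rownames(m))
        vals <- if (ok) {
            v <- m[pr[["product"]], ] / m[pr[["precursor"]], ]
            ifelse(is.finite(v), v, NA_real_)
        } else rep(NA_real_, ncol(m))
        data.frame(index = ix, sample_id = colnames(m), value = unname(vals),
                   defined = ok & is.finite(vals),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
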