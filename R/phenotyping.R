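#' Trapezoidal area under a tolerance-test curve
#'
#' Standard trapezoidal rule over the measured timepoints (T0 included), as
#' used to summarize glucose and insulin excursions of the oral glucose and
#' insulin tolerance tests.  Units: analyte unit x minutes.
#'
#' @param times strictly increasing timepoints in minutes, starting at 0.
#' @param values positive analyte values, one per timepoint.
#' @return The area (scalar).
#' @examples
#' aucTrapezoid(c(0, 15, 30, 60, 120), c(5, 10, 10, 7, 5))  # 877.5
#' @export
aucTrapezoid <- function(times, values) {
    if (length(times) < 2L)
        stop("at least 2 timepoints are required")
    stopifnot(length(times) == length(values))
    if (any(diff(times) <= 0) || times[1] != 0)
        stop("times must be strictly increasing and start at 0")
    if (any(!is.finite(values)) || any(values <= 0))
        stop("values must be finite and positive")
    pracma::trapz(times, values)
}

#' Quantitative insulin-sensitivity check index
#'
#' QUICKI = 1 / (log10(insulin_T0) + log10(glucose_T0)), with base-10
#' logarithms (the original index convention).  Higher values mean higher
#' insulin sensitivity.
#'
#' @param glucose_t0,insulin_t0 fasting glucose and insulin (> 0); vectorized.
#' @return Numeric vector of indices.
#' @examples
#' quicki(glucose_t0 = 100, insulin_t0 = 10)  # 1/(2 + 1) = 1/3
#' @export
quicki <- function(glucose_t0, insulin_t0) {
    if (any(glucose_t0 <= 0) || any(insulin_t0 <= 0))
        stop("fasting glucose and insulin must be positive")
    den <- log10(insulin_t0) + log10(glucose_t0)
    if (any(den == 0))
        stop("log10(insulin) + log10(glucose) is zero; QUICKI undefined")
    1 / den
}

#' MRI body-composition ratios
#'
#' From body weight (BW), total fat (TF) and subcutaneous fat (SAT), with
#' visceral fat derived as VAT = TF - SAT, computes TF/BW, VAT/TF, SAT/TF and
#' the SAT:VAT ratio.  VAT/TF + SAT/TF = 1 by construction.  Degenerate
#' denominators (TF = 0, VAT = 0) give flagged NA values, not errors.
#'
#' @param bw body weight (> 0); vectorized.
#' @param tf total fat (>= 0, <= bw).
#' @param sat subcutaneous fat (>= 0, <= tf).
#' @return data.frame: tf_bw, vat_tf, sat_tf, sat_vat, tf_defined,
#'   sat_vat_defined.
#' @examples
#' bodyCompositionRatios(bw = 40, tf = 10, sat = 6)  # 0.25, 0.4, 0.6, 1.5
#' @export
bodyCompositionRatios <- function(bw, tf, sat) {
    if (any(bw <= 0)) stop("body weight must be positive")
    if (any(tf < 0) || any(tf > bw))
        stop("total fat must satisfy 0 <= TF <= BW")
    if (any(sat < 0) || any(sat > tf))
        stop("subcutaneous fat must satisfy 0 <= SAT <= TF")
    vat <- tf - sat
    tf_ok <- tf > 0
    vat_ok <- vat > 0
    data.frame(
        tf_bw = tf / bw,
        vat_tf = ifelse(tf_ok, vat / tf, NA_real_),
        sat_tf = ifelse(tf_ok, sat / tf, NA_real_),
        sat_vat = ifelse(vat_ok, sat / vat, NA_real_),
        tf_defined = tf_ok,
        sat_vat_defined = vat_ok)
}

#' Default MRS lipid-peak grouping
#'
#' The grouping of the nine liver proton-MRS lipid resonances into saturated
#' (methyl/methylene chain signals), mono-unsaturated (allylic and olefinic)
#' and poly-unsaturated (diallylic) components, shipped as a plain-text
#' config (\code{inst/extdata/mrs_peak_groups.tsv}).  The assignment is an
#' approximation by chemical shift; edit the config to match an acquisition's
#' peak basis.
#'
#' @return Named list of character vectors: \code{fSL}, \code{fMUL},
#'   \code{fPUL}.
#' @export
defaultMrsGroups <- function() {
    path <- system.file("extdata", "mrs_peak_groups.tsv", package = "mesea",
                        mustWork = TRUE)
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    split(df$label, factor(df$fraction, levels = c("fSL", "fMUL", "fPUL")))
}

#' Hepatic lipid fractions from localized proton MRS peaks
#'
#' Peaks whose fit has an estimated relative standard deviation of 20 percent
#' or more are excluded first (the quality filter keeps SD < 20).  Then
#' fLM = sum(lipid areas) / (sum(lipid areas) + water area) estimates the
#' hepatic lipid mass fraction, and fSL / fMUL / fPUL are the saturated,
#' mono-unsaturated and poly-unsaturated fractions of the classified lipid
#' signal (summing to 1 over classified peaks).
#'
#' @param peaks data.frame with columns \code{label}, \code{area} (>= 0),
#'   \code{sd_percent} (>= 0); the lipid resonances.
#' @param water_area water reference peak area (> 0).
#' @param groups peak-label grouping, as from \code{\link{defaultMrsGroups}}.
#' @return data.frame (one row): fLM, fSL, fMUL, fPUL, n_peaks_used.
#' @export
mrsLipidFractions <- function(peaks, water_area, groups = defaultMrsGroups()) {
    need <- c("label", "area", "sd_percent")
    if (!all(need %in% colnames(peaks)))
        stop("peaks need columns: ", paste(need, collapse = ", "))
    if (any(peaks$area < 0) || any(peaks$sd_percent < 0))
        stop("areas and sd_percent must be non-negative")
    if (length(water_area) != 1L || water_area <= 0)
        stop("water area must be a positive scalar")
    ok <- peaks$sd_percent < 20
    if (!any(ok))
        stop("no peaks pass SD filter")
    kept <- peaks[ok, , drop = FALSE]
    lipid_total <- sum(kept$area)
    flm <- lipid_total / (lipid_total + water_area)
    grp_sum <- vapply(groups, function(lbl) sum(kept$area[kept$label %in% lbl]),
                      numeric(1))
    classified <- sum(grp_sum)
    fr <- if (classified > 0) grp_sum / classified
          else stats::setNames(rep(NA_real_, 3), names(groups))
    data.frame(fLM = flm, fSL = unname(fr[["fSL"]]),
               fMUL = unname(fr[["fMUL"]]), fPUL = unname(fr[["fPUL"]]),
               n_peaks_used = nrow(kept))
}

#' Per-animal phenotype indices from a long-format phenotype table
#'
#' Computes, for every animal in a table as produced by
#' \code{\link{simulatePhenotypes}}: glucose and insulin AUC over the
#' tolerance-test timepoints, QUICKI from the T0 values, and the MRI
#' body-composition ratios.
#'
#' @param phenotypes long data.frame: sample_id, variable, time_min, value.
#' @return data.frame, one row per animal: sample_id, auc_glucose,
#'   auc_insulin, quicki, tf_bw, vat_tf, sat_tf, sat_vat.
#' @export
phenotypeIndices <- function(phenotypes) {
    ids <- unique(phenotypes$sample_id)
    out <- lapply(ids, function(id) {
        px <- phenotypes[phenotypes$sample_id == id, ]
        grab <- function(v) {
            d <- px[px$variable == v & !is.na(px$time_min), ]
            d <- d[order(d$time_min), ]
            d
        }
        scalar <- function(v) px$value[px$variable == v & is.na(px$time_min)][1]
        glc <- grab("glucose"); ins <- grab("insulin")
        bc <- bodyCompositionRatios(scalar("body_weight"),
                                    scalar("total_fat"), scalar("sat_fat"))
        data.frame(sample_id = id,
                   auc_glucose = aucTrapezoid(glc$time_min, glc$value),
                   auc_insulin = aucTrapezoid(ins$time_min, ins$value),
                   quicki = quicki(glc$value[glc$time_min == 0],
                                   ins$value[ins$time_min == 0]),
                   bc[, c("tf_bw", "vat_tf", "sat_tf", "sat_vat")],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
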