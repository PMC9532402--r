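#' @importFrom stats p.adjust lm aov TukeyHSD dhyper
#' @importFrom car Anova
NULL

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' q_(k) = min over j >= k of (m * p_(j) / j), clipped at 1, returned in the
#' original order (a thin wrapper over \code{p.adjust(..., "BH")} with input
#' validation).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bhFdr <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorted ascending, the k-th adjusted p is
#' max over j <= k of (1 - (1 - p_(j))^(m - j + 1)), clipped at 1; rejections
#' are taken at \code{alpha} on the adjusted values.  Output tracks the input
#' order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha family-wise error level (default 0.05).
#' @return list: \code{adjusted} (numeric, input order), \code{reject}
#'   (logical, input order).
#' @examples
#' holmSidak(c(0.01, 0.04))$adjusted  # 0.0199, 0.04
#' @export
holmSidak <- function(p, alpha = 0.05) {
    if (any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    step <- 1 - (1 - ps)^(m - seq_len(m) + 1)
    adj <- pmin(cummax(step), 1)
    out <- numeric(m)
    out[o] <- adj
    list(adjusted = out, reject = out < alpha)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' With both margins fixed, sums the hypergeometric probabilities of all
#' tables at most as probable as the observed one (the "method of small
#' p-values", with the standard 1e-7 relative tolerance for floating-point
#' probability ties -- the convention of standard exact-test
#' implementations).
#'
#' @param tab 2x2 matrix of non-negative integer counts; all margins > 0.
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(0, 5, 5, 0), 2))  # 2/choose(10,5) = 2/252
#' @export
fisherExact2x2 <- function(tab) {
    tab <- as.matrix(tab)
    if (!identical(dim(tab), c(2L, 2L)) &&
        !identical(dim(tab), as.integer(c(2, 2))))
        stop("a 2x2 table is required")
    if (any(tab < 0) || any(tab != round(tab)))
        stop("table entries must be non-negative integers")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("all margins must be positive")
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    support <- max(0, r1 - c2):min(r1, c1)
    d <- dhyper(support, c1, c2, r1)
    d_obs <- dhyper(tab[1, 1], c1, c2, r1)
    min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

.checkFactorial <- function(observations) {
    need <- c("value", "sex", "maternal_diet")
    if (!all(need %in% colnames(observations)))
        stop("observations need columns: ", paste(need, collapse = ", "))
    obs <- data.frame(
        value = as.numeric(observations$value),
        sex = factor(as.character(observations$sex), levels = SEX_LEVELS),
        maternal_diet = factor(as.character(observations$maternal_diet),
                               levels = DIET_LEVELS))
    if (any(!is.finite(obs$value))) stop("values must be finite")
    cells <- table(obs$sex, obs$maternal_diet)
    empty <- which(cells == 0, arr.ind = TRUE)
    if (nrow(empty))
        stop("empty design cell(s): ",
             paste(sprintf("%s/%s", rownames(cells)[empty[, 1]],
                           colnames(cells)[empty[, 2]]), collapse = ", "))
    if (sum(cells >= 2) < 3)
        stop("at least 3 of the 4 cells need >= 2 observations")
    obs
}

#' Two-way ANOVA for the sex x maternal-diet design
#'
#' Type-III sums of squares with sum-to-zero contrasts (the GraphPad-style
#' analysis, well-defined on unbalanced cells such as the 5/5/6/3 design),
#' testing the sex main effect, the maternal-diet main effect and their
#' interaction.
#'
#' @param observations data.frame with columns \code{value}, \code{sex}
#'   (F/M), \code{maternal_diet} (moC/moHF); every cell occupied, at least 3
#'   cells with >= 2 observations.
#' @return data.frame: effect (sex, maternal_diet, interaction), F, df, p.
#' @export
twoWayAnova <- function(observations) {
    obs <- .checkFactorial(observations)
    fit <- lm(value ~ sex * maternal_diet, data = obs,
              contrasts = list(sex = "contr.sum",
                               maternal_diet = "contr.sum"))
    aa <- car::Anova(fit, type = 3)
    idx <- c("sex", "maternal_diet", "sex:maternal_diet")
    data.frame(effect = c("sex", "maternal_diet", "interaction"),
               F = aa[idx, "F value"],
               df = aa[idx, "Df"],
               p = aa[idx, "Pr(>F)"],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Tukey multiple-comparison test among the four design groups
#'
#' Run only when the two-way ANOVA flags any effect at p < \code{trigger_p}
#' (the gate is part of the contract); otherwise an explicit "not triggered"
#' result is returned.  Uses the studentized range on the four sex x diet
#' groups (Tukey-Kramer harmonic-mean adjustment on unbalanced groups).
#'
#' @param observations as for \code{\link{twoWayAnova}}.
#' @param trigger_p ANOVA gate (default 0.05).
#' @return list: \code{triggered} (logical), \code{anova} (the gating table),
#'   \code{pairs} (data.frame comparison, diff, lwr, upr, p_adj; NULL when
#'   not triggered).
#' @export
tukeyHsd <- function(observations, trigger_p = 0.05) {
    an <- twoWayAnova(observations)
    if (!any(an$p < trigger_p, na.rm = TRUE))
        return(list(triggered = FALSE, anova = an, pairs = NULL))
    obs <- .checkFactorial(observations)
    obs$group <- factor(paste(obs$sex, obs$maternal_diet, sep = "-"))
    hsd <- TukeyHSD(aov(value ~ group, data = obs))$group
    list(triggered = TRUE, anova = an,
         pairs = data.frame(comparison = rownames(hsd),
                            diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                            upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                            row.names = NULL, stringsAsFactors = FALSE))
}
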