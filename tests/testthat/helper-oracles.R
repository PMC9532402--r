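# Independent reference implementations used as oracles.  These deliberately
# take the most direct route (full prefix-sum scans, double loops, exhaustive
# enumeration) so they share no code path with the package.

# full O(N) prefix-sum scan of the running sum over a membership mask
bruteMes <- function(member, mode = "signed_extremum") {
    N <- length(member)
    G <- sum(member)
    x <- ifelse(member, sqrt((N - G) / G), -sqrt(G / (N - G)))
    s <- cumsum(x)
    if (mode == "literal_max") return(max(s))
    if (max(s) >= -min(s)) max(s) else min(s)
}

# exhaustive two-sided permutation p over all C(N, G) membership patterns
exhaustiveMesP <- function(member, mode = "signed_extremum") {
    N <- length(member)
    G <- sum(member)
    obs <- bruteMes(member, mode)
    pats <- utils::combn(N, G)
    null <- apply(pats, 2, function(pos) {
        m <- rep(FALSE, N); m[pos] <- TRUE
        bruteMes(m, mode)
    })
    mean(abs(null) >= abs(obs))
}

# min-over-tail BH by double loop
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (k in seq_len(m)) {
        tail_terms <- vapply(k:m, function(j) (m / j) * ps[j], numeric(1))
        q[k] <- min(1, min(tail_terms))
    }
    out <- numeric(m)
    out[o] <- q
    out
}

# step-down Sidak by double loop
bruteHolmSidak <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    for (k in seq_len(m)) {
        terms <- vapply(seq_len(k), function(j) 1 - (1 - ps[j])^(m - j + 1),
                        numeric(1))
        adj[k] <- min(1, max(terms))
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

# step-by-step trimmed-mean-of-M evaluation (Robinson-Oshlack definition:
# 30% two-sided trim on M, 5% on A, inverse asymptotic-variance weights,
# reference = column whose 0.75-quantile count fraction is closest to the
# mean of those fractions; factors renormalized to geometric mean 1)
bruteTmm <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
    lib <- colSums(counts)
    q75 <- apply(counts, 2, function(y) quantile(y, 0.75)) / lib
    ref <- which.min(abs(q75 - mean(q75)))
    yr <- counts[, ref]; nr <- lib[ref]
    one <- function(k) {
        yk <- counts[, k]; nk <- lib[k]
        keep <- yk > 0 & yr > 0
        M <- log2((yk[keep] / nk) / (yr[keep] / nr))
        A <- 0.5 * log2((yk[keep] / nk) * (yr[keep] / nr))
        w <- 1 / ((nk - yk[keep]) / (nk * yk[keep]) +
                  (nr - yr[keep]) / (nr * yr[keep]))
        n <- length(M)
        loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
        loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
        inside <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
        2^(sum(w[inside] * M[inside]) / sum(w[inside]))
    }
    f <- vapply(seq_len(ncol(counts)), one, numeric(1))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(counts)
    f
}

# two-sided Fisher p by enumeration with choose() products (independent of
# dhyper); same small-p-values convention with the standard tie tolerance
bruteFisherP <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    N <- sum(tab)
    support <- max(0, r1 - c2):min(r1, c1)
    pr <- vapply(support, function(a)
        choose(c1, a) * choose(c2, r1 - a) / choose(N, r1), numeric(1))
    p_obs <- pr[support == tab[1, 1]]
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# closed-form balanced two-way ANOVA decomposition (equal cell size n)
balancedAnovaOracle <- function(values, sex, diet) {
    stopifnot(length(unique(table(sex, diet))) == 1)
    n <- table(sex, diet)[1]
    grand <- mean(values)
    mS <- tapply(values, sex, mean)
    mD <- tapply(values, diet, mean)
    mC <- tapply(values, interaction(sex, diet), mean)
    cellOf <- interaction(sex, diet)
    ssS <- 2 * n * sum((mS - grand)^2)
    ssD <- 2 * n * sum((mD - grand)^2)
    ssC <- n * sum((mC - grand)^2)
    ssI <- ssC - ssS - ssD
    ssE <- sum((values - mC[cellOf])^2)
    dfe <- length(values) - 4
    data.frame(effect = c("sex", "maternal_diet", "interaction"),
               F = c(ssS, ssD, ssI) / (ssE / dfe),
               p = pf(c(ssS, ssD, ssI) / (ssE / dfe), 1, dfe,
                      lower.tail = FALSE))
}

# Kolmogorov-Smirnov distance from U(0,1)
ksUniform <- function(p) {
    n <- length(p)
    s <- sort(p)
    max(pmax(abs(seq_len(n) / n - s), abs(s - (seq_len(n) - 1) / n)))
}

# small ranked list: N genes ranked g001 > g002 > ... (descending scores)
makeRanked <- function(N, contrastName = "test") {
    rankGenes(stats::setNames(seq(N, 1), sprintf("g%03d", seq_len(N))),
              contrastName = contrastName)
}

# membership mask -> gene ids of makeRanked(N)
maskGenes <- function(member) sprintf("g%03d", which(member))
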