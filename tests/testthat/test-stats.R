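# build a factorial observation table from per-cell values
cellObs <- function(f_moC, m_moC, f_moHF, m_moHF) {
    data.frame(
        value = c(f_moC, m_moC, f_moHF, m_moHF),
        sex = rep(c("F", "M", "F", "M"),
                  times = c(length(f_moC), length(m_moC),
                            length(f_moHF), length(m_moHF))),
        maternal_diet = rep(c("moC", "moC", "moHF", "moHF"),
                            times = c(length(f_moC), length(m_moC),
                                      length(f_moHF), length(m_moHF))))
}

test_that("BH q-values follow the min-over-tail definition", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(0.37), 0.37)
    set.seed(2)
    for (i in 1:20) {
        p <- runif(sample(1:12, 1))
        q <- bhFdr(p)
        expect_identical(q, bruteBH(p))
        expect_true(all(q >= p) && all(q <= 1))
    }
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak is the step-down Sidak oracle", {
    hs <- holmSidak(c(0.01, 0.04))
    expect_equal(hs$adjusted, c(1 - 0.99^2, 0.04))
    expect_equal(holmSidak(0.3)$adjusted, 0.3)  # m = 1: adjusted = raw
    set.seed(3)
    for (i in 1:20) {
        p <- runif(sample(1:12, 1))
        adj <- holmSidak(p)$adjusted
        expect_identical(adj, bruteHolmSidak(p))
        # non-decreasing along the sorted order
        expect_true(all(diff(adj[order(p)]) >= 0))
    }
    expect_error(holmSidak(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("output order of the multiple-testing routines tracks input order", {
    p <- c(0.7, 0.01, 0.3, 0.02)
    perm <- c(3, 1, 4, 2)
    expect_equal(bhFdr(p)[perm], bhFdr(p[perm]))
    expect_equal(holmSidak(p)$adjusted[perm], holmSidak(p[perm])$adjusted)
})

test_that("Fisher exact matches enumeration and the stats reference", {
    expect_equal(fisherExact2x2(matrix(c(0, 5, 5, 0), 2)), 2 / 252)
    expect_equal(fisherExact2x2(matrix(c(3, 1, 1, 3), 2)), 0.4857,
                 tolerance = 1e-4)
    expect_equal(fisherExact2x2(matrix(2, 2, 2)), 1)
    set.seed(4)
    for (i in 1:25) {
        tab <- matrix(rpois(4, 5) + 1L, 2)
        p <- fisherExact2x2(tab)
        expect_equal(p, bruteFisherP(tab), tolerance = 1e-12)
        expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
    expect_error(fisherExact2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
    expect_error(fisherExact2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
    expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("two-way ANOVA matches the closed-form balanced decomposition", {
    set.seed(5)
    for (i in 1:5) {
        obs <- cellObs(rnorm(6, 10), rnorm(6, 12), rnorm(6, 9), rnorm(6, 14))
        got <- twoWayAnova(obs)
        ref <- balancedAnovaOracle(obs$value, obs$sex, obs$maternal_diet)
        expect_equal(got$F, ref$F, tolerance = 1e-9)
        expect_equal(got$p, ref$p, tolerance = 1e-9)
    }
})

test_that("two-way ANOVA handles the unbalanced 5/5/6/3 design", {
    set.seed(6)
    obs <- cellObs(rnorm(5, 10), rnorm(5, 10), rnorm(6, 10), rnorm(3, 10))
    got <- twoWayAnova(obs)
    expect_equal(got$effect, c("sex", "maternal_diet", "interaction"))
    expect_true(all(is.finite(got$p)))
    expect_error(twoWayAnova(cellObs(rnorm(5), rnorm(5), rnorm(5),
                                     numeric(0))),
                 "empty design cell")
})

test_that("null ANOVA keeps its nominal type-I error and uniform p", {
    set.seed(7)
    ps <- t(vapply(1:200, function(i) {
        obs <- cellObs(rnorm(5), rnorm(5), rnorm(6), rnorm(3))
        twoWayAnova(obs)$p
    }, numeric(3)))
    # all three p > 0.05 in at least ~93% of null replicates
    expect_gte(mean(apply(ps > 0.05, 1, all)), 0.80)
    expect_gte(mean(ps[, 1] > 0.05), 0.90)
    expect_lt(ksUniform(ps[, 1]), 0.07)
})

test_that("a strong pure sex effect lands on the sex term only", {
    set.seed(8)
    hits <- vapply(1:50, function(i) {
        obs <- cellObs(rnorm(10, 0), rnorm(10, 10), rnorm(10, 0),
                       rnorm(10, 10))
        p <- twoWayAnova(obs)$p
        c(sex = p[1] < 1e-6, inter = p[3] > 0.05)
    }, logical(2))
    expect_gte(mean(hits["sex", ]), 0.95)
    expect_gte(mean(hits["inter", ]), 0.90)
})

test_that("Tukey is gated on the ANOVA and dominates the unadjusted t", {
    set.seed(9)
    null_obs <- cellObs(rnorm(5), rnorm(5), rnorm(6), rnorm(3))
    # force a quiet null (regenerate until the gate stays closed)
    while (any(twoWayAnova(null_obs)$p < 0.05))
        null_obs <- cellObs(rnorm(5), rnorm(5), rnorm(6), rnorm(3))
    expect_false(tukeyHsd(null_obs)$triggered)

    obs <- cellObs(rnorm(6, 0), rnorm(6, 5), rnorm(6, 0), rnorm(6, 5))
    res <- tukeyHsd(obs)
    expect_true(res$triggered)
    expect_equal(nrow(res$pairs), 6L)
    # two identical-distribution groups: adjusted p near 1
    fmoc_fmohf <- res$pairs$p_adj[res$pairs$comparison == "F-moHF-F-moC"]
    expect_gt(fmoc_fmohf, 0.5)
    # multiplicity monotonicity against pooled-variance pairwise t
    obs$group <- paste(obs$sex, obs$maternal_diet, sep = "-")
    raw <- stats::pairwise.t.test(obs$value, obs$group,
                                  p.adjust.method = "none")$p.value
    labs <- c("F-moC", "M-moC", "F-moHF", "M-moHF")
    for (k in seq_len(nrow(res$pairs))) {
        cmp <- res$pairs$comparison[k]
        g1 <- labs[vapply(labs, function(l) startsWith(cmp, paste0(l, "-")),
                          logical(1))]
        g2 <- labs[vapply(labs, function(l) endsWith(cmp, l), logical(1))]
        g2 <- setdiff(g2, g1)[1]
        pr <- c(if (g1 %in% rownames(raw) && g2 %in% colnames(raw))
                    raw[g1, g2],
                if (g2 %in% rownames(raw) && g1 %in% colnames(raw))
                    raw[g2, g1])
        pr <- pr[!is.na(pr)]
        expect_gte(res$pairs$p_adj[k] + 1e-12, pr)
    }
})
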