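test_that("increment vectors follow the two-level step construction", {
    r4 <- makeRanked(4)
    inc <- xiIncrements(r4, c("g001", "g002"))
    expect_equal(inc@x, c(1, 1, -1, -1))
    expect_equal(inc@G, 2L)

    r10 <- makeRanked(10)
    inc10 <- xiIncrements(r10, c("g001", "g002"))
    expect_equal(unique(inc10@x[inc10@member]), 2)
    expect_equal(unique(inc10@x[!inc10@member]), -0.5)

    # conservation across a grid of (N, G)
    for (N in c(5L, 17L, 60L)) {
        r <- makeRanked(N)
        for (G in c(1L, 2L, floor(N / 2), N - 1L)) {
            inc <- xiIncrements(r, sprintf("g%03d", seq_len(G)))
            expect_lt(abs(sum(inc@x)), 1e-9)
        }
    }
})

test_that("members absent from the universe are dropped before computing G", {
    r <- makeRanked(10)
    inc <- xiIncrements(r, c("g001", "g003", "not_a_gene"))
    expect_equal(inc@G, 2L)
})

test_that("degenerate sets (G = 0 or G = N) are rejected", {
    r <- makeRanked(6)
    expect_error(xiIncrements(r, "absent_gene"), "G = 0")
    expect_error(xiIncrements(r, sprintf("g%03d", 1:6)), "G = N")
})

test_that("the score matches its worked examples in both modes", {
    r4 <- makeRanked(4)
    top <- xiIncrements(r4, c("g001", "g002"))
    bottom <- xiIncrements(r4, c("g003", "g004"))
    expect_equal(mesStatistic(top), 2)
    expect_equal(mesStatistic(top, "literal_max"), 2)
    expect_equal(mesStatistic(bottom), -2)
    expect_equal(mesStatistic(bottom, "literal_max"), 0)

    # N=10, G=2, members at ranks 1 and 6: running sums peak at +2
    r10 <- makeRanked(10)
    inc <- xiIncrements(r10, c("g001", "g006"))
    expect_equal(mesStatistic(inc), 2)
    expect_equal(bruteMes(inc@member), 2)
})

test_that("the O(G) score equals the full prefix-sum scan on random instances", {
    set.seed(11)
    for (i in 1:200) {
        N <- sample(3:50, 1)
        G <- sample(seq_len(N - 1), 1)
        member <- rep(FALSE, N)
        member[sample.int(N, G)] <- TRUE
        r <- makeRanked(N)
        inc <- xiIncrements(r, maskGenes(member))
        expect_identical(mesStatistic(inc), bruteMes(member))
        expect_identical(mesStatistic(inc, "literal_max"),
                         bruteMes(member, "literal_max"))
    }
})

test_that("|MES| is bounded by sqrt(G(N-G)), attained by contiguous blocks", {
    set.seed(7)
    for (i in 1:50) {
        N <- sample(4:80, 1)
        G <- sample(seq_len(N - 1), 1)
        member <- rep(FALSE, N); member[sample.int(N, G)] <- TRUE
        r <- makeRanked(N)
        bound <- sqrt(G * (N - G))
        expect_lte(abs(mesStatistic(xiIncrements(r, maskGenes(member)))),
                   bound + 1e-9)
        top <- rep(FALSE, N); top[seq_len(G)] <- TRUE
        expect_equal(mesStatistic(xiIncrements(r, maskGenes(top))), bound)
        bot <- rev(top)
        expect_equal(mesStatistic(xiIncrements(r, maskGenes(bot))), -bound)
    }
})

test_that("the score depends only on the membership pattern over ranks", {
    member <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
    r1 <- makeRanked(8)
    # different labels and different (still descending) score magnitudes
    r2 <- rankGenes(stats::setNames(c(90, 12, 11.5, 3, 2.9, 0, -4, -100),
                                    paste0("x", 1:8)))
    s1 <- mesStatistic(xiIncrements(r1, maskGenes(member)))
    s2 <- mesStatistic(xiIncrements(r2, paste0("x", which(member))))
    expect_identical(s1, s2)
})

test_that("permutation p is seeded, bounded below, and matches the exhaustive null", {
    r6 <- makeRanked(6)
    top3 <- c("g001", "g002", "g003")
    a <- permutationPvalue(r6, top3, B = 500, seed = 99)
    b <- permutationPvalue(r6, top3, B = 500, seed = 99)
    expect_identical(a, b)
    expect_gte(a$p, 1 / 501)

    # exhaustive two-sided p over all C(6,3)=20 patterns is 2/20
    member <- c(rep(TRUE, 3), rep(FALSE, 3))
    expect_equal(exhaustiveMesP(member), 0.1)
    pv <- permutationPvalue(r6, top3, B = 4000, seed = 5)
    se <- sqrt(0.1 * 0.9 / 4000)
    expect_lt(abs(pv$p - 0.1), 3 * se + 2 / 4001)
})

test_that("permutation p agrees with exhaustive enumeration for small N", {
    set.seed(21)
    for (i in 1:5) {
        N <- sample(5:9, 1)
        G <- sample(2:(N - 2), 1)
        member <- rep(FALSE, N); member[sample.int(N, G)] <- TRUE
        p_exact <- exhaustiveMesP(member)
        B <- 4000
        pv <- permutationPvalue(makeRanked(N), maskGenes(member),
                                B = B, seed = i)
        se <- sqrt(p_exact * (1 - p_exact) / B)
        expect_lt(abs(pv$p - p_exact), 3 * se + 2 / (B + 1))
    }
})

test_that("collection-level enrichment skips degenerate sets with a reason", {
    r <- makeRanked(30)
    sets <- list(tiny = c("g001", "g002", "g003"),
                 none = c("zz1", "zz2", "zz3", "zz4", "zz5"),
                 ok = sprintf("g%03d", 1:8))
    res <- enrichCollection(r, sets, B = 100, min_size = 5, seed = 1)
    expect_equal(res$reason[res$set_id == "tiny"], "below min_size")
    expect_equal(res$reason[res$set_id == "none"], "no overlap with universe")
    expect_false(res$skipped[res$set_id == "ok"])
    expect_true(is.na(res$q_BH[res$set_id == "tiny"]))
    # direction tracks the MES sign for every tested set
    tested <- !res$skipped
    expect_equal(res$direction[tested],
                 ifelse(res$MES[tested] > 0, "up", "down"))
})

test_that("a planted top-decile set is recovered as significantly enriched", {
    study <- simulateStudy(n_genes = 1000, n_sets = 10, n_enriched = 1,
                           enriched_size = 40, seed = 17)
    rpkm <- computeRpkm(geneFilter(study$counts))
    ct <- canonicalContrasts(study$counts)$M_vs_F_moC
    ranked <- rankGenes(log2FoldChange(rpkm, ct), "M_vs_F_moC")
    res <- enrichCollection(ranked, study$sets, B = 1000, seed = 17)
    planted <- res[res$set_id == "set_enriched_01", ]
    expect_true(planted$significant)
    expect_equal(planted$direction, "up")
})

test_that("per-set substreams make results independent of collection order", {
    r <- makeRanked(50)
    sets <- list(s1 = sprintf("g%03d", 1:10), s2 = sprintf("g%03d", 20:30),
                 s3 = sprintf("g%03d", c(2, 9, 14, 33, 41, 48)))
    a <- enrichCollection(r, sets, B = 200, seed = 3)
    b <- enrichCollection(r, rev(sets), B = 200, seed = 3)
    b <- b[match(a$set_id, b$set_id), ]
    expect_equal(a$p_perm, b$p_perm)
    expect_equal(a$MES, b$MES)
})
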