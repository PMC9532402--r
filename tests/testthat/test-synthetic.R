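test_that("the default design reproduces the study group sizes", {
    d <- studyDesign()
    expect_equal(d@groups$n, c(5L, 5L, 6L, 3L))
    st <- sampleTable(d)
    expect_equal(nrow(st), 19L)
    expect_false(anyDuplicated(st$sample_id) > 0)
    expect_error(studyDesign(c("F-moC" = 5)), "group labels")
    expect_error(validObject(studyDesign(c("F-moC" = 0, "M-moC" = 5,
                                           "F-moHF" = 6, "M-moHF" = 3))),
                 "positive integers")
})

test_that("every generator is bit-reproducible under its seed", {
    truth <- simulateTruth(100, seed = 4)
    expect_identical(simulateTruth(100, seed = 4), truth)
    d <- studyDesign()
    expect_identical(simulateCounts(d, truth, seed = 9),
                     simulateCounts(d, truth, seed = 9))
    expect_false(identical(assay(simulateCounts(d, truth, seed = 9)),
                           assay(simulateCounts(d, truth, seed = 10))))
    expect_identical(simulateLipidTable(design = d, seed = 2),
                     simulateLipidTable(design = d, seed = 2))
    expect_identical(simulatePhenotypes(d, seed = 3),
                     simulatePhenotypes(d, seed = 3))
    gs <- simulateGeneSets(5, c(5, 20), truth,
                           names(truth@baselineMean), seed = 6)
    gs2 <- simulateGeneSets(5, c(5, 20), truth,
                            names(truth@baselineMean), seed = 6)
    expect_identical(gs$collection@sets, gs2$collection@sets)
})

test_that("generators leave the caller's RNG state untouched", {
    set.seed(123)
    before <- .Random.seed
    invisible(simulateTruth(10, seed = 1))
    expect_identical(.Random.seed, before)
})

test_that("planted log2FC is recovered empirically at large n", {
    # law of large numbers against the generator's own mean parameterization
    big <- studyDesign(c("F-moC" = 200, "M-moC" = 200,
                         "F-moHF" = 2, "M-moHF" = 2))
    truth <- simulateTruth(60, seed = 8, dispersion = 0.1)
    truth <- plantEffect(truth, names(truth@baselineMean)[1:20],
                         "M-moC", log2fc = 1)
    se <- simulateCounts(big, truth, seed = 8)
    cd <- colData(se)
    m_moc <- rownames(cd)[cd$sex == "M" & cd$maternal_diet == "moC"]
    f_moc <- rownames(cd)[cd$sex == "F" & cd$maternal_diet == "moC"]
    cm <- assay(se, "counts")
    emp <- log2(rowMeans(cm[1:20, m_moc]) / rowMeans(cm[1:20, f_moc]))
    expect_true(all(abs(emp - 1) < 0.1 + 2 / sqrt(truth@baselineMean[1:20])))
    expect_lt(abs(mean(emp) - 1), 0.1)
})

test_that("group count means converge to the planted means", {
    big <- studyDesign(c("F-moC" = 500, "M-moC" = 2,
                         "F-moHF" = 2, "M-moHF" = 2))
    truth <- simulateTruth(20, seed = 5, meanlog = 5, sdlog = 0.5)
    se <- simulateCounts(big, truth, seed = 5)
    cd <- colData(se)
    f_moc <- rownames(cd)[cd$sex == "F" & cd$maternal_diet == "moC"]
    emp <- rowMeans(assay(se, "counts")[, f_moc])
    expect_true(all(abs(emp / truth@baselineMean - 1) < 0.05))
})

test_that("planting an effect on an unknown gene names the offender", {
    truth <- simulateTruth(10, seed = 1)
    expect_error(plantEffect(truth, "nonexistent_gene", "M-moC", 1),
                 "nonexistent_gene")
})

test_that("gene-set generation honors its contracts", {
    truth <- simulateTruth(200, seed = 2)
    universe <- names(truth@baselineMean)
    expect_equal(length(simulateGeneSets(0, c(5, 10), truth, universe,
                                         seed = 1)$collection), 0L)
    expect_error(simulateGeneSets(3, c(20, 5), truth, universe, seed = 1),
                 "inverted")
    gs <- simulateGeneSets(6, c(10, 30), truth, universe, seed = 3,
                           n_enriched = 2, direction = "up", strength = 1.5)
    # planted members carry a positive planted shift in the target group
    for (id in c("set_enriched_01", "set_enriched_02"))
        expect_true(all(
            gs$truth@groupLog2FC[gs$collection[[id]], "M-moC"] > 0))
    expect_equal(gs$truth@enrichedSets$set_id,
                 c("set_enriched_01", "set_enriched_02"))

    # GMT round-trip identity
    path <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(gs$collection, path)
    back <- readGMT(path)
    expect_identical(back@sets, gs$collection@sets)
})

test_that("our GMT files are read identically by an independent parser", {
    truth <- simulateTruth(100, seed = 12)
    gs <- simulateGeneSets(4, c(5, 15), truth, names(truth@baselineMean),
                           seed = 12)$collection
    path <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(gs, path)
    ref <- fgsea::gmtPathways(path)
    expect_identical(ref[names(gs)], gs@sets)
})

test_that("lipid generator output is fully parseable and class-plausible", {
    tab <- simulateLipidTable(classes = c("TG", "PC", "Cer"),
                              species_per_class = 10, seed = 4)
    ann <- parseLipidSpecies(rownames(tab))  # would error on a bad name
    expect_true(all(assay(tab, "intensity") > 0))
    tg <- ann[ann$lipid_class == "TG", ]
    expect_true(all(tg$total_carbons >= 46 & tg$total_carbons <= 60))
    expect_true(all(ann$sphingoid[ann$lipid_class == "Cer"]))
    expect_error(simulateLipidTable(classes = "XX", seed = 1), "unsupported")
})

test_that("phenotype generator obeys its structural constraints", {
    phen <- simulatePhenotypes(studyDesign(), seed = 6)
    glc <- phen[phen$variable == "glucose", ]
    expect_equal(sort(unique(glc$time_min)), c(0, 15, 30, 60, 120))
    expect_true(all(phen$value > 0))
    wide <- reshape(phen[is.na(phen$time_min), c("sample_id", "variable", "value")],
                    idvar = "sample_id", timevar = "variable",
                    direction = "wide")
    expect_equal(wide$value.sat_fat + wide$value.vat_fat, wide$value.total_fat)
    expect_true(all(wide$value.total_fat <= wide$value.body_weight))
})
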