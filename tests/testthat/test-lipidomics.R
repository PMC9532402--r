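# 4-sample lipid fixture with two groups of two
lipidFixture <- function(intens, species = rownames(intens)) {
    lipidSpeciesTable(intens)
}

test_that("the species grammar parses and round-trips", {
    p <- parseLipidSpecies(c("TG(54:3)", "Cer(d34:1)", "PC(36:2)", "TG54"))
    expect_equal(p$lipid_class, c("TG", "Cer", "PC", "TG"))
    expect_equal(p$total_carbons, c(54L, 34L, 36L, 54L))
    expect_equal(p$double_bonds, c(3L, 1L, 2L, NA_integer_))
    expect_equal(p$sphingoid, c(FALSE, TRUE, FALSE, FALSE))
    expect_identical(formatLipidSpecies(p), p$name)

    expect_error(parseLipidSpecies("XYZ(10:1)"), "unknown lipid class")
    expect_error(parseLipidSpecies("TG(54:"), "malformed")
    expect_error(parseLipidSpecies("TG(3:10)"), "exceed")
    expect_error(parseLipidSpecies(""), "non-empty")
})

test_that("generator species names all survive the parser round-trip", {
    tab <- simulateLipidTable(classes = names(mesea:::.LIPID_CLASS_RANGES),
                              species_per_class = 5, seed = 9)
    parsed <- parseLipidSpecies(rownames(tab))
    expect_identical(formatLipidSpecies(parsed), rownames(tab))
})

test_that("the peak filter applies its boundary rules and is idempotent", {
    peaks <- data.frame(
        species = c("keep", "dim", "off_mass", "at_floor", "at_ppm"),
        raw_intensity = c(2e4, 5e3, 2e4, 1e4, 2e4),
        mass_error_ppm = c(3, 3, 6, 3, 5))
    kept <- filterPeaks(peaks)
    expect_equal(kept$species, c("keep", "at_ppm"))  # 1e4 strict, 5 ppm incl.
    expect_identical(filterPeaks(kept), kept)
    empty <- peaks[0, ]
    expect_equal(nrow(filterPeaks(empty)), 0L)
})

test_that("relative abundance is a simplex at every aggregation level", {
    intens <- matrix(c(2, 2, 6, 2,
                       2, 2, 2, 6,
                       4, 4, 4, 4), 3, 4, byrow = TRUE,
                     dimnames = list(c("TG(54:1)", "TG(54:3)", "PC(36:2)"),
                                     c("a1", "a2", "b1", "b2")))
    tab <- lipidFixture(intens)
    for (lvl in c("class", "carbon-class", "species")) {
        fr <- classRelativeAbundance(tab, lvl)
        expect_true(all(abs(colSums(fr) - 1) < 1e-12))
        expect_true(all(fr >= 0))
    }
    # TG(54:1) and TG(54:3) pool into carbon-class TG54
    cc <- classRelativeAbundance(tab, "carbon-class")
    expect_setequal(rownames(cc), c("TG54", "PC36"))
    expect_equal(cc["TG54", "a1"], 0.5)
    # single species -> fraction 1
    solo <- lipidFixture(matrix(5, 1, 2, dimnames = list("SM(d36:1)",
                                                         c("s1", "s2"))))
    expect_equal(unname(classRelativeAbundance(solo, "class")[1, ]), c(1, 1))
})

test_that("saturation profiles are per-double-bond simplexes", {
    intens <- matrix(c(1, 3,
                       1, 1,
                       2, 0.5), 3, 2, byrow = TRUE,
                     dimnames = list(c("TG(50:0)", "TG(52:2)", "PC(36:2)"),
                                     c("s1", "s2")))
    tab <- lipidFixture(intens)
    prof <- saturationProfile(tab)
    s1 <- prof[prof$sample_id == "s1", ]
    expect_equal(s1$fraction[s1$double_bonds == 0], 0.25)
    expect_equal(s1$fraction[s1$double_bonds == 2], 0.75)
    agg <- tapply(prof$fraction, prof$sample_id, sum)
    expect_true(all(abs(agg - 1) < 1e-12))
    byc <- saturationProfile(tab, by_class = TRUE)
    sums <- tapply(byc$fraction, paste(byc$lipid_class, byc$sample_id), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    # class-level species (unset double bonds) are rejected by name
    bad <- lipidFixture(matrix(c(1, 1), 1, 2,
                               dimnames = list("TG54", c("s1", "s2"))))
    expect_error(saturationProfile(bad), "TG54")
})

test_that("group fold changes follow their log base, floor and symmetry", {
    intens <- matrix(c(10, 10, 1, 1,
                       3, 3, 3, 3), 2, 4, byrow = TRUE,
                     dimnames = list(c("TG(50:1)", "PC(34:1)"),
                                     c("a1", "a2", "b1", "b2")))
    tab <- lipidFixture(intens)
    ct <- contrast("AvB", c("a1", "a2"), c("b1", "b2"))
    fc <- groupFoldChanges(tab, ct, base = "log10")
    expect_equal(fc$logFC[fc$species == "TG(50:1)"], 1)  # 10x means
    expect_equal(fc$logFC[fc$species == "PC(34:1)"], 0)
    expect_equal(fc$p[fc$species == "PC(34:1)"], 1)
    rev_fc <- groupFoldChanges(tab, contrast("BvA", c("b1", "b2"),
                                             c("a1", "a2")))
    expect_equal(rev_fc$logFC, -fc$logFC)
    # adjusted p equals the independent step-down Sidak oracle
    set.seed(8)
    intens2 <- matrix(rlnorm(40, log(1e5), 0.4), 10, 4,
                      dimnames = list(sprintf("TG(%d:2)", seq(40, 58, 2)),
                                      c("a1", "a2", "b1", "b2")))
    fc2 <- groupFoldChanges(lipidFixture(intens2), ct)
    expect_identical(fc2$p_adj, bruteHolmSidak(fc2$p))
})

test_that("desaturase indices are product/precursor ratios with NA flags", {
    fa <- c("C18:1n-9" = 1, "C18:0" = 4, "C20:4n-6" = 2, "C20:3n-6" = 1)
    idx <- desaturaseIndices(fa)
    expect_equal(idx$value[idx$index == "delta9"], 0.25)
    expect_equal(idx$value[idx$index == "delta5"], 2)
    expect_true(all(idx$defined))
    # missing precursor -> flagged NA, not an error
    idx2 <- desaturaseIndices(fa[c("C18:1n-9", "C18:0")])
    expect_true(is.na(idx2$value[idx2$index == "delta5"]))
    expect_false(idx2$defined[idx2$index == "delta5"])
    # C16 variant
    idx3 <- desaturaseIndices(c("C16:1n-7" = 3, "C16:0" = 6), delta9 = "C16")
    expect_equal(idx3$value[idx3$index == "delta9"], 0.5)
    expect_error(desaturaseIndices(c("C18:0" = -1)), "non-negative")
})
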