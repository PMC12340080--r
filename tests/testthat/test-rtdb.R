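omPC <- function(...) paste0("PC ", ...)

## the three single- and double-label observations of one omega pair,
## after isotope-effect correction, inside the 5-s grouping window
pairEntries <- function(rts = c(20.00, 20.03, 20.06)) {
    data.frame(lipid_class = "PC",
               chains = c(paste0("20:4(n", UM, "6)_22:5"),
                          paste0("20:4_22:5(n", UM, "3)"),
                          paste0("20:4(n", UM, "6)_22:5(n", UM, "3)")),
               rt_min = rts, batch = c("runB", "runC", "runBC"),
               stringsAsFactors = FALSE)
}

test_that("omega combinations from separate label runs aggregate into one entry", {
    g <- groupOmegaCombinations(pairEntries(), toleranceS = 5)
    expect_equal(nrow(g), 1L)
    expect_identical(g$species_key_omega,
                     omPC("20:4(n", UM, "6)_22:5(n", UM, "3)"))
    expect_identical(g$batches, "runB;runBC;runC")
    expect_equal(g$reference_rt_min, 20.03)
    expect_identical(g$flags, "")
})

test_that("entries beyond the grouping tolerance remain separate", {
    e <- pairEntries(c(20.0, 20.2, 20.4))   # 12 s apart
    g <- groupOmegaCombinations(e, toleranceS = 5)
    expect_equal(nrow(g), 3L)
})

test_that("grouping is idempotent and order-invariant", {
    e <- rbind(pairEntries(),
               data.frame(lipid_class = "PC",
                          chains = paste0("16:0_18:1(n", UM, "9)"),
                          rt_min = c(14.0, 14.02, 14.5),
                          batch = c("a", "b", "c")))
    g1 <- groupOmegaCombinations(e, toleranceS = 5)
    g2 <- groupOmegaCombinations(
        data.frame(lipid_class = g1$lipid_class, chains = g1$chains,
                   rt_min = g1$reference_rt_min, batch = g1$batches,
                   evidence = g1$evidence), toleranceS = 5)
    expect_equal(g2, g1, ignore_attr = TRUE)
    for (seed in 1:4) {
        set.seed(seed)
        gp <- groupOmegaCombinations(e[sample(nrow(e)), ], toleranceS = 5)
        expect_equal(gp, g1, ignore_attr = TRUE)
    }
})

test_that("conflicting omega assignments inside one cluster are flagged", {
    e <- data.frame(lipid_class = "PC",
                    chains = c(paste0("16:0_18:1(n", UM, "9)"),
                               paste0("16:0_18:1(n", UM, "7)")),
                    rt_min = c(15.0, 15.02), batch = c("a", "b"))
    g <- groupOmegaCombinations(e, toleranceS = 5)
    expect_equal(nrow(g), 1L)
    expect_identical(g$flags, "conflict")
})

test_that("buildRTDB corrects, strips labels and reports skipped rows", {
    m <- new("IsotopeEffectModel", kRatio = 1.0015^17, fA = 1, t0 = 0.5,
             perDeuteriumRatio = 1.0015, nRef = 17)
    ids <- data.frame(batch = "b1", class = "PC",
                      chains = c("16:0_A18:1", "16:0_18:banana"),
                      rt_min = c(18.0, 12.0), stringsAsFactors = FALSE)
    db <- buildRTDB(ids, m, gradientSpan = c(0.5, 32))
    e <- rtdbEntries(db)
    expect_equal(nrow(e), 1L)
    expect_identical(e$species_key_omega,
                     omPC("16:0_18:1(n", UM, "9)"))
    expect_equal(e$reference_rt_min, 18 + 17.5 * (1.0015^17 - 1),
                 tolerance = 1e-9)
    expect_equal(nrow(buildLog(db)), 1L)
    expect_equal(buildLog(db)$row, 2L)
    ## identifications of the same omega pair from two label runs aggregate
    ids2 <- data.frame(batch = c("runB", "runC"), class = "PC",
                       chains = c("B20:4_22:5", "20:4_C22:5"),
                       rt_min = omegaRT:::.labeledRT(
                           c(20, 20), list(11L, 5L), m))
    db2 <- buildRTDB(ids2, m, gradientSpan = c(0.5, 32))
    expect_equal(nrow(rtdbEntries(db2)), 1L)
    expect_identical(rtdbEntries(db2)$batches, "runB;runC")
})

test_that("merging preserves identity, sums disjoint sets and pools batches", {
    a <- makeDB(c(paste0("16:0_18:1(n", UM, "9)"),
                  paste0("16:0_20:4(n", UM, "6)")),
                c(14, 12), batches = "A")
    ## self-merge with identity calibration is the identity
    m <- mergeRTDBs(list(a, a), calibrations = list(NULL, "identity"))
    expect_equal(rtdbEntries(m)[, c("species_key_omega",
                                    "reference_rt_min")],
                 rtdbEntries(a)[, c("species_key_omega",
                                    "reference_rt_min")],
                 ignore_attr = TRUE)
    ## disjoint species: aggregate count is the sum
    b <- makeDB(paste0("18:0_22:6(n", UM, "3)"), 13, batches = "B")
    m2 <- mergeRTDBs(list(a, b), calibrations = list(NULL, "identity"))
    expect_equal(nrow(rtdbEntries(m2)), 3L)
    ## shared species within tolerance appears once with both batches
    c_ <- makeDB(paste0("16:0_18:1(n", UM, "9)"), 14.02, batches = "C")
    m3 <- mergeRTDBs(list(a, c_), calibrations = list(NULL, "identity"))
    e3 <- rtdbEntries(m3)
    shared <- e3[e3$species_key_omega ==
                     omPC("16:0_18:1(n", UM, "9)"), ]
    expect_equal(nrow(shared), 1L)
    expect_identical(shared$batches, "A;C")
    ## merging never invents species
    expect_true(all(e3$species_key_omega %in%
                        c(rtdbEntries(a)$species_key_omega,
                          rtdbEntries(c_)$species_key_omega)))
    ## missing calibration for a non-reference DB is an error
    expect_error(mergeRTDBs(list(a, b)), "missing calibration")
    ## curated outliers are excluded
    m4 <- mergeRTDBs(list(a, b), calibrations = list(NULL, "identity"),
                     excludeKeys = omPC("16:0_20:4(n", UM, "6)"))
    expect_false(omPC("16:0_20:4(n", UM, "6)") %in%
                     rtdbEntries(m4)$species_key_omega)
})

test_that("RT databases round-trip through files", {
    db <- makeDB(c(paste0("16:0_18:1(n", UM, "9)"),
                   paste0("15:0_20:4(n", UM, "6)")),
                 c(14, 12), classes = c("PC", "PI"),
                 evidence = c("SIL-experiment", "standard"))
    for (ext in c("tsv", "csv")) {
        f <- withr::local_tempfile(fileext = paste0(".", ext))
        writeRTDB(db, f)
        back <- readRTDB(f)
        expect_equal(rtdbEntries(back), rtdbEntries(db),
                     ignore_attr = TRUE)
        expect_equal(gradientSpan(back), gradientSpan(db))
        expect_identical(back@methodId, db@methodId)
    }
    ## empty database is valid
    f <- withr::local_tempfile(fileext = ".csv")
    empty <- RTDB(data.frame(lipid_class = character(),
                             chains = character(),
                             reference_rt_min = numeric(),
                             batches = character()),
                  gradientSpan = c(0.5, 32))
    writeRTDB(empty, f)
    expect_equal(nrow(rtdbEntries(readRTDB(f))), 0L)
    ## schema violations name the missing column
    e <- rtdbEntries(db); e$reference_rt_min <- NULL
    f2 <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(e, f2, sep = "\t", row.names = FALSE,
                       fileEncoding = "UTF-8")
    expect_error(readRTDB(f2), "reference_rt_min")
})
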