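## coelution fixture: PC 18:0/22:5 omega isomers more than a minute apart,
## plus the coeluting PC 16:0/24:5(n-6) at the same retention time
coelutionDB <- function() {
    makeDB(c(paste0("18:0_22:5(n", UM, "3)"),
             paste0("18:0_22:5(n", UM, "6)"),
             paste0("16:0_24:5(n", UM, "6)")),
           c(21.9, 23.0, 21.9))
}

test_that("candidates are key-matched, windowed and sorted by |dRT|", {
    db <- coelutionDB()
    peak <- list(lipid_class = "PC", chains = "18:0_22:5", rt_min = 21.9)
    cand <- findCandidates(peak, db, rtWindowS = 15)
    expect_equal(nrow(cand), 1L)   # the n-6 isomer is > 1 min away
    expect_identical(cand$species_key_omega,
                     paste0("PC 18:0_22:5(n", UM, "3)"))
    ## species absent from the database
    none <- findCandidates(list(lipid_class = "PC", chains = "16:0_16:1",
                                rt_min = 12), db)
    expect_equal(nrow(none), 0L)
    ## two isomers inside the window are ordered by |dRT|
    db2 <- makeDB(c(paste0("16:0_18:1(n", UM, "9)"),
                    paste0("16:0_18:1(n", UM, "7)")), c(14.00, 14.15))
    cand2 <- findCandidates(list(lipid_class = "PC", chains = "16:0_18:1",
                                 rt_min = 14.02), db2, rtWindowS = 15)
    expect_equal(nrow(cand2), 2L)
    expect_true(abs(cand2$delta_rt_s[1]) <= abs(cand2$delta_rt_s[2]))
    ## an m/z far off at 10 ppm removes the candidates
    mz <- monoisotopicMass(LipidSpecies("PC", "16:0_18:1"), "[M+H]+")
    withMz <- findCandidates(list(lipid_class = "PC", chains = "16:0_18:1",
                                  rt_min = 14.02, mz = mz + 0.05,
                                  adduct = "[M+H]+"), db2)
    expect_equal(nrow(withMz), 0L)
})

test_that("assignment policy separates automated, ambiguous and suggested", {
    cand <- function(d) data.frame(species_key_omega = sprintf("k%d", seq_along(d)),
                                   chains = rep("x", length(d)),
                                   reference_rt_min = rep(20, length(d)),
                                   delta_rt_s = d,
                                   flags = rep("", length(d)))
    a <- assignOmega(cand(0), matchS = 5)
    expect_identical(a$status, "automated")
    expect_equal(a$confidence, 1.0)
    expect_identical(assignOmega(cand(c(2, 4)), matchS = 5)$status,
                     "ambiguous")
    s <- assignOmega(cand(8), matchS = 5)
    expect_identical(s$status, "suggested")
    expect_identical(assignOmega(cand(numeric())), list(
        status = "none", chosen = NULL, confidence = 0,
        competitors = cand(numeric())[0, , drop = FALSE]))
    ## near competitor blocks automation even with one candidate in window
    b <- assignOmega(cand(c(4, 6)), matchS = 5, marginFactor = 2)
    expect_identical(b$status, "suggested")
    ## far competitor does not
    c_ <- assignOmega(cand(c(2, 12)), matchS = 5, marginFactor = 2)
    expect_identical(c_$status, "automated")
})

test_that("confidence decreases with |dRT| and policy is monotone in matchS", {
    for (seed in 1:10) {
        set.seed(seed)
        d <- sort(round(runif(sample(1:4, 1), -20, 20), 1))
        cand <- data.frame(species_key_omega = paste0("k", seq_along(d)),
                           chains = "x", reference_rt_min = 20,
                           delta_rt_s = d[order(abs(d))], flags = "")
        wide <- assignOmega(cand, matchS = 6)
        narrow <- assignOmega(cand, matchS = 3)
        ## shrinking the window never converts non-automated to automated
        if (wide$status != "automated")
            expect_false(narrow$status == "automated")
        if (!is.null(wide$chosen) && !is.null(narrow$chosen))
            expect_gte(wide$confidence, narrow$confidence)
    }
})

test_that("coeluting molecular species are annotated per species", {
    db <- coelutionDB()
    ids <- data.frame(lipid_class = "PC",
                      chains = c("18:0_22:5", "16:0_24:5"),
                      rt_min = c(21.9, 21.9))
    out <- annotateRun(ids, db)
    expect_identical(out$annotations$status, c("automated", "automated"))
    expect_identical(out$annotations$assigned_key,
                     c(paste0("PC 18:0_22:5(n", UM, "3)"),
                       paste0("PC 16:0_24:5(n", UM, "6)")))
    expect_equal(out$summary$n[out$summary$status == "automated"], 2L)
    ## assignments never cross molecular keys
    expect_identical(
        omegaRT:::.molecularKey("PC", out$annotations$assigned_chains),
        omegaRT:::.molecularKey("PC", out$annotations$chains))
})

test_that("empty tables and gradient mismatches are handled explicitly", {
    db <- coelutionDB()
    empty <- data.frame(lipid_class = character(), chains = character(),
                        rt_min = numeric())
    out <- annotateRun(empty, db)
    expect_equal(nrow(out$annotations), 0L)
    expect_true(all(out$summary$n == 0L))
    late <- data.frame(lipid_class = "PC", chains = "18:0_22:5",
                       rt_min = 55)
    expect_error(annotateRun(late, db), "calibration|map the RT-DB")
})

test_that("well-separated isomer runs are annotated almost perfectly", {
    ## separations >= 10 s with 1-s RT noise (>= 6x the noise SD)
    cfg <- simConfig(seed = 31, rt_noise_sd_s = 1, min_separation_s = 10,
                     n_species_per_class = 9, n_replicates = 1,
                     classes = c("PC", "PE", "PI", "PS"),
                     warp = list(name = "identity", params = list()))
    db <- synthRTDB(cfg)
    run <- simulateRun(db, makeWarp("identity"), cfg, seed = 32)
    bio <- run[!run$standard, , drop = FALSE]
    out <- annotateRun(bio, db)$annotations
    correct <- out$status == "automated" & out$assigned_key == out$true_key
    expect_gte(sum(correct), nrow(out) - 1L)
})
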