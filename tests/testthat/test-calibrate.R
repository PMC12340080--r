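## a DB of n unique molecular species spread over the gradient, plus an
## observation table under a warp with replicate noise
calibFixture <- function(n = 20, warp = function(t) t, sd = 0, seed = 1,
                         reps = 3, span = c(0.5, 32)) {
    set.seed(seed)
    stopifnot(n <= 112)
    oms <- c(3L, 6L, 7L, 9L, 10L)
    i <- seq_len(n) - 1L
    ## bijective (sat, carbons, double bonds) triples keep molecular keys
    ## unique, so every species is anchor-eligible
    chains <- sprintf("%d:0_%d:%d(n%s%d)",
                      12L + 2L * (i %% 7L),
                      18L + 2L * ((i %/% 7L) %% 4L),
                      1L + (i %/% 28L) %% 4L,
                      UM, oms[i %% 5L + 1L])
    rts <- seq(span[1] + 2, span[2] - 2, length.out = n)
    db <- makeDB(chains, rts, classes = "PC", span = span)
    e <- rtdbEntries(db)
    obs <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
        data.frame(lipid_class = "PC",
                   chains = vapply(strsplit(e$chains[i], "_"), function(tk)
                       paste(formatChain(omegaRT:::.stripOmega(
                           parseChain(tk))), collapse = "_"), character(1)),
                   rt_min = warp(e$reference_rt_min[i]) +
                       rnorm(reps, 0, sd),
                   standard = FALSE, stringsAsFactors = FALSE)
    }))
    list(db = db, obs = obs)
}

test_that("anchor selection strategies follow their contracts", {
    ## strategy 3 takes all shared standards
    db <- makeDB(c(paste0("15:0_18:1(n", UM, "9)"),
                   paste0("15:0_20:4(n", UM, "6)"),
                   paste0("15:0_22:6(n", UM, "3)")),
                 c(10, 8, 9), evidence = "standard")
    target <- data.frame(lipid_class = "PC",
                         chains = rtdbEntries(db)$chains,
                         rt_min = c(20, 16, 18), standard = TRUE)
    a <- selectAnchors(db, target, strategy = 3)
    expect_equal(nrow(a), 3L)
    expect_true(all(a$reliability == "standard"))
    ## disjoint species sets give the "no anchors" error
    other <- data.frame(lipid_class = "PE", chains = "16:0_18:1",
                        rt_min = 12, standard = FALSE)
    expect_error(selectAnchors(db, other, strategy = 1), "no anchors")
})

test_that("strategy 2 screens anchors by replicate spread", {
    set.seed(7)
    n <- 50
    fx <- calibFixture(n, warp = function(t) 2 * t, sd = 0.005, seed = 7)
    ## make 10 species unreliable: replicate spread well above 0.05 min
    bad <- unique(fx$obs$chains)[1:10]
    i <- fx$obs$chains %in% bad
    fx$obs$rt_min[i] <- fx$obs$rt_min[i] + rep(c(-0.12, 0, 0.12),
                                               length.out = sum(i))
    ## add 3 standards present on both sides
    stdDb <- makeDB(c(paste0("15:0_18:1(n", UM, "9)"),
                      paste0("15:0_20:4(n", UM, "6)"),
                      paste0("15:0_22:6(n", UM, "3)")),
                    c(10, 8, 12), evidence = "standard")
    db <- mergeRTDBs(list(fx$db, stdDb),
                     calibrations = list(NULL, "identity"))
    std <- data.frame(lipid_class = "PC", chains = rtdbEntries(stdDb)$chains,
                      rt_min = 2 * rtdbEntries(stdDb)$reference_rt_min,
                      standard = TRUE)
    target <- rbind(fx$obs, std)
    a <- selectAnchors(db, target, strategy = 2)
    expect_equal(nrow(a), 43L)   # 50 + 3 - 10 screened out
    expect_equal(sum(a$reliability == "standard"), 3L)
})

test_that("binning yields median knots and re-merges to monotone order", {
    a <- data.frame(species_key = letters[1:4], group = "PC",
                    rt_source = c(1.1, 2.1, 3.1, 4.1),
                    rt_target = c(2.0, 4.0, 6.0, 8.0),
                    reliability = "biological")
    k <- binAnchors(a, binWidthMin = 0.5)
    expect_equal(k$PC$source, a$rt_source)
    expect_equal(k$PC$target, a$rt_target)
    expect_equal(k$global$source, a$rt_source)
    ## median of an in-bin triplet
    a2 <- data.frame(species_key = letters[1:3], group = "PC",
                     rt_source = c(5.01, 5.02, 5.03),
                     rt_target = c(10.0, 10.1, 10.4),
                     reliability = "biological")
    k2 <- binAnchors(a2, binWidthMin = 0.5)
    expect_equal(k2$PC$target, 10.1)
    ## random anchors agree with the brute-force merge oracle
    for (seed in 1:6) {
        set.seed(seed)
        m <- 25
        src <- round(runif(m, 0, 10), 2)
        tgt <- 2 * src + rnorm(m, 0, 0.3)
        an <- data.frame(species_key = paste0("s", 1:m), group = "PC",
                         rt_source = src, rt_target = tgt,
                         reliability = "biological")
        got <- binAnchors(an, 0.5)$PC
        oracle <- bruteKnots(src, tgt, 0.5)
        expect_equal(got$source, oracle$source)
        expect_equal(got$target, oracle$target)
        expect_true(all(diff(got$source) > 0))
    }
})

test_that("spline mapping is exact at knots and affine on collinear knots", {
    id <- list(global = data.frame(source = 1:6, target = 1:6, n = 1L))
    m <- fitRTMapping(id)
    expect_equal(mapRT(m, 2.5)$rt_target, 2.5, tolerance = 1e-9)
    dbl <- list(global = data.frame(source = 1:6, target = 2 * (1:6),
                                    n = 1L))
    m2 <- fitRTMapping(dbl)
    expect_equal(mapRT(m2, 2.5)$rt_target, 5.0, tolerance = 1e-9)
    grid <- seq(0.5, 6.5, by = 0.25)
    expect_equal(mapRT(m2, grid)$rt_target, 2 * grid, tolerance = 1e-9)
    ## interpolation exactness on a curved warp
    warp <- function(t) t + 0.1 * t^2
    kn <- list(global = data.frame(source = seq(0, 10, 2),
                                   target = warp(seq(0, 10, 2)), n = 1L))
    m3 <- fitRTMapping(kn)
    expect_equal(mapRT(m3, kn$global$source)$rt_target, kn$global$target,
                 tolerance = 1e-9)
    expect_equal(mapRT(m3, 5.0)$rt_target, 7.5, tolerance = 0.05)
})

test_that("mapping extrapolates linearly and flags fallback groups", {
    kn <- list(global = data.frame(source = c(1, 2, 3),
                                   target = c(2, 4, 6), n = 1L))
    m <- fitRTMapping(kn)   # < 4 knots globally -> linear interpolant
    expect_identical(m@types[["global"]], "linear")
    out <- mapRT(m, c(2.5, 5))
    expect_equal(out$rt_target, c(5, 10))   # boundary slope 2 beyond 3
    expect_identical(out$flag, c("", "extrapolated"))
    ## unknown group falls back to global with a flag
    out2 <- mapRT(m, 2, group = "PI")
    expect_identical(out2$group_used, "global")
    expect_identical(out2$flag, "fallback")
    ## cubic groups also continue with the boundary slope
    kn2 <- list(global = data.frame(source = 1:6, target = 2 * (1:6),
                                    n = 1L))
    m2 <- fitRTMapping(kn2)
    expect_equal(mapRT(m2, 8)$rt_target, 16, tolerance = 1e-9)
    expect_identical(mapRT(m2, 8)$flag, "extrapolated")
})

test_that("mapped RTs stay monotone on well-spaced monotone warps", {
    for (seed in 1:4) {
        set.seed(seed)
        src <- seq(1, 30, by = 0.8)
        warp <- function(t) 2 * t + 3 * plogis((t - 15) / 4)
        an <- data.frame(species_key = paste0("s", seq_along(src)),
                         group = "PC", rt_source = src,
                         rt_target = warp(src),
                         reliability = "biological")
        m <- fitCalibration(an, binWidthMin = 0.5)
        grid <- seq(1, 30, by = 0.1)
        expect_true(all(diff(mapRT(m, grid)$rt_target) > 0))
    }
})

test_that("held-out deviation is small for smooth warps and bounded under noise", {
    warp <- function(t) 1.8 * t + 2 * plogis((t - 15) / 5)
    fx <- calibFixture(60, warp = warp, sd = 0, seed = 3, reps = 1)
    a <- selectAnchors(fx$db, fx$obs, strategy = 1)
    fitIdx <- seq(1, nrow(a), by = 2)[1:30]
    hold <- setdiff(seq_len(nrow(a)), fitIdx)[1:30]
    m <- fitCalibration(a[fitIdx, ])
    ev <- evaluateMapping(m, a[hold, ])
    expect_lt(ev$median_abs_dev_s, 1)
    expect_error(evaluateMapping(m, a[0, ]), "empty holdout")
    ## holdout equal to the knots is reproduced exactly
    kn <- calibrationKnots(m)$global
    ev0 <- evaluateMapping(m, data.frame(species_key = "k", group = "PC",
                                         rt_source = kn$source,
                                         rt_target = kn$target))
    expect_equal(ev0$median_abs_dev_s, 0, tolerance = 1e-9)
    ## with 2-s Gaussian anchor noise the median deviation stays in [1,4] s
    devs <- vapply(1:100, function(s) {
        fxn <- calibFixture(60, warp = warp, sd = 2 / 60, seed = 100 + s,
                            reps = 1)
        an <- selectAnchors(fxn$db, fxn$obs, strategy = 1)
        fi <- seq(1, nrow(an), by = 2)[1:30]
        ho <- setdiff(seq_len(nrow(an)), fi)[1:30]
        evaluateMapping(fitCalibration(an[fi, ]),
                        an[ho, ])$median_abs_dev_s
    }, numeric(1))
    expect_gt(median(devs), 1)
    expect_lt(median(devs), 4)
})
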