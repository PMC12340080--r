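## Synthetic-data generator: ground-truth omega-resolved RT databases,
## gradient warps, labeled/unlabeled runs with RT noise and deuterium
## isotope effects, and an end-to-end benchmark harness.
##
## The elution model is a fixture convention emulating qualitative RPLC
## behavior (RT increases with chain carbons and decreases with double
## bonds); omega-isomer family members are placed with pairwise RT
## separations of at least the configured minimum (10 s by default).

.SIM_SAT <- c("14:0", "16:0", "18:0")
.SIM_UNSAT <- list(
    `16:1` = c(7L, 10L), `18:1` = c(7L, 9L), `18:2` = c(6L, 9L),
    `18:3` = c(3L, 6L), `20:3` = c(6L, 7L, 9L), `20:4` = c(3L, 6L),
    `22:4` = c(6L, 7L), `22:5` = c(3L, 6L), `22:6` = c(3L, 6L),
    `24:5` = c(3L, 6L))
.SIM_CLASS_OFFSET <- c(PC = 0, PE = 0.3, PI = -0.4, PS = 0.2, PG = -0.2,
                       BMP = -0.1, LPC = 0, LPE = 0.3)
.SIM_STANDARDS <- data.frame(
    lipid_class = c("PC", "PC", "PE", "PI", "PG", "PC"),
    chains = c("15:0_18:1(n\u22129)", "15:0_18:2(n\u22126)",
               "15:0_16:1(n\u22127)", "15:0_20:4(n\u22126)",
               "15:0_16:1(n\u221210)", "15:0_22:6(n\u22123)"),
    stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults emulate the reference study design: a 30-min-like gradient
#' (span 0.5-32 min, dead time 0.5 min), omega-isomer families separated by
#' at least 10 s, Gaussian RT noise of 2 s, technical triplicates, six
#' authentic standards (marked with a synthetic 15:0 chain), and a
#' 30-to-60-min gradient-stretch warp.
#'
#' @param seed Mandatory integer seed; every stochastic generator call is
#'   reproducible given (config, seed).
#' @param ... Overrides for any default field, e.g. `rt_noise_sd_s`,
#'   `n_species_per_class`, `classes`, `min_separation_s`,
#'   `gradient_span_min`, `t0`, `per_deuterium_ratio`, `warp`,
#'   `n_anchors`, `n_holdout`, `match_s`, `wide_s`, `margin_factor`.
#' @return A list of class `omegaRT_sim_config`.
#' @export
simConfig <- function(seed, ...) {
    if (missing(seed) || is.na(seed))
        stop("a seed is mandatory for the simulator", call. = FALSE)
    cfg <- list(
        seed = as.integer(seed),
        classes = c("PC", "PE", "PI", "PS", "PG", "BMP", "LPC", "LPE"),
        n_species_per_class = 18L,
        family_pair_prob = 0.5,
        min_separation_s = 10,
        max_separation_factor = 3,
        gradient_span_min = c(0.5, 32),
        t0 = 0.5,
        per_deuterium_ratio = 1.0015,
        f_a = 1,
        rt_noise_sd_s = 2,
        n_replicates = 3L,
        n_standards = 6L,
        warp = list(name = "gradient_stretch", params = list(factor = 2)),
        strategy = 1L,
        n_anchors = 40L,
        n_holdout = 30L,
        bin_width_min = 0.5,
        match_s = 5, wide_s = 15, margin_factor = 2)
    cfg <- utils::modifyList(cfg, list(...))
    if (cfg$min_separation_s <= 0)
        stop("min_separation_s must be > 0", call. = FALSE)
    if (cfg$rt_noise_sd_s < 0) stop("rt_noise_sd_s must be >= 0",
                                    call. = FALSE)
    if (cfg$per_deuterium_ratio <= 0)
        stop("per_deuterium_ratio must be > 0", call. = FALSE)
    if (diff(cfg$gradient_span_min) <= 0)
        stop("gradient span must be increasing", call. = FALSE)
    class(cfg) <- "omegaRT_sim_config"
    cfg
}

.simIsotopeModel <- function(config)
    new("IsotopeEffectModel", kRatio = config$per_deuterium_ratio,
        fA = config$f_a, t0 = config$t0,
        perDeuteriumRatio = config$per_deuterium_ratio, nRef = 1)

#' Generate a ground-truth omega-resolved RT database
#'
#' Species are drawn per class from a fixed fatty-acyl pool; base RTs
#' increase with total carbons and decrease with total double bonds.
#' Molecular species hosting an unsaturated chain become omega-isomer
#' families (pairs with probability `family_pair_prob`) whose members are
#' placed with pairwise separations of at least `min_separation_s` (lower
#' omega positions elute earlier). Standards are appended as omega-resolved
#' entries with evidence "standard". Deterministic given the config seed.
#'
#' @param config A [simConfig()] configuration.
#' @return An [RTDB-class]; the entries are the ground truth.
#' @export
synthRTDB <- function(config) {
    stopifnot(inherits(config, "omegaRT_sim_config"))
    set.seed(config$seed)
    span <- config$gradient_span_min
    rtBase <- function(ctot, dtot, cls) {
        off <- .SIM_CLASS_OFFSET[cls]
        if (is.na(off)) off <- 0
        2 + 0.62 * (ctot - 12) - 0.9 * dtot + off +
            stats::runif(1, -0.4, 0.4)
    }
    rows <- list()
    for (cls in config$classes) {
        def <- .classDef(cls)
        nsp <- config$n_species_per_class
        if (nsp == 0L) next
        seen <- character()
        for (i in seq_len(nsp)) {
            for (try in 1:50) {
                un <- sample(names(.SIM_UNSAT), 1L)
                sat <- sample(.SIM_SAT, 1L)
                mol <- if (def$chain_count == 2L) paste(sat, un, sep = "_")
                       else un
                if (!(mol %in% seen)) break
            }
            if (mol %in% seen) next
            seen <- c(seen, mol)
            cd <- as.integer(strsplit(un, ":")[[1L]])
            omSet <- .SIM_UNSAT[[un]]
            fam <- if (stats::runif(1) < config$family_pair_prob &&
                       length(omSet) >= 2L)
                sort(sample(omSet, 2L)) else sample(omSet, 1L)
            ctot <- cd[1L] + if (def$chain_count == 2L)
                as.integer(sub(":.*", "", sat)) else 0L
            base <- rtBase(ctot, cd[2L], cls)
            seps <- stats::runif(length(fam),
                                 config$min_separation_s,
                                 config$min_separation_s *
                                     config$max_separation_factor) / 60
            rts <- base + cumsum(seps) - seps[1L]
            for (j in seq_along(fam)) {
                unTok <- sprintf("%d:%d(n\u2212%d)", cd[1L], cd[2L], fam[j])
                chains <- if (def$chain_count == 2L)
                    paste(sat, unTok, sep = "_") else unTok
                rows[[length(rows) + 1L]] <- data.frame(
                    lipid_class = cls, chains = chains,
                    reference_rt_min = rts[j], batches = "sim",
                    evidence = "SIL-experiment", flags = "",
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (config$n_standards > 0L) {
        std <- .SIM_STANDARDS[seq_len(min(config$n_standards,
                                          nrow(.SIM_STANDARDS))), ,
                              drop = FALSE]
        for (i in seq_len(nrow(std))) {
            ch <- parseChain(.splitChains(std$chains[i])$tokens[[1L]])
            rows[[length(rows) + 1L]] <- data.frame(
                lipid_class = std$lipid_class[i], chains = std$chains[i],
                reference_rt_min = rtBase(sum(ch$carbons),
                                          sum(ch$double_bonds),
                                          std$lipid_class[i]),
                batches = "sim", evidence = "standard", flags = "",
                stringsAsFactors = FALSE)
        }
    }
    entries <- do.call(rbind, rows)
    if (is.null(entries))
        entries <- data.frame(lipid_class = character(),
                              chains = character(),
                              reference_rt_min = numeric(),
                              batches = character())
    if (nrow(entries) &&
        (min(entries$reference_rt_min) <= config$t0 + 0.5 ||
         max(entries$reference_rt_min) >= span[2L] - 0.2))
        stop("infeasible packing: species RTs exceed the gradient span",
             call. = FALSE)
    RTDB(entries, gradientSpan = span, methodId = "sim-source")
}

#' Construct a gradient warp between chromatographic methods
#'
#' Families: `identity`; `affine` (params `a` > 0, `b`);
#' `gradient_stretch` (param `factor`, default 2: a continuous piecewise
#' linear map emulating a 30-min method re-run as a 60-min-like method,
#' nonuniform in the middle of the gradient); `logistic` (params
#' `amplitude` >= 0, `midpoint`, `scale` > 0: t + amplitude *
#' plogis((t - midpoint)/scale)). All warps are validated to be strictly
#' increasing over the span.
#'
#' @param name Warp family name.
#' @param params Named list of family parameters.
#' @param span Source gradient span (minutes) used for validation and for
#'   the stretch control points.
#' @return A vectorized warp function of RT in minutes.
#' @export
makeWarp <- function(name = c("identity", "affine", "gradient_stretch",
                              "logistic"),
                     params = list(), span = c(0.5, 32)) {
    name <- match.arg(name)
    f <- switch(name,
        identity = function(t) t,
        affine = {
            a <- params$a %||% 1; b <- params$b %||% 0
            if (a <= 0) stop("non-monotone parameterization: a must be > 0",
                             call. = FALSE)
            function(t) a * t + b
        },
        gradient_stretch = {
            fac <- params$factor %||% 2
            if (fac <= 0)
                stop("non-monotone parameterization: factor must be > 0",
                     call. = FALSE)
            xs <- span[2L] * c(0, 0.12, 0.35, 0.6, 1)
            ys <- fac * span[2L] * c(0, 0.2, 0.42, 0.68, 1)
            .linearMap(xs, ys)
        },
        logistic = {
            A <- params$amplitude %||% 2
            m <- params$midpoint %||% mean(span)
            s <- params$scale %||% (diff(span) / 8)
            if (A < 0 || s <= 0)
                stop("non-monotone parameterization of logistic warp",
                     call. = FALSE)
            function(t) t + A * stats::plogis((t - m) / s)
        })
    grid <- seq(span[1L], span[2L], length.out = 512L)
    if (any(diff(f(grid)) <= 0))
        stop("non-monotone parameterization: warp is not strictly ",
             "increasing over the span", call. = FALSE)
    f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an LC-MS/MS identification run from a ground-truth database
#'
#' Observed RT = warp(true RT), shifted by the deuterium isotope effect for
#' labeled species (the exact inverse of [correctLabeledRT()], so the
#' noiseless round trip is exact), plus Gaussian RT noise truncated to the
#' warped gradient span. With a `labelPlan`, only species with at least one
#' chain whose omega matches a plan label are emitted, carrying the label
#' prefixes (the partner chain loses its omega, as in a real single-label
#' experiment); without, a routine run is emitted in which biological
#' species appear at molecular level (omega unknown) and standards keep
#' their omega identity.
#'
#' @param db Ground-truth [RTDB-class] from [synthRTDB()].
#' @param warp Warp function from [makeWarp()].
#' @param config A [simConfig()] configuration.
#' @param labelPlan NULL, or a character vector of SIL label codes applied
#'   to every omega-matching chain.
#' @param runId Run identifier.
#' @param seed Seed for the stochastic parts (defaults to config seed + 1).
#' @param registry SIL label registry.
#' @return data.frame with observation columns (`run_id`, `replicate`,
#'   `lipid_class`, `chains`, `sn_resolved`, `rt_min`, `mz`, `intensity`,
#'   `standard`, `batch`) and ground-truth columns (`true_key`,
#'   `true_rt_min`).
#' @export
simulateRun <- function(db, warp, config, labelPlan = NULL,
                        runId = "simrun", seed = config$seed + 1L,
                        registry = silLabelRegistry()) {
    stopifnot(inherits(config, "omegaRT_sim_config"))
    set.seed(seed)
    e <- rtdbEntries(db)
    iso <- .simIsotopeModel(config)
    if (!is.null(labelPlan)) {
        i <- match(labelPlan, registry$code)
        if (anyNA(i))
            stop("unknown label code in plan: ",
                 paste(labelPlan[is.na(i)], collapse = ", "), call. = FALSE)
        planOmega <- stats::setNames(registry$omega[i], labelPlan)
    }
    rows <- list()
    for (k in seq_len(nrow(e))) {
        isStd <- e$evidence[k] == "standard"
        ch <- parseChain(.splitChains(e$chains[k])$tokens[[1L]])
        dCounts <- integer(nrow(ch))
        if (!is.null(labelPlan)) {
            if (isStd) next
            hit <- !is.na(ch$omega) & ch$omega %in% planOmega
            if (!any(hit)) next
            ch$label[hit] <- names(planOmega)[match(ch$omega[hit],
                                                    planOmega)]
            ch$omega[!hit] <- NA_integer_
            dCounts <- .chainDCount(ch, registry)
            obsChains <- paste(formatChain(ch), collapse = "_")
        } else if (isStd) {
            obsChains <- e$chains[k]
        } else {
            obsChains <- paste(formatChain(.sortChains(.stripOmega(ch))),
                               collapse = "_")
        }
        rtTrue <- .labeledRT(warp(e$reference_rt_min[k]), list(dCounts),
                             iso)
        mz <- .speciesMz(e$lipid_class[k], ch,
                         .classDef(e$lipid_class[k])$default_adduct)
        inten <- stats::rlnorm(1, meanlog = 13, sdlog = 1.2)
        for (rep in seq_len(config$n_replicates)) {
            rows[[length(rows) + 1L]] <- data.frame(
                run_id = runId, replicate = rep,
                lipid_class = e$lipid_class[k], chains = obsChains,
                sn_resolved = FALSE, rt_min = rtTrue, mz = mz,
                intensity = inten, standard = isStd, batch = runId,
                true_key = e$species_key_omega[k],
                true_rt_min = warp(e$reference_rt_min[k]),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(out)
    lim <- range(warp(gradientSpan(db)))
    noise <- stats::rnorm(nrow(out), 0, config$rt_noise_sd_s / 60)
    out$rt_min <- pmin(pmax(out$rt_min + noise, lim[1L]), lim[2L])
    rownames(out) <- NULL
    out
}

#' End-to-end benchmark of calibration and annotation
#'
#' For each seed: generate a ground-truth database, simulate a target run
#' under the configured warp and noise, select anchors, fit the RT mapping
#' on an anchor subset, evaluate held-out anchors, map the database, run
#' the annotation and score it against the ground truth.
#'
#' @param config A [simConfig()] configuration (its `warp`, `strategy`,
#'   `n_anchors`, `n_holdout` and assignment policy fields drive the
#'   pipeline).
#' @param nSeeds Number of independent seeds (default 20).
#' @return List with `per_seed` (one row per seed: calibration deviations
#'   in seconds, annotation precision/recall, counts) and `summary`
#'   (means, SDs and pooled medians across seeds).
#' @export
benchmarkPipeline <- function(config, nSeeds = 20L) {
    stopifnot(inherits(config, "omegaRT_sim_config"))
    res <- list()
    for (s in seq_len(nSeeds)) {
        cfg <- config
        cfg$seed <- config$seed + 1000L * s
        db <- synthRTDB(cfg)
        warp <- makeWarp(cfg$warp$name, cfg$warp$params,
                         span = cfg$gradient_span_min)
        target <- simulateRun(db, warp, cfg, runId = paste0("seed", s),
                              seed = cfg$seed + 1L)
        anchors <- selectAnchors(db, target, strategy = cfg$strategy)
        n <- nrow(anchors)
        nFit <- min(cfg$n_anchors, max(2L, n - 2L))
        fitIdx <- unique(round(seq(1L, n, length.out = nFit)))
        hold <- setdiff(seq_len(n), fitIdx)
        if (length(hold) > cfg$n_holdout)
            hold <- hold[unique(round(seq(1L, length(hold),
                                          length.out = cfg$n_holdout)))]
        model <- fitCalibration(anchors[fitIdx, , drop = FALSE],
                                binWidthMin = cfg$bin_width_min)
        ev <- evaluateMapping(model, anchors[hold, , drop = FALSE])
        mapped <- applyCalibration(db, model)
        bio <- target[!target$standard, , drop = FALSE]
        ann <- annotateRun(bio, mapped, matchS = cfg$match_s,
                           wideS = cfg$wide_s,
                           marginFactor = cfg$margin_factor)$annotations
        auto <- ann$status == "automated"
        correct <- auto & ann$assigned_key == ann$true_key
        res[[s]] <- data.frame(
            seed = cfg$seed,
            median_dev_s = ev$median_abs_dev_s,
            mean_dev_s = ev$mean_abs_dev_s,
            n_anchors_fit = length(fitIdx), n_holdout = ev$n,
            n_peaks = nrow(ann), n_automated = sum(auto),
            precision_automated = if (any(auto))
                sum(correct) / sum(auto) else NA_real_,
            recall_automated = sum(correct) / nrow(ann))
    }
    per <- do.call(rbind, res)
    list(per_seed = per,
         summary = list(
             median_dev_s = stats::median(per$median_dev_s),
             mean_dev_s = mean(per$mean_dev_s),
             median_dev_s_sd = stats::sd(per$median_dev_s),
             mean_dev_s_sd = stats::sd(per$mean_dev_s),
             precision_automated = mean(per$precision_automated,
                                        na.rm = TRUE),
             recall_automated = mean(per$recall_automated),
             n_seeds = nSeeds))
}
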