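## Anchor-species selection and cubic-spline RT mapping between
## chromatographic conditions.

#' Select anchor species shared between an RT database and a target run
#'
#' Anchors are species present on both sides: the database provides the
#' source RT, the target identification table the observed RT (median over
#' replicate observations of the same peak). Standards (rows with
#' `standard = TRUE`, matched at omega level) and biological species
#' (matched at molecular level, which requires a unique database entry for
#' that molecular species) are distinguished by a reliability tier.
#'
#' Three strategies: 1 maximizes the anchor count (all single-peak shared
#' species; when standards are available they screen biological outliers
#' against a preliminary standards-only fit); 2 prioritizes reliability
#' (standards plus biological anchors with replicate RT spread below
#' `sdMaxMin` and a single chromatographic peak); 3 takes all matches (the
#' strategy for runs of standards), keeping multi-peak species as multiple
#' candidate anchors when they are standards.
#'
#' @param db Source [RTDB-class].
#' @param target Identification table with columns `lipid_class` (or
#'   `class`), `chains`, `rt_min`, optional `standard` (logical) and
#'   `run_id`.
#' @param strategy 1, 2 or 3.
#' @param standardsAvailable Whether standard measurements are available;
#'   defaults to the presence of `standard = TRUE` rows.
#' @param control List of screen thresholds: `sdMaxMin` (replicate RT SD
#'   ceiling, min, default 0.05), `multiPeakGapMin` (gap splitting replicate
#'   observations into separate peaks, default 0.2), `outlierMaxMin`
#'   (residual ceiling for the standards-based outlier screen, default 1).
#' @return data.frame of anchors: `species_key`, `group` (lipid class),
#'   `rt_source`, `rt_target`, `reliability`, `n_obs`, `rt_sd`, ordered by
#'   source RT then key.
#' @export
selectAnchors <- function(db, target, strategy = 2L,
                          standardsAvailable = NULL,
                          control = list()) {
    ctl <- utils::modifyList(list(sdMaxMin = 0.05, multiPeakGapMin = 0.2,
                                  outlierMaxMin = 1), control)
    if (!strategy %in% 1:3) stop("strategy must be 1, 2 or 3", call. = FALSE)
    if (is.null(target$lipid_class) && !is.null(target$class))
        target$lipid_class <- target$class
    if (is.null(target$standard)) target$standard <- FALSE
    if (is.null(standardsAvailable))
        standardsAvailable <- any(target$standard)
    e <- rtdbEntries(db)
    e <- e[e$flags != "conflict", , drop = FALSE]
    molCount <- table(e$species_molecular)

    tkeyMol <- .molecularKey(target$lipid_class, target$chains)
    tkeyOm <- ifelse(target$standard,
                     vapply(seq_len(nrow(target)), function(i) {
                         k <- .chainKeys(target$lipid_class[i],
                                         target$chains[i])
                         k$omega
                     }, character(1)), NA_character_)

    anchors <- list()
    for (key in unique(ifelse(target$standard, tkeyOm, tkeyMol))) {
        isStd <- key %in% e$species_key_omega &&
            any(target$standard[tkeyOm %in% key])
        if (isStd) {
            rowsT <- which(tkeyOm %in% key & target$standard)
            dbRow <- e[e$species_key_omega == key, , drop = FALSE]
        } else {
            rowsT <- which(tkeyMol == key & !target$standard)
            dbRow <- e[e$species_molecular == key, , drop = FALSE]
            if (nrow(dbRow) != 1L) next   # omega-ambiguous in the DB
        }
        if (!length(rowsT) || !nrow(dbRow)) next
        rts <- sort(target$rt_min[rowsT])
        peaks <- split(rts, cumsum(c(1, diff(rts) > ctl$multiPeakGapMin)))
        multi <- length(peaks) > 1L
        if (multi && !(strategy == 3L && isStd)) next
        for (p in peaks) {
            anchors[[length(anchors) + 1L]] <- data.frame(
                species_key = key, group = dbRow$lipid_class[1L],
                rt_source = dbRow$reference_rt_min[1L],
                rt_target = stats::median(p),
                reliability = if (isStd) "standard" else "biological",
                n_obs = length(p), rt_sd = stats::sd(p),
                stringsAsFactors = FALSE)
        }
    }
    a <- do.call(rbind, anchors)
    if (is.null(a) || !nrow(a)) stop("no anchors", call. = FALSE)
    a$rt_sd[is.na(a$rt_sd)] <- 0
    if (strategy == 2L)
        a <- a[a$reliability == "standard" | a$rt_sd <= ctl$sdMaxMin, ,
               drop = FALSE]
    if (strategy == 1L && standardsAvailable) {
        std <- a[a$reliability == "standard", , drop = FALSE]
        if (nrow(std) >= 2L) {
            f <- if (nrow(std) >= 4L)
                stats::splinefun(std$rt_source, std$rt_target,
                                 method = "natural")
            else {
                co <- stats::coef(stats::lm(rt_target ~ rt_source,
                                            data = std))
                function(x) co[1L] + co[2L] * x
            }
            resid <- abs(a$rt_target - f(a$rt_source))
            a <- a[a$reliability == "standard" |
                       resid <= ctl$outlierMaxMin, , drop = FALSE]
        }
    }
    if (!nrow(a)) stop("no anchors", call. = FALSE)
    a <- a[order(a$rt_source, a$species_key), , drop = FALSE]
    rownames(a) <- NULL
    a
}

#' Bin anchors into spline knots
#'
#' Anchors of each group (and of the pooled "global" group) are partitioned
#' into source-RT bins of `binWidthMin`; each non-empty bin contributes one
#' knot at the median source and median target RT of its members. Adjacent
#' knots that are not strictly increasing in source RT are re-merged (their
#' member anchors pooled and re-medianed) until the knot sequence is
#' strictly increasing.
#'
#' @param anchors Anchor data.frame from [selectAnchors()].
#' @param binWidthMin Bin width in minutes (default 0.5).
#' @return Named list of knot data.frames (`source`, `target`, `n`), one
#'   per group plus `"global"`.
#' @export
binAnchors <- function(anchors, binWidthMin = 0.5) {
    if (!nrow(anchors)) stop("no anchors to bin", call. = FALSE)
    groups <- c(split(anchors, anchors$group), list(global = anchors))
    lapply(groups, function(a) .binOne(a, binWidthMin))
}

.binOne <- function(a, binWidthMin) {
    bin <- floor(a$rt_source / binWidthMin)
    members <- split(seq_len(nrow(a)), bin)
    knot <- function(idx) c(source = stats::median(a$rt_source[idx]),
                            target = stats::median(a$rt_target[idx]),
                            n = length(idx))
    k <- do.call(rbind, lapply(members, knot))
    k <- k[order(k[, "source"]), , drop = FALSE]
    members <- members[order(vapply(members, function(i)
        stats::median(a$rt_source[i]), numeric(1)))]
    ## re-merge until strictly increasing in source RT
    repeat {
        if (nrow(k) < 2L || all(diff(k[, "source"]) > 0)) break
        i <- which(diff(k[, "source"]) <= 0)[1L]
        members[[i]] <- c(members[[i]], members[[i + 1L]])
        members[[i + 1L]] <- NULL
        k <- do.call(rbind, lapply(members, knot))
    }
    data.frame(source = k[, "source"], target = k[, "target"],
               n = as.integer(k[, "n"]), row.names = NULL)
}

#' Fit per-group RT mapping models
#'
#' Groups with at least 4 knots get a natural interpolating cubic spline
#' through their knots; sparser groups are not fitted and fall back (class
#' -> user-defined group -> global) at mapping time. If even the global
#' pool has fewer than 4 knots, a linear interpolant is used for it when it
#' has at least 2; with no group reaching 2 knots fitting fails.
#'
#' @param knots Named list of knot data.frames from [binAnchors()].
#' @param groupOf Optional named character vector assigning lipid classes
#'   to user-defined groups (the middle link of the fallback chain).
#' @param binWidthMin Bin width recorded in the model.
#' @return A [CalibrationModel-class].
#' @export
fitRTMapping <- function(knots, groupOf = character(),
                         binWidthMin = 0.5) {
    funs <- list(); types <- character(); kn <- list(); rngs <- list()
    for (g in names(knots)) {
        k <- knots[[g]]
        if (nrow(k) >= 4L) {
            funs[[g]] <- stats::splinefun(k$source, k$target,
                                          method = "natural")
            types[[g]] <- "cubic"
        } else if (g == "global" && nrow(k) >= 2L) {
            funs[[g]] <- .linearMap(k$source, k$target)
            types[[g]] <- "linear"
        } else next
        kn[[g]] <- k
        rngs[[g]] <- range(k$source)
    }
    if (!length(funs))
        stop("no group has enough knots (>= 4, or >= 2 globally) to fit a ",
             "mapping", call. = FALSE)
    new("CalibrationModel", funs = funs, knots = kn, types = types,
        ranges = rngs, groupOf = groupOf, binWidth = binWidthMin)
}

## piecewise-linear interpolant with boundary-slope extrapolation
.linearMap <- function(x, y) {
    force(x); force(y)
    n <- length(x)
    sl <- diff(y) / diff(x)
    function(t) {
        out <- stats::approx(x, y, xout = pmin(pmax(t, x[1L]), x[n]))$y
        lo <- t < x[1L]; hi <- t > x[n]
        out[lo] <- y[1L] + sl[1L] * (t[lo] - x[1L])
        out[hi] <- y[n] + sl[n - 1L] * (t[hi] - x[n])
        out
    }
}

#' Convenience: anchors to fitted calibration in one step
#'
#' @param anchors Anchor data.frame from [selectAnchors()].
#' @param binWidthMin Bin width in minutes.
#' @param groupOf Optional class -> user-group assignment.
#' @return A [CalibrationModel-class].
#' @export
fitCalibration <- function(anchors, binWidthMin = 0.5,
                           groupOf = character()) {
    fitRTMapping(binAnchors(anchors, binWidthMin), groupOf = groupOf,
                 binWidthMin = binWidthMin)
}

#' Map source retention times onto the target chromatography
#'
#' Resolves each requested group along the fallback chain (group ->
#' user-defined group -> global) to a fitted interpolant, taking for every
#' RT the most specific model whose knot range covers it. When no model in
#' the chain covers the RT, the widest (global) model continues linearly
#' with its boundary slope and the result is flagged "extrapolated";
#' mappings served by a fallback group are flagged "fallback".
#'
#' @param model A [CalibrationModel-class].
#' @param rtSource Source retention times (minutes).
#' @param group Group name(s), recycled along `rtSource`.
#' @return data.frame with `rt_target`, `group_used`, `flag`.
#' @export
mapRT <- function(model, rtSource, group = "global") {
    group <- rep_len(group, length(rtSource))
    out <- data.frame(rt_target = numeric(length(rtSource)),
                      group_used = character(length(rtSource)),
                      flag = character(length(rtSource)),
                      stringsAsFactors = FALSE)
    for (g in unique(group)) {
        chain <- unique(c(g, unname(model@groupOf[g]), "global"))
        chain <- chain[!is.na(chain) & chain %in% names(model@funs)]
        if (!length(chain))
            stop("no mapping available for group '", g,
                 "' (empty fallback chain)", call. = FALSE)
        i <- which(group == g)
        ## per RT: the most specific model whose knot range covers it;
        ## if none does, extrapolate with the widest (last) model
        covers <- vapply(chain, function(u) {
            rng <- model@ranges[[u]]
            rtSource[i] >= rng[1L] & rtSource[i] <= rng[2L]
        }, logical(length(i)))
        covers <- matrix(covers, nrow = length(i))
        pick <- apply(covers, 1L, function(z) which(z)[1L])
        ex <- is.na(pick)
        pick[ex] <- length(chain)
        use <- chain[pick]
        out$rt_target[i] <- vapply(seq_along(i), function(j)
            model@funs[[use[j]]](rtSource[i[j]]), numeric(1))
        out$group_used[i] <- use
        flags <- ifelse(use != g, "fallback", "")
        flags[ex] <- trimws(paste(flags[ex], "extrapolated"))
        out$flag[i] <- flags
    }
    out
}

#' Map a whole RT database onto the target chromatography
#'
#' @param db Source [RTDB-class].
#' @param model A [CalibrationModel-class] fitted from source -> target
#'   anchors.
#' @param methodId Identifier for the target chromatography.
#' @return An [RTDB-class] with mapped reference RTs; mapping flags are
#'   appended to the entry flags.
#' @export
applyCalibration <- function(db, model, methodId = "mapped") {
    e <- rtdbEntries(db)
    if (nrow(e)) {
        m <- mapRT(model, e$reference_rt_min, group = e$lipid_class)
        e$reference_rt_min <- m$rt_target
        e$flags <- trimws(paste(e$flags, m$flag))
    }
    span <- range(c(vapply(model@knots, function(k) range(k$target),
                           numeric(2)),
                    if (nrow(e)) e$reference_rt_min))
    span <- span + c(-0.5, 0.5)
    RTDB(e, gradientSpan = span, methodId = methodId)
}

#' Evaluate a calibration on held-out anchors
#'
#' @param model A [CalibrationModel-class].
#' @param holdout Anchor data.frame (disjoint from the anchors used to
#'   fit).
#' @return List with `median_abs_dev_s`, `mean_abs_dev_s`, `n` and a
#'   `per_group` data.frame.
#' @export
evaluateMapping <- function(model, holdout) {
    if (is.null(holdout) || !nrow(holdout))
        stop("empty holdout set", call. = FALSE)
    pred <- mapRT(model, holdout$rt_source, group = holdout$group)
    dev <- (pred$rt_target - holdout$rt_target) * 60
    per <- do.call(rbind, lapply(split(abs(dev), holdout$group),
                                 function(d) data.frame(
                                     median_abs_dev_s = stats::median(d),
                                     mean_abs_dev_s = mean(d),
                                     n = length(d))))
    per$group <- rownames(per); rownames(per) <- NULL
    list(median_abs_dev_s = stats::median(abs(dev)),
         mean_abs_dev_s = mean(abs(dev)), n = length(dev),
         per_group = per[, c("group", "median_abs_dev_s", "mean_abs_dev_s",
                             "n")])
}
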