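## Assigning chain-specific omega positions to identified molecular species
## using a mapped RT database.
##
## Assignments never cross molecular-species keys: a peak identified as
## PC 18:0_22:5 can only receive omega-resolved DB entries of PC 18:0_22:5,
## so coeluting isomers of the same sum composition (e.g. PC 16:0_24:5 at
## the same RT) are resolved per species, never per sum composition.

#' Find omega-resolved database candidates for one peak
#'
#' Candidates are database entries whose native molecular-species key
#' (omega stripped) equals the peak's key and whose mapped reference RT
#' lies within `rtWindowS` of the observed peak RT, sorted by |dRT|. When
#' the peak carries an m/z and an adduct, candidates additionally must
#' match the theoretical m/z within `mzTolPpm`.
#'
#' @param peak List or one-row data.frame with `lipid_class` (or `class`),
#'   `chains`, `rt_min`, optional `mz` and `adduct`.
#' @param db Mapped [RTDB-class] on the same gradient as the peak's run.
#' @param rtWindowS Candidate window in seconds (default 15).
#' @param mzTolPpm m/z tolerance in ppm (default 10).
#' @return data.frame of candidates: `species_key_omega`, `chains`,
#'   `reference_rt_min`, `delta_rt_s`, `flags`; empty when nothing matches.
#' @export
findCandidates <- function(peak, db, rtWindowS = 15, mzTolPpm = 10) {
    peak <- as.list(peak)
    if (is.null(peak$lipid_class)) peak$lipid_class <- peak$class
    key <- .molecularKey(peak$lipid_class, peak$chains)
    e <- rtdbEntries(db)
    cand <- e[e$species_molecular == key & e$flags != "conflict", ,
              drop = FALSE]
    if (nrow(cand) && !is.null(peak$mz) && !is.na(peak$mz) &&
        !is.null(peak$adduct) && !is.na(peak$adduct)) {
        keep <- vapply(seq_len(nrow(cand)), function(i) {
            ch <- parseChain(.splitChains(cand$chains[i])$tokens[[1L]])
            mzWithin(peak$mz, .speciesMz(cand$lipid_class[i], ch,
                                         peak$adduct), ppm = mzTolPpm)
        }, logical(1))
        cand <- cand[keep, , drop = FALSE]
    }
    if (!nrow(cand))
        return(data.frame(species_key_omega = character(),
                          chains = character(),
                          reference_rt_min = numeric(),
                          delta_rt_s = numeric(), flags = character()))
    cand$delta_rt_s <- (cand$reference_rt_min - peak$rt_min) * 60
    cand <- cand[abs(cand$delta_rt_s) <= rtWindowS, , drop = FALSE]
    cand <- cand[order(abs(cand$delta_rt_s)), , drop = FALSE]
    rownames(cand) <- NULL
    cand[, c("species_key_omega", "chains", "reference_rt_min",
             "delta_rt_s", "flags")]
}

#' Decide the omega assignment for one peak
#'
#' Policy: \emph{automated} iff exactly one candidate lies inside the match
#' window and its nearest competitor (any other candidate in the wide
#' window) is at least `marginFactor` times farther from the peak;
#' \emph{ambiguous} iff two or more candidates fall inside the match
#' window; \emph{suggested} iff candidates exist in the wide window but the
#' automated conditions fail; \emph{none} otherwise. The confidence of a
#' chosen entry is max(0, 1 - |dRT|/match_s), monotone decreasing in
#' |dRT|.
#'
#' @param candidates Candidate data.frame from [findCandidates()] (wide
#'   window).
#' @param matchS Match window in seconds (default 5, mirroring the omega
#'   grouping tolerance).
#' @param marginFactor Required ratio between the nearest competitor's and
#'   the chosen candidate's |dRT| (default 2).
#' @return List: `status` ("automated", "suggested", "ambiguous", "none"),
#'   `chosen` (one-row candidate data.frame or NULL), `confidence`,
#'   `competitors` (remaining candidates with their dRT).
#' @export
assignOmega <- function(candidates, matchS = 5, marginFactor = 2) {
    empty <- list(status = "none", chosen = NULL, confidence = 0,
                  competitors = candidates[0, , drop = FALSE])
    if (!nrow(candidates)) return(empty)
    within <- abs(candidates$delta_rt_s) <= matchS
    if (sum(within) >= 2L)
        return(list(status = "ambiguous", chosen = NULL, confidence = 0,
                    competitors = candidates))
    chosen <- candidates[1L, , drop = FALSE]
    competitors <- candidates[-1L, , drop = FALSE]
    conf <- max(0, 1 - abs(chosen$delta_rt_s) / matchS)
    if (sum(within) == 1L) {
        marginOk <- !nrow(competitors) ||
            min(abs(competitors$delta_rt_s)) >=
                marginFactor * abs(chosen$delta_rt_s)
        if (marginOk)
            return(list(status = "automated", chosen = chosen,
                        confidence = conf, competitors = competitors))
    }
    list(status = "suggested", chosen = chosen, confidence = conf,
         competitors = competitors)
}

#' Annotate an identification table with omega positions
#'
#' Every row is matched against the mapped database and receives an
#' assignment status, the chosen omega-resolved key, its dRT and a
#' confidence. Runs whose RT range falls outside the database's gradient
#' span by more than `spanSlackMin` abort with an error advising
#' calibration, since that indicates the database was not mapped to this
#' chromatography.
#'
#' @param ids Identification table: `lipid_class` (or `class`), `chains`,
#'   `rt_min`; optional `mz`, `adduct`, `run_id`.
#' @param db Mapped [RTDB-class].
#' @param matchS,wideS,marginFactor,mzTolPpm Assignment policy (seconds,
#'   seconds, ratio, ppm).
#' @param spanSlackMin Permitted excess of run RTs over the database
#'   gradient span, minutes (default 3).
#' @return List with `annotations` (the input plus `status`,
#'   `assigned_key`, `assigned_chains`, `delta_rt_s`, `confidence`,
#'   `n_candidates`) and `summary` (counts by status).
#' @export
annotateRun <- function(ids, db, matchS = 5, wideS = 15, marginFactor = 2,
                        mzTolPpm = 10, spanSlackMin = 3) {
    if (is.null(ids$lipid_class) && !is.null(ids$class))
        ids$lipid_class <- ids$class
    need <- c("lipid_class", "chains", "rt_min")
    miss <- setdiff(need, names(ids))
    if (length(miss))
        stop("identification table lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    span <- gradientSpan(db)
    if (nrow(ids) &&
        (min(ids$rt_min) < span[1L] - spanSlackMin ||
         max(ids$rt_min) > span[2L] + spanSlackMin))
        stop("run retention times fall outside the database gradient span ",
             sprintf("(%.1f-%.1f min): ", span[1L], span[2L]),
             "map the RT-DB to this chromatography first (see ",
             "selectAnchors/fitRTMapping/applyCalibration)", call. = FALSE)
    n <- nrow(ids)
    ids$status <- rep("none", n)
    ids$assigned_key <- rep(NA_character_, n)
    ids$assigned_chains <- rep(NA_character_, n)
    ids$delta_rt_s <- rep(NA_real_, n)
    ids$confidence <- rep(NA_real_, n)
    ids$n_candidates <- rep(0L, n)
    for (i in seq_len(n)) {
        cand <- findCandidates(ids[i, , drop = FALSE], db,
                               rtWindowS = wideS, mzTolPpm = mzTolPpm)
        a <- assignOmega(cand, matchS = matchS,
                         marginFactor = marginFactor)
        ids$status[i] <- a$status
        ids$n_candidates[i] <- nrow(cand)
        if (!is.null(a$chosen)) {
            ids$assigned_key[i] <- a$chosen$species_key_omega
            ids$assigned_chains[i] <- a$chosen$chains
            ids$delta_rt_s[i] <- a$chosen$delta_rt_s
            ids$confidence[i] <- a$confidence
        }
    }
    lev <- c("automated", "suggested", "ambiguous", "none")
    summary <- as.data.frame(table(factor(ids$status, levels = lev)),
                             stringsAsFactors = FALSE)
    names(summary) <- c("status", "n")
    list(annotations = ids, summary = summary)
}
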