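#' @import methods
NULL

setOldClass("data.frame")

#' Lipid molecular species
#'
#' A lipid (sub)class with its fatty-acyl chains at molecular-species level,
#' optionally sn-resolved, with an adduct. Chains are stored as the
#' vectorized chain table produced by [parseChain()].
#'
#' @slot lipidClass Character, a class registered in [lipidClassRegistry()].
#' @slot chains data.frame of chains (one row per chain).
#' @slot snResolved Logical; if TRUE chain order is the sn order.
#' @slot adduct Character adduct name or NA.
#' @export
setClass("LipidSpecies",
         representation(lipidClass = "character", chains = "data.frame",
                        snResolved = "logical", adduct = "character"))

setValidity("LipidSpecies", function(object) {
    def <- tryCatch(.classDef(object@lipidClass),
                    error = function(e) conditionMessage(e))
    if (is.character(def)) return(def)
    if (nrow(object@chains) != def$chain_count)
        return(sprintf("class %s requires %d chain(s), got %d",
                       object@lipidClass, def$chain_count,
                       nrow(object@chains)))
    msg <- tryCatch({ .validateChains(object@chains); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(msg)) return(msg)
    if (def$ether_linkage != "none" &&
        sum(object@chains$linkage == def$ether_linkage) != 1L)
        return(sprintf("class %s requires exactly one %s chain",
                       object@lipidClass, def$ether_linkage))
    if (!is.na(object@adduct)) {
        ad <- tryCatch(.adductDef(object@adduct),
                       error = function(e) conditionMessage(e))
        if (is.character(ad)) return(ad)
    }
    TRUE
})

#' Construct a LipidSpecies
#'
#' @param lipidClass Registered lipid class (e.g. "PC", "PI", "LPC").
#' @param chains Chain tokens, either a character vector (or a single joined
#'   string with "_" or "/" separators) or a chain data.frame.
#' @param snResolved Logical; defaults to TRUE when a "/"-joined string is
#'   given.
#' @param adduct Optional adduct name.
#' @return A [LipidSpecies-class] object.
#' @export
#' @examples
#' LipidSpecies("PC", "16:0_20:4(n−6)")
#' LipidSpecies("PI", "18:0/20:3(n−9)")
LipidSpecies <- function(lipidClass, chains, snResolved = NA,
                         adduct = NA_character_) {
    if (is.character(chains)) {
        if (length(chains) == 1L && grepl("[_/]", chains)) {
            sp <- .splitChains(chains)
            if (is.na(snResolved)) snResolved <- sp$sn_resolved
            chains <- sp$tokens[[1L]]
        }
        chains <- parseChain(chains)
    }
    if (is.na(snResolved)) snResolved <- FALSE
    new("LipidSpecies", lipidClass = lipidClass, chains = chains,
        snResolved = snResolved, adduct = adduct)
}

setMethod("show", "LipidSpecies", function(object) {
    cat("LipidSpecies:",
        speciesKey(object,
                   level = if (object@snResolved) "sn" else "molecular"),
        if (!is.na(object@adduct)) object@adduct else "", "\n")
})

#' Deuterium isotope-effect model for retention-time correction
#'
#' Captures the adjusted total isotope effect (aTIE) estimated from pairs of
#' native and deuterated standards:
#' aTIE = ((k_H / k_D) - 1) / f_a + 1, with retention factors
#' k = (t_R - t_0) / t_0. The per-deuterium retention-factor ratio is
#' k_ratio^(1/n_ref), where n_ref is the deuterium count of the calibration
#' standard scale.
#'
#' @slot kRatio k_H / k_D at the reference deuterium count.
#' @slot fA Gradient-adjustment factor (default 1).
#' @slot t0 Column dead time, minutes.
#' @slot perDeuteriumRatio Per-deuterium retention-factor ratio.
#' @slot nRef Reference deuterium count for `kRatio`.
#' @export
setClass("IsotopeEffectModel",
         representation(kRatio = "numeric", fA = "numeric", t0 = "numeric",
                        perDeuteriumRatio = "numeric", nRef = "numeric"))

setValidity("IsotopeEffectModel", function(object) {
    if (object@kRatio <= 0) return("kRatio must be > 0")
    if (object@fA <= 0) return("fA must be > 0")
    if (object@t0 < 0) return("t0 must be >= 0")
    if (object@perDeuteriumRatio <= 0)
        return("perDeuteriumRatio must be > 0")
    if (abs(object@perDeuteriumRatio^object@nRef - object@kRatio) > 1e-8)
        return("perDeuteriumRatio inconsistent with kRatio and nRef")
    TRUE
})

setMethod("show", "IsotopeEffectModel", function(object) {
    cat(sprintf(paste0("IsotopeEffectModel: aTIE = %.5f (k_H/k_D = %.5f at ",
                       "n_D = %g, f_a = %g, t0 = %g min)\n"),
                aTIE(object), object@kRatio, object@nRef, object@fA,
                object@t0))
})

#' Omega-resolved retention-time database
#'
#' Entries are native (label-free) lipid molecular species with
#' experimentally verified omega positions and a reference retention time
#' under a defined chromatography, together with the measurement batches the
#' evidence came from.
#'
#' @slot entries data.frame with columns `lipid_class`, `chains`
#'   (omega-resolved, "_"-joined), `species_key_omega`, `species_molecular`
#'   (omega-stripped matching key), `reference_rt_min`, `batches`
#'   (";"-joined), `evidence` (`SIL-experiment`, `orthogonal`, `standard`),
#'   `flags`.
#' @slot gradientSpan Numeric length-2, gradient span in minutes.
#' @slot methodId Free-text chromatographic method identifier.
#' @slot log data.frame of rows skipped while building (row, reason).
#' @export
setClass("RTDB",
         representation(entries = "data.frame", gradientSpan = "numeric",
                        methodId = "character", log = "data.frame"))

.RTDB_COLS <- c("lipid_class", "chains", "species_key_omega",
                "species_molecular", "reference_rt_min", "batches",
                "evidence", "flags")

setValidity("RTDB", function(object) {
    miss <- setdiff(.RTDB_COLS, names(object@entries))
    if (length(miss))
        return(paste("entries lack column(s):", paste(miss, collapse = ", ")))
    if (length(object@gradientSpan) != 2L ||
        diff(object@gradientSpan) <= 0)
        return("gradientSpan must be two increasing minutes values")
    e <- object@entries
    if (nrow(e)) {
        if (any(e$reference_rt_min < object@gradientSpan[1L] |
                e$reference_rt_min > object@gradientSpan[2L]))
            return("reference_rt_min outside the gradient span")
        if (any(!nzchar(e$batches) | is.na(e$batches)))
            return("every entry needs at least one source batch")
    }
    TRUE
})

#' Construct an RTDB from an entry table
#'
#' @param entries Entry data.frame; minimally `lipid_class`, `chains`,
#'   `reference_rt_min`, `batches`; the keys, `evidence` and `flags` columns
#'   are derived/filled when absent.
#' @param gradientSpan Gradient span in minutes, length 2.
#' @param methodId Chromatographic method identifier.
#' @param log Skipped-row report.
#' @return An [RTDB-class] object.
#' @export
RTDB <- function(entries, gradientSpan, methodId = "unspecified",
                 log = data.frame(row = integer(), reason = character())) {
    entries <- .completeEntries(entries)
    new("RTDB", entries = entries, gradientSpan = as.numeric(gradientSpan),
        methodId = methodId, log = log)
}

.completeEntries <- function(entries) {
    if (!nrow(entries)) {
        for (cl in .RTDB_COLS)
            if (is.null(entries[[cl]]))
                entries[[cl]] <- if (cl == "reference_rt_min") numeric()
                                 else character()
        return(entries[, .RTDB_COLS, drop = FALSE])
    }
    if (is.null(entries$evidence)) entries$evidence <- "SIL-experiment"
    if (is.null(entries$flags)) entries$flags <- ""
    keys <- .chainKeys(entries$lipid_class, entries$chains)
    entries$chains <- keys$chains
    entries$species_key_omega <- keys$omega
    entries$species_molecular <- keys$molecular
    entries[, .RTDB_COLS, drop = FALSE]
}

setMethod("show", "RTDB", function(object) {
    e <- object@entries
    cat(sprintf("RTDB (%s): %d entries, %d lipid class(es), span %.2f-%.2f min\n",
                object@methodId, nrow(e), length(unique(e$lipid_class)),
                object@gradientSpan[1L], object@gradientSpan[2L]))
    if (nrow(object@log))
        cat(" ", nrow(object@log), "input row(s) skipped while building\n")
})

#' @describeIn RTDB Entry table accessor.
#' @param db,object An `RTDB`.
#' @export
rtdbEntries <- function(db) db@entries

#' @describeIn RTDB Gradient span accessor (minutes).
#' @export
gradientSpan <- function(db) db@gradientSpan

#' @describeIn RTDB Lipid classes present.
#' @export
lipidClasses <- function(db) sort(unique(db@entries$lipid_class))

#' @describeIn RTDB Skipped-row report from [buildRTDB()].
#' @export
buildLog <- function(db) db@log

#' Retention-time calibration model
#'
#' Per-group piecewise-cubic mapping from a source chromatography to a
#' target one, fitted through binned anchor knots. Groups with fewer than
#' four knots fall back along class -> user group -> global. Outside the
#' knot range the mapping continues linearly with the boundary slope and the
#' result is flagged "extrapolated".
#'
#' @slot funs Named list of interpolants (one per fitted group).
#' @slot knots Named list of knot data.frames (`source`, `target`, `n`).
#' @slot types Named character: "cubic" or "linear" per fitted group.
#' @slot ranges Named list of valid source-RT ranges.
#' @slot groupOf Named character mapping class -> user-defined group.
#' @slot binWidth Bin width in minutes used for the knots.
#' @export
setClass("CalibrationModel",
         representation(funs = "list", knots = "list", types = "character",
                        ranges = "list", groupOf = "character",
                        binWidth = "numeric"))

setValidity("CalibrationModel", function(object) {
    if (!length(object@funs)) return("no fitted groups")
    if (!setequal(names(object@funs), names(object@knots)))
        return("funs and knots name mismatch")
    for (g in names(object@knots)) {
        k <- object@knots[[g]]
        if (any(diff(k$source) <= 0))
            return(sprintf("knots of group '%s' not strictly increasing", g))
        dev <- max(abs(object@funs[[g]](k$source) - k$target))
        if (dev > 1e-9)
            return(sprintf("interpolant of group '%s' misses its knots", g))
    }
    TRUE
})

setMethod("show", "CalibrationModel", function(object) {
    cat(sprintf("CalibrationModel: %d group(s), bin width %.2f min\n",
                length(object@funs), object@binWidth))
    for (g in names(object@funs))
        cat(sprintf("  %-12s %-6s %3d knots, source range %.2f-%.2f min\n",
                    g, object@types[[g]], nrow(object@knots[[g]]),
                    object@ranges[[g]][1L], object@ranges[[g]][2L]))
})

#' @describeIn CalibrationModel Knot tables per fitted group.
#' @param model A `CalibrationModel`.
#' @export
calibrationKnots <- function(model) model@knots

#' @describeIn CalibrationModel Valid source range of a fitted group.
#' @param group Group name.
#' @export
validRange <- function(model, group = "global") model@ranges[[group]]
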