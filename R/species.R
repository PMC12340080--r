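## Canonical species keys and exact-mass arithmetic.

.sortChains <- function(chains) {
    o <- order(chains$carbons, chains$double_bonds,
               ifelse(is.na(chains$omega), 999L, chains$omega),
               chains$linkage,
               ifelse(is.na(chains$label), "", chains$label))
    chains[o, , drop = FALSE]
}

#' Canonical key of a lipid species
#'
#' Deterministic string keys used to match species across tables:
#' \describe{
#'   \item{sum}{class plus summed carbons:double-bonds ("PI 38:3").}
#'   \item{molecular}{chains sorted by (carbons, double bonds, omega) and
#'     joined with "_"; chain order is ignored ("PC 16:0_20:4(n−6)").}
#'   \item{sn}{chains in sn order joined with "/"; errors unless the species
#'     is sn-resolved.}
#'   \item{omega}{the most resolved key: "/" in sn order when sn-resolved,
#'     else the sorted "_" form.}
#' }
#' Omega suffixes appear wherever the omega position is known; strip them
#' first (see [buildRTDB()] internals) to match at plain molecular level.
#'
#' @param species A [LipidSpecies-class].
#' @param level One of "sum", "molecular", "sn", "omega".
#' @return A single character key.
#' @export
#' @examples
#' sp <- LipidSpecies("PC", c("20:4(n−6)", "16:0"))
#' speciesKey(sp, "molecular")
#' speciesKey(sp, "sum")
setGeneric("speciesKey", function(species, level = "molecular")
    standardGeneric("speciesKey"))

#' @rdname speciesKey
#' @export
setMethod("speciesKey", "LipidSpecies", function(species,
                                                 level = "molecular") {
    level <- match.arg(level, c("sum", "molecular", "sn", "omega"))
    ch <- species@chains
    if (level == "sum")
        return(sprintf("%s %d:%d", species@lipidClass, sum(ch$carbons),
                       sum(ch$double_bonds)))
    if (level == "sn") {
        if (!species@snResolved)
            stop("sn-level key requested for a species that is not ",
                 "sn-resolved", call. = FALSE)
        return(paste(species@lipidClass,
                     paste(formatChain(ch), collapse = "/")))
    }
    if (level == "omega" && species@snResolved)
        return(paste(species@lipidClass,
                     paste(formatChain(ch), collapse = "/")))
    paste(species@lipidClass,
          paste(formatChain(.sortChains(ch)), collapse = "_"))
})

## vectorized keys for table processing; chains given as joined strings
.chainKeys <- function(lipidClass, chains) {
    sp <- .splitChains(chains)
    canon <- character(length(chains))
    omega <- character(length(chains))
    molecular <- character(length(chains))
    for (i in seq_along(chains)) {
        ch <- parseChain(sp$tokens[[i]])
        ch <- .stripLabels(ch)
        srt <- .sortChains(ch)
        canon[i] <- paste(formatChain(srt), collapse = "_")
        omega[i] <- paste(lipidClass[i], canon[i])
        molecular[i] <- paste(lipidClass[i],
                              paste(formatChain(.stripOmega(srt)),
                                    collapse = "_"))
    }
    list(chains = canon, omega = omega, molecular = molecular)
}

## omega-stripped molecular key for arbitrary (possibly labeled) chain fields
.molecularKey <- function(lipidClass, chains) {
    sp <- .splitChains(chains)
    vapply(seq_along(chains), function(i) {
        ch <- .stripOmega(parseChain(sp$tokens[[i]]))
        paste(lipidClass[i], paste(formatChain(.sortChains(ch)),
                                   collapse = "_"))
    }, character(1))
}

#' Monoisotopic mass of a lipid species as an adduct ion
#'
#' The neutral monoisotopic mass is the class base formula plus the
#' per-chain contributions; SIL labels add their exact heavy-isotope shifts.
#' The m/z is (neutral mass + adduct mass shift) / |charge|, the adduct
#' shift being electron-corrected.
#'
#' @param species A [LipidSpecies-class].
#' @param adduct Adduct name; defaults to the species' adduct slot or the
#'   class default.
#' @return m/z in Da.
#' @export
#' @examples
#' monoisotopicMass(LipidSpecies("PC", "18:0_22:5(n−3)"), "[M+H]+")
setGeneric("monoisotopicMass", function(species, adduct = NULL)
    standardGeneric("monoisotopicMass"))

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "LipidSpecies", function(species,
                                                       adduct = NULL) {
    if (is.null(adduct))
        adduct <- if (!is.na(species@adduct)) species@adduct
                  else .classDef(species@lipidClass)$default_adduct
    .speciesMz(species@lipidClass, species@chains, adduct)
})

.neutralMass <- function(lipidClass, chains) {
    def <- .classDef(lipidClass)
    em <- elementMasses()
    base <- .formulaMass(def$base_formula)
    h <- .chainHCount(chains)
    o <- ifelse(chains$linkage == "acyl", 1L, 0L)
    chainMass <- sum(chains$carbons * em[["C"]] + h * em[["H"]] +
                     o * em[["O"]])
    lab <- !is.na(chains$label)
    shift <- if (any(lab)) sum(labelMassShift(chains$label[lab])) else 0
    unname(base + chainMass + shift)
}

.speciesMz <- function(lipidClass, chains, adduct) {
    ad <- .adductDef(adduct)
    (.neutralMass(lipidClass, chains) + ad$mass_shift) / abs(ad$charge)
}

#' Match an observed m/z against a theoretical one
#'
#' @param mz Observed m/z value(s).
#' @param mzTheoretical Theoretical m/z value(s).
#' @param ppm Tolerance in parts per million (default 10, Orbitrap-class).
#' @return Logical vector.
#' @export
#' @examples
#' mzWithin(836.610, monoisotopicMass(LipidSpecies("PC", "18:0_22:5(n−3)")))
mzWithin <- function(mz, mzTheoretical, ppm = 10) {
    abs(mz - mzTheoretical) / mzTheoretical * 1e6 <= ppm
}
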