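## Registries for SIL labels, lipid classes and adducts, plus the small
## isotope-mass table that backs all exact-mass arithmetic.

.omegaRT <- new.env(parent = emptyenv())

#' Monoisotopic masses of the elements and heavy isotopes used here
#'
#' Values in Da (u), sufficient for glycerophospholipid chemistry: C, H, N,
#' O, P, S plus deuterium (`D`) and `13C`.
#'
#' @return Named numeric vector of monoisotopic masses.
#' @export
#' @examples
#' elementMasses()[["C"]]
elementMasses <- function() {
    c(C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
      P = 30.97376163, S = 31.97207100,
      D = 2.01410177812, `13C` = 13.00335483507)
}

#' Parse a molecular formula into element counts
#'
#' Minimal Hill-style formula parser ("C8H20NO6P" etc.); no parentheses or
#' isotope markers, which the class registry does not need.
#'
#' @param formula Character vector of formulas.
#' @return A named list of named integer vectors (element -> count).
#' @export
#' @examples
#' parseFormula("C5H11N")
parseFormula <- function(formula) {
    out <- lapply(formula, function(f) {
        if (is.na(f) || !nzchar(f))
            stop("empty formula", call. = FALSE)
        m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1]]
        toks <- regmatches(f, list(m))[[1]]
        if (sum(nchar(toks)) != nchar(f))
            stop("malformed formula: '", f, "'", call. = FALSE)
        el <- sub("[0-9]*$", "", toks)
        n <- as.integer(ifelse(grepl("[0-9]+$", toks),
                               sub("^[A-Za-z]+", "", toks), "1"))
        tapply(n, el, sum)[unique(el)]
    })
    names(out) <- formula
    out
}

.formulaMass <- function(formula) {
    em <- elementMasses()
    vapply(parseFormula(formula), function(cnt) {
        bad <- setdiff(names(cnt), names(em))
        if (length(bad))
            stop("unknown element(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
        sum(em[names(cnt)] * cnt)
    }, numeric(1))
}

.extdata <- function(file) {
    p <- system.file("extdata", file, package = "omegaRT")
    if (!nzchar(p)) p <- file.path("inst", "extdata", file)
    p
}

.readRegistry <- function(path) {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, fileEncoding = "UTF-8")
}

#' Registry of stable-isotope label encodings
#'
#' Single-capital-letter prefixes marking SIL fatty acyls in shorthand names.
#' The built-in registry holds the five encodings used to build the reference
#' database: A = n-9 with 17 deuteriums, B = n-6 (D11), C = n-3 (D5),
#' D = n-7 (13C16), E = n-10 (D19). The registry is an editable TSV with
#' columns `code`, `element` (`D` or `13C`), `atom_count`, `omega`.
#'
#' @param path Optional path to an alternative registry file.
#' @return data.frame with columns code, element, atom_count, omega.
#' @export
#' @examples
#' silLabelRegistry()
silLabelRegistry <- function(path = NULL) {
    if (is.null(path)) {
        if (is.null(.omegaRT$labels))
            .omegaRT$labels <- .validateLabelRegistry(
                .readRegistry(.extdata("sil_labels.tsv")))
        return(.omegaRT$labels)
    }
    .validateLabelRegistry(.readRegistry(path))
}

.validateLabelRegistry <- function(reg) {
    need <- c("code", "element", "atom_count", "omega")
    miss <- setdiff(need, names(reg))
    if (length(miss))
        stop("label registry lacks column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(reg$code))
        stop("label registry has duplicated prefix codes", call. = FALSE)
    if (!all(grepl("^[A-Z]$", reg$code)))
        stop("label prefix codes must be single capital letters", call. = FALSE)
    if (!all(reg$element %in% c("D", "13C")))
        stop("label element must be 'D' or '13C'", call. = FALSE)
    if (any(reg$atom_count < 1))
        stop("label atom_count must be >= 1", call. = FALSE)
    reg
}

#' Registry of supported lipid classes
#'
#' Maps each lipid (sub)class to its headgroup+backbone base formula, its
#' chain count (1 for lyso classes), the ether linkage expected for O-/P-
#' variants, and a default adduct. Species formulas are the base formula plus
#' per-chain contributions (acyl CcH(2c-2-2d)O, alkyl CcH(2c-2d),
#' alkenyl CcH(2c-2-2d)), so ether classes share the diacyl base formula.
#'
#' @param path Optional path to an alternative registry TSV.
#' @return data.frame with columns class, base_formula, chain_count,
#'   ether_linkage, default_adduct.
#' @export
lipidClassRegistry <- function(path = NULL) {
    if (is.null(path)) {
        if (is.null(.omegaRT$classes))
            .omegaRT$classes <- .validateClassRegistry(
                .readRegistry(.extdata("lipid_classes.tsv")))
        return(.omegaRT$classes)
    }
    .validateClassRegistry(.readRegistry(path))
}

.validateClassRegistry <- function(reg) {
    need <- c("class", "base_formula", "chain_count", "ether_linkage",
              "default_adduct")
    miss <- setdiff(need, names(reg))
    if (length(miss))
        stop("class registry lacks column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(reg$class))
        stop("class registry has duplicated classes", call. = FALSE)
    .formulaMass(reg$base_formula)   # validates formulas
    reg
}

#' Registry of adducts
#'
#' @param path Optional path to an alternative registry TSV with columns
#'   `adduct`, `mass_shift` (Da, electron-corrected), `charge`.
#' @return data.frame of adduct definitions.
#' @export
adductRegistry <- function(path = NULL) {
    if (is.null(path)) {
        if (is.null(.omegaRT$adducts))
            .omegaRT$adducts <- .validateAdductRegistry(
                .readRegistry(.extdata("adducts.tsv")))
        return(.omegaRT$adducts)
    }
    .validateAdductRegistry(.readRegistry(path))
}

.validateAdductRegistry <- function(reg) {
    need <- c("adduct", "mass_shift", "charge")
    miss <- setdiff(need, names(reg))
    if (length(miss))
        stop("adduct registry lacks column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (any(reg$charge == 0))
        stop("adduct charge must be non-zero", call. = FALSE)
    reg
}

.classDef <- function(lipidClass, registry = lipidClassRegistry()) {
    i <- match(lipidClass, registry$class)
    if (anyNA(i))
        stop("unregistered lipid class: ",
             paste(unique(lipidClass[is.na(i)]), collapse = ", "),
             call. = FALSE)
    registry[i, , drop = FALSE]
}

.adductDef <- function(adduct, registry = adductRegistry()) {
    i <- match(adduct, registry$adduct)
    if (anyNA(i))
        stop("unregistered adduct: ",
             paste(unique(adduct[is.na(i)]), collapse = ", "), call. = FALSE)
    registry[i, , drop = FALSE]
}
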