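## Fatty-acyl shorthand parsing and formatting.
##
## A chain token looks like "18:1(n-9)", "A18:1" (SIL prefix), "O-16:0"
## (alkyl ether) or "P-18:0" (alkenyl / vinyl ether). Both the Unicode minus
## and the ASCII hyphen are accepted inside "(n-x)"; the formatter emits the
## Unicode minus.

.UMINUS <- "\u2212"

.normMinus <- function(x) gsub(.UMINUS, "-", x)

#' Parse fatty-acyl shorthand tokens
#'
#' Vectorized parser for chain tokens at up to omega resolution, with
#' optional single-letter SIL prefix and O-/P- ether linkage prefix. A SIL
#' prefix implies the label's omega position on unsaturated chains (e.g.
#' "A18:1" is D17-labeled 18:1(n-9)); an explicit omega that contradicts the
#' label is an error.
#'
#' @param x Character vector of chain tokens.
#' @param registry SIL label registry, see [silLabelRegistry()].
#' @return A data.frame with one row per token: `carbons`, `double_bonds`,
#'   `omega` (NA when unknown), `linkage` (`acyl`/`alkyl`/`alkenyl`) and
#'   `label` (prefix code or NA).
#' @export
#' @examples
#' parseChain(c("18:1(n−9)", "A18:1", "O-16:0"))
parseChain <- function(x, registry = silLabelRegistry()) {
    if (length(x) == 0)
        return(data.frame(carbons = integer(), double_bonds = integer(),
                          omega = integer(), linkage = character(),
                          label = character(), stringsAsFactors = FALSE))
    if (any(is.na(x) | !nzchar(x)))
        stop("empty chain token", call. = FALSE)
    y <- .normMinus(x)
    pat <- "^(O-|P-)?([A-Z])?([0-9]+):([0-9]+)(\\(n-([0-9]+)\\))?$"
    ok <- grepl(pat, y, perl = TRUE)
    if (!all(ok)) {
        bad <- x[!ok][1L]
        ## distinguish an unknown prefix letter from a malformed token
        if (grepl("^(O-|P-)?[A-Za-z]", .normMinus(bad)) &&
            grepl("[0-9]+:[0-9]+", bad))
            stop("cannot parse chain token '", bad,
                 "': unknown prefix or malformed omega suffix", call. = FALSE)
        stop("malformed carbons:double_bonds token in '", bad, "'",
             call. = FALSE)
    }
    g <- regmatches(y, regexec(pat, y, perl = TRUE))
    linkraw <- vapply(g, `[`, character(1), 2L)
    label <- vapply(g, `[`, character(1), 3L)
    carbons <- as.integer(vapply(g, `[`, character(1), 4L))
    dbs <- as.integer(vapply(g, `[`, character(1), 5L))
    omtxt <- vapply(g, `[`, character(1), 7L)
    omega <- suppressWarnings(as.integer(omtxt))
    linkage <- c(`O-` = "alkyl", `P-` = "alkenyl")[linkraw]
    linkage[is.na(linkage)] <- "acyl"
    label[!nzchar(label)] <- NA_character_

    known <- !is.na(label)
    if (any(known)) {
        i <- match(label[known], registry$code)
        if (anyNA(i))
            stop("unknown SIL prefix letter '",
                 label[known][is.na(i)][1L], "' in token '",
                 x[known][is.na(i)][1L], "'", call. = FALSE)
        lab_om <- registry$omega[i]
        has_db <- dbs[known] >= 1L
        conflict <- has_db & !is.na(omega[known]) & omega[known] != lab_om
        if (any(conflict))
            stop("omega suffix contradicts SIL prefix in token '",
                 x[known][conflict][1L], "'", call. = FALSE)
        omega[known] <- ifelse(has_db, lab_om, NA_integer_)
    }
    chains <- data.frame(carbons = carbons, double_bonds = dbs,
                         omega = omega, linkage = unname(linkage),
                         label = label, stringsAsFactors = FALSE)
    .validateChains(chains, registry, token = x)
    chains
}

.validateChains <- function(chains, registry = silLabelRegistry(),
                            token = NULL) {
    tok <- if (is.null(token)) formatChain(chains, validate = FALSE) else token
    bad <- chains$double_bonds < 0L |
        chains$double_bonds > floor((chains$carbons - 1L) / 2)
    if (any(bad))
        stop("impossible double-bond count in '", tok[bad][1L], "'",
             call. = FALSE)
    known <- !is.na(chains$omega)
    bad <- known & (chains$omega > chains$carbons - 1L | chains$omega < 1L)
    if (any(bad))
        stop("omega position outside chain in '", tok[bad][1L], "'",
             call. = FALSE)
    bad <- known & chains$double_bonds < 1L
    if (any(bad))
        stop("omega position given for a saturated chain in '",
             tok[bad][1L], "'", call. = FALSE)
    lab <- !is.na(chains$label)
    if (any(lab)) {
        i <- match(chains$label[lab], registry$code)
        if (anyNA(i))
            stop("unknown SIL prefix letter in '", tok[lab][is.na(i)][1L],
                 "'", call. = FALSE)
        avail <- ifelse(registry$element[i] == "13C", chains$carbons[lab],
                        .chainHCount(chains[lab, , drop = FALSE]))
        over <- registry$atom_count[i] > avail
        if (any(over))
            stop("label heavy-atom count exceeds substitutable atoms in '",
                 tok[lab][over][1L], "'", call. = FALSE)
    }
    invisible(chains)
}

## hydrogens contributed by the chain within an intact lipid
.chainHCount <- function(chains) {
    h <- 2L * chains$carbons - 2L * chains$double_bonds
    h - ifelse(chains$linkage %in% c("acyl", "alkenyl"), 2L, 0L)
}

#' Format fatty-acyl chains back to shorthand
#'
#' Inverse of [parseChain()]. Labeled chains are written with the prefix
#' letter only (the label implies the omega position); unlabeled chains with
#' known omega get the "(n-x)" suffix with a Unicode minus.
#'
#' @param chains data.frame as returned by [parseChain()].
#' @param validate Check chain invariants before formatting.
#' @return Character vector of canonical tokens.
#' @export
formatChain <- function(chains, validate = TRUE) {
    if (validate && nrow(chains)) .validateChains(chains)
    pre <- c(acyl = "", alkyl = "O-", alkenyl = "P-")[chains$linkage]
    lab <- ifelse(is.na(chains$label), "", chains$label)
    om <- ifelse(is.na(chains$label) & !is.na(chains$omega),
                 paste0("(n", .UMINUS, chains$omega, ")"), "")
    paste0(pre, lab, chains$carbons, ":", chains$double_bonds, om)
}

#' Mass shift introduced by a SIL label
#'
#' Exact shift is atom_count x (heavy - light) isotope mass; nominal is the
#' exact shift rounded to the nearest integer (the 5/11/16/17/19 Da shifts of
#' the built-in labels).
#'
#' @param label Prefix code(s) from the registry, or a registry-like
#'   data.frame with columns `element` and `atom_count`.
#' @param mode `"exact"` or `"nominal"`.
#' @param registry SIL label registry.
#' @return Numeric vector of shifts in Da.
#' @export
#' @examples
#' labelMassShift(c("A", "B", "C", "D", "E"), mode = "nominal")
labelMassShift <- function(label, mode = c("exact", "nominal"),
                           registry = silLabelRegistry()) {
    mode <- match.arg(mode)
    if (is.character(label)) {
        i <- match(label, registry$code)
        if (anyNA(i))
            stop("unknown label code: ",
                 paste(label[is.na(i)], collapse = ", "), call. = FALSE)
        label <- registry[i, , drop = FALSE]
    }
    em <- elementMasses()
    per <- ifelse(label$element == "D", em[["D"]] - em[["H"]],
                  em[["13C"]] - em[["C"]])
    shift <- label$atom_count * per
    if (mode == "nominal") round(shift) else shift
}

## deuterium counts per chain (0 for unlabeled and 13C-labeled chains)
.chainDCount <- function(chains, registry = silLabelRegistry()) {
    n <- integer(nrow(chains))
    lab <- !is.na(chains$label)
    if (any(lab)) {
        i <- match(chains$label[lab], registry$code)
        n[lab] <- ifelse(registry$element[i] == "D",
                         registry$atom_count[i], 0L)
    }
    n
}

## split a joined chains field ("16:0_20:4(n-6)" or "18:0/20:3(n-9)")
.splitChains <- function(x) {
    x <- .normMinus(x)
    sn <- grepl("/", x, fixed = TRUE)
    toks <- strsplit(x, ifelse(sn, "/", "_"), fixed = FALSE)
    list(tokens = toks, sn_resolved = sn)
}

.stripLabels <- function(chains) { chains$label <- NA_character_; chains }

.stripOmega <- function(chains) {
    chains$omega <- NA_integer_
    .stripLabels(chains)
}
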