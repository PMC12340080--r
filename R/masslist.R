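## Combinatorial mass-list generation for native and SIL lipid species.

## multiset combinations (with repetition) of indices 1..n, size k
.multisetCombn <- function(n, k) {
    if (k == 0L) return(matrix(integer(), nrow = 0L, ncol = 1L))
    if (k == 1L) return(matrix(seq_len(n), nrow = 1L))
    prev <- .multisetCombn(n, k - 1L)
    cols <- list()
    for (j in seq_len(ncol(prev))) {
        top <- prev[k - 1L, j]
        for (i in top:n) cols[[length(cols) + 1L]] <- c(prev[, j], i)
    }
    do.call(cbind, cols)
}

#' Enumerate lipid molecular species from a fatty-acyl pool
#'
#' Generates every unordered multiset combination of pool chains that
#' satisfies the class chain count (1 for lyso classes, 2 otherwise) and
#' optional totals constraints. Homo-chain pairs are emitted once.
#'
#' @param lipidClass Registered lipid class.
#' @param chainPool Character vector of chain tokens (may carry omega and
#'   SIL prefixes).
#' @param constraints Optional list with any of `minCarbons`, `maxCarbons`,
#'   `minDoubleBonds`, `maxDoubleBonds` applied to chain totals.
#' @return data.frame with columns `lipid_class`, `chains` (sorted,
#'   "_"-joined), `species_key`, `total_carbons`, `total_double_bonds`,
#'   ordered by key. Contradictory constraints give a warning and an empty
#'   result.
#' @export
#' @examples
#' enumerateMolecularSpecies("PC", c("16:0", "18:1(n−9)", "20:4(n−6)"))
enumerateMolecularSpecies <- function(lipidClass, chainPool,
                                      constraints = list()) {
    if (!length(chainPool)) stop("empty chain pool", call. = FALSE)
    def <- .classDef(lipidClass)
    pool <- parseChain(chainPool)
    k <- def$chain_count
    bad <- c(!is.null(constraints$minCarbons) &&
                 !is.null(constraints$maxCarbons) &&
                 constraints$minCarbons > constraints$maxCarbons,
             !is.null(constraints$minDoubleBonds) &&
                 !is.null(constraints$maxDoubleBonds) &&
                 constraints$minDoubleBonds > constraints$maxDoubleBonds)
    if (any(bad)) {
        warning("contradictory constraints; returning no species")
        return(data.frame(lipid_class = character(), chains = character(),
                          species_key = character(),
                          total_carbons = integer(),
                          total_double_bonds = integer()))
    }
    combos <- .multisetCombn(nrow(pool), k)
    rows <- lapply(seq_len(ncol(combos)), function(j) {
        ch <- .sortChains(pool[combos[, j], , drop = FALSE])
        data.frame(lipid_class = lipidClass,
                   chains = paste(formatChain(ch), collapse = "_"),
                   total_carbons = sum(ch$carbons),
                   total_double_bonds = sum(ch$double_bonds),
                   stringsAsFactors = FALSE)
    })
    out <- unique(do.call(rbind, rows))
    keep <- rep(TRUE, nrow(out))
    if (!is.null(constraints$minCarbons))
        keep <- keep & out$total_carbons >= constraints$minCarbons
    if (!is.null(constraints$maxCarbons))
        keep <- keep & out$total_carbons <= constraints$maxCarbons
    if (!is.null(constraints$minDoubleBonds))
        keep <- keep & out$total_double_bonds >= constraints$minDoubleBonds
    if (!is.null(constraints$maxDoubleBonds))
        keep <- keep & out$total_double_bonds <= constraints$maxDoubleBonds
    out <- out[keep, , drop = FALSE]
    out$species_key <- paste(out$lipid_class, out$chains)
    out <- out[order(out$species_key), , drop = FALSE]
    rownames(out) <- NULL
    out[, c("lipid_class", "chains", "species_key", "total_carbons",
            "total_double_bonds")]
}

#' Expand species with stable-isotope label combinations
#'
#' For every species, enumerates all distinct assignments of 0 to
#' `maxLabeledChains` labels onto eligible chains. A label is eligible for a
#' chain only when the chain's omega position matches the label's implied
#' omega (which requires an unsaturated chain); mixed-label and doubly
#' labeled variants are generated, the native (0-label) rows are retained,
#' and duplicates arising from homo-chain pairs appear once.
#'
#' @param species data.frame from [enumerateMolecularSpecies()] (columns
#'   `lipid_class`, `chains`).
#' @param labels Character vector of label prefix codes.
#' @param maxLabeledChains Maximum number of labeled chains per species.
#' @param registry SIL label registry.
#' @return data.frame like `species` with additional columns `label_codes`
#'   (""-separated concatenation, "" for native) and `n_heavy_atoms`.
#' @export
applySilLabels <- function(species, labels, maxLabeledChains = 2L,
                           registry = silLabelRegistry()) {
    i <- match(labels, registry$code)
    if (anyNA(i))
        stop("unknown label code: ", paste(labels[is.na(i)], collapse = ", "),
             call. = FALSE)
    labdef <- registry[i, , drop = FALSE]
    out <- list()
    for (s in seq_len(nrow(species))) {
        ch <- parseChain(.splitChains(species$chains[s])$tokens[[1L]])
        variants <- .labelAssignments(ch, labdef, maxLabeledChains)
        for (v in variants) {
            codes <- sort(v$label[!is.na(v$label)])
            nh <- if (length(codes))
                sum(labdef$atom_count[match(codes, labdef$code)]) else 0L
            out[[length(out) + 1L]] <- data.frame(
                lipid_class = species$lipid_class[s],
                chains = paste(formatChain(.sortChains(v)), collapse = "_"),
                label_codes = paste(codes, collapse = ""),
                n_heavy_atoms = nh, stringsAsFactors = FALSE)
        }
    }
    res <- unique(do.call(rbind, out))
    res$species_key <- paste(res$lipid_class, res$chains)
    res <- res[order(res$species_key), , drop = FALSE]
    rownames(res) <- NULL
    res
}

.labelAssignments <- function(ch, labdef, maxLabeled) {
    eligible <- lapply(seq_len(nrow(ch)), function(i) {
        if (ch$double_bonds[i] < 1L || is.na(ch$omega[i]))
            return(character())
        labdef$code[labdef$omega == ch$omega[i]]
    })
    variants <- list(ch)   # native
    idx <- which(lengths(eligible) > 0L)
    if (!length(idx) || maxLabeled < 1L) return(variants)
    for (k in seq_len(min(maxLabeled, length(idx)))) {
        subsets <- utils::combn(idx, k, simplify = FALSE)
        for (sset in subsets) {
            grids <- expand.grid(eligible[sset], stringsAsFactors = FALSE)
            for (g in seq_len(nrow(grids))) {
                v <- ch
                v$label[sset] <- unlist(grids[g, ])
                ok <- tryCatch({ .validateChains(v); TRUE },
                               error = function(e) FALSE)
                if (ok) variants[[length(variants) + 1L]] <- v
            }
        }
    }
    variants
}

#' Build a mass list from species rows
#'
#' Attaches theoretical m/z values for the requested adducts, one row per
#' (species, adduct).
#'
#' @param species data.frame with `lipid_class`, `chains` (optionally
#'   `label_codes`, `n_heavy_atoms` from [applySilLabels()]).
#' @param adducts Character vector of adduct names; defaults to each class'
#'   default adduct.
#' @return Mass-list data.frame with columns `species_key`, `lipid_class`,
#'   `chains`, `adduct`, `mz_theoretical`, `label_codes`, `n_heavy_atoms`.
#' @export
buildMassList <- function(species, adducts = NULL) {
    rows <- list()
    for (s in seq_len(nrow(species))) {
        ch <- parseChain(.splitChains(species$chains[s])$tokens[[1L]])
        ads <- if (is.null(adducts))
            .classDef(species$lipid_class[s])$default_adduct else adducts
        for (a in ads) {
            rows[[length(rows) + 1L]] <- data.frame(
                species_key = paste(species$lipid_class[s],
                                    species$chains[s]),
                lipid_class = species$lipid_class[s],
                chains = species$chains[s],
                adduct = a,
                mz_theoretical = .speciesMz(species$lipid_class[s], ch, a),
                label_codes = if (!is.null(species$label_codes))
                    species$label_codes[s] else "",
                n_heavy_atoms = if (!is.null(species$n_heavy_atoms))
                    species$n_heavy_atoms[s] else 0L,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (anyDuplicated(out[, c("species_key", "adduct")]))
        stop("duplicate (species_key, adduct) rows in mass list",
             call. = FALSE)
    rownames(out) <- NULL
    out
}
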