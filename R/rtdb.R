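## Building omega-resolved RT databases from SIL-experiment identifications.

.EVIDENCE_RANK <- c(standard = 1L, orthogonal = 2L, `SIL-experiment` = 3L)

#' Group omega-combination identifications of the same molecular species
#'
#' Identifications that share a molecular species (omega positions ignored)
#' and whose isotope-effect-corrected retention times fall within a grouping
#' tolerance (default 5 s) are merged into a single database entry: the
#' reference RT is the median (or mean) of the members, omega assignments
#' are combined union-consistently across members (this is how omega
#' combinations observed in separate single-label experiments are inferred),
#' and source batches are pooled. Clusters are formed by single-linkage on
#' RT. Members that disagree on the omega of the same chain yield an entry
#' flagged "conflict", which is excluded from automated use downstream.
#'
#' @param entries data.frame with columns `lipid_class`, `chains` (native
#'   tokens, omega possibly known on a subset of chains), `rt_min`
#'   (corrected RT), `batch`, optionally `evidence`.
#' @param toleranceS Grouping tolerance in seconds (default 5).
#' @param representative "median" (default, robust) or "mean".
#' @return data.frame of aggregated entries with RTDB columns.
#' @export
groupOmegaCombinations <- function(entries, toleranceS = 5,
                                   representative = c("median", "mean")) {
    representative <- match.arg(representative)
    need <- c("lipid_class", "chains", "rt_min", "batch")
    miss <- setdiff(need, names(entries))
    if (length(miss))
        stop("entries lack column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (is.null(entries$evidence)) entries$evidence <- "SIL-experiment"
    if (!nrow(entries))
        return(.completeEntries(data.frame()))
    molKey <- .molecularKey(entries$lipid_class, entries$chains)
    out <- list()
    for (key in sort(unique(molKey))) {
        sub <- entries[molKey == key, , drop = FALSE]
        sub <- sub[order(sub$rt_min, sub$chains, sub$batch), , drop = FALSE]
        cl <- cumsum(c(1, diff(sub$rt_min) > toleranceS / 60))
        for (ci in unique(cl)) {
            mem <- sub[cl == ci, , drop = FALSE]
            merged <- .mergeOmega(mem$chains)
            rt <- if (representative == "median") stats::median(mem$rt_min)
                  else mean(mem$rt_min)
            ev <- mem$evidence[which.min(.EVIDENCE_RANK[mem$evidence])]
            batches <- sort(unique(unlist(strsplit(as.character(mem$batch),
                                                   ";", fixed = TRUE))))
            out[[length(out) + 1L]] <- data.frame(
                lipid_class = mem$lipid_class[1L],
                chains = merged$chains,
                reference_rt_min = rt,
                batches = paste(batches, collapse = ";"),
                evidence = ev,
                flags = merged$flag,
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    res <- .completeEntries(res)
    res[order(res$species_key_omega, res$reference_rt_min), , drop = FALSE]
}

## union-consistent merge of omega assignments across cluster members;
## members share the molecular key, so sorted (carbons, db, linkage)
## signatures coincide position by position
.mergeOmega <- function(chainStrings) {
    parsed <- lapply(chainStrings, function(s) {
        ch <- .stripLabels(parseChain(.splitChains(s)$tokens[[1L]]))
        ch[order(ch$carbons, ch$double_bonds, ch$linkage,
                 ifelse(is.na(ch$omega), 999L, ch$omega)), , drop = FALSE]
    })
    base <- parsed[[1L]]
    flag <- ""
    for (pos in seq_len(nrow(base))) {
        oms <- unique(stats::na.omit(vapply(parsed, function(p)
            p$omega[pos], integer(1))))
        if (length(oms) > 1L) {
            flag <- "conflict"
            base$omega[pos] <- NA_integer_
        } else if (length(oms) == 1L) {
            base$omega[pos] <- oms
        }
    }
    list(chains = paste(formatChain(.sortChains(base)), collapse = "_"),
         flag = flag)
}

#' Build an omega-resolved RT database from SIL identifications
#'
#' Pipeline: correct the deuterium isotope effect on each labeled
#' identification, strip the labels to native species keys (the omega
#' positions the labels imply are retained), then group omega combinations
#' per molecular species across experiments and batches. Rows whose chain
#' tokens fail to parse are skipped and reported in the build log.
#'
#' @param ids Identification table with columns `batch`, `lipid_class` (or
#'   `class`), `chains`, `rt_min`; optional `evidence`.
#' @param model An [IsotopeEffectModel-class] for the measurement series.
#' @param gradientSpan Gradient span in minutes (length 2).
#' @param groupToleranceS Grouping tolerance in seconds (default 5).
#' @param methodId Chromatographic method identifier.
#' @return An [RTDB-class]; skipped rows via [buildLog()].
#' @export
buildRTDB <- function(ids, model, gradientSpan, groupToleranceS = 5,
                      methodId = "unspecified") {
    if (is.null(ids$lipid_class) && !is.null(ids$class))
        ids$lipid_class <- ids$class
    need <- c("batch", "lipid_class", "chains", "rt_min")
    miss <- setdiff(need, names(ids))
    if (length(miss))
        stop("identification table lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (is.null(ids$evidence)) ids$evidence <- "SIL-experiment"
    keep <- logical(nrow(ids))
    reason <- character(nrow(ids))
    corrected <- numeric(nrow(ids))
    native <- character(nrow(ids))
    for (i in seq_len(nrow(ids))) {
        res <- tryCatch({
            tk <- .splitChains(ids$chains[i])$tokens[[1L]]
            ch <- parseChain(tk)
            rt <- correctLabeledRT(ids$rt_min[i], list(.chainDCount(ch)),
                                   model)
            list(rt = rt,
                 chains = paste(formatChain(.sortChains(.stripLabels(ch))),
                                collapse = "_"))
        }, error = function(e) conditionMessage(e))
        if (is.character(res)) {
            reason[i] <- res
        } else {
            keep[i] <- TRUE
            corrected[i] <- res$rt
            native[i] <- res$chains
        }
    }
    log <- data.frame(row = which(!keep), reason = reason[!keep],
                      stringsAsFactors = FALSE)
    ok <- data.frame(lipid_class = ids$lipid_class[keep],
                     chains = native[keep], rt_min = corrected[keep],
                     batch = ids$batch[keep], evidence = ids$evidence[keep],
                     stringsAsFactors = FALSE)
    entries <- groupOmegaCombinations(ok, toleranceS = groupToleranceS)
    RTDB(entries, gradientSpan = gradientSpan, methodId = methodId,
         log = log)
}

#' Merge measurement-batch RT databases into one aggregate database
#'
#' Entries of every non-reference database are mapped onto the reference
#' elution profile with the supplied calibration models, then grouped per
#' molecular species with the usual tolerance. Every aggregate entry lists
#' all contributing batches; entries whose omega-level key appears in
#' `excludeKeys` (manual outlier curation) are dropped first.
#'
#' @param dbs List of [RTDB-class] objects; the first (or `reference`) is
#'   the reference gradient.
#' @param calibrations List parallel to `dbs`: a [CalibrationModel-class]
#'   mapping that DB onto the reference, or the string "identity". The
#'   reference entry is ignored; a missing calibration for a non-reference
#'   DB is an error.
#' @param reference Index of the reference DB (default 1).
#' @param toleranceS Grouping tolerance in seconds.
#' @param excludeKeys Character vector of `species_key_omega` values to
#'   exclude as curated outliers.
#' @return The aggregate [RTDB-class] on the reference gradient.
#' @export
mergeRTDBs <- function(dbs, calibrations = NULL, reference = 1L,
                       toleranceS = 5, excludeKeys = character()) {
    stopifnot(length(dbs) >= 1L)
    if (is.null(calibrations)) calibrations <- vector("list", length(dbs))
    rows <- list()
    for (i in seq_along(dbs)) {
        e <- rtdbEntries(dbs[[i]])
        if (!nrow(e)) next
        if (i != reference) {
            cal <- calibrations[[i]]
            if (is.null(cal))
                stop("missing calibration for non-reference DB ", i,
                     call. = FALSE)
            if (!identical(cal, "identity")) {
                m <- mapRT(cal, e$reference_rt_min, group = e$lipid_class)
                e$reference_rt_min <- m$rt_target
            }
        }
        rows[[length(rows) + 1L]] <-
            data.frame(lipid_class = e$lipid_class, chains = e$chains,
                       rt_min = e$reference_rt_min, batch = e$batches,
                       evidence = e$evidence,
                       key = e$species_key_omega, stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, rows)
    if (!is.null(all) && length(excludeKeys))
        all <- all[!(all$key %in% excludeKeys), , drop = FALSE]
    if (is.null(all)) all <- data.frame(lipid_class = character(),
                                        chains = character(),
                                        rt_min = numeric(),
                                        batch = character())
    entries <- groupOmegaCombinations(all, toleranceS = toleranceS)
    span <- gradientSpan(dbs[[reference]])
    if (nrow(entries))
        span <- c(min(span[1L], min(entries$reference_rt_min)),
                  max(span[2L], max(entries$reference_rt_min)))
    RTDB(entries, gradientSpan = span,
         methodId = dbs[[reference]]@methodId)
}
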