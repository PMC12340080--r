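## Reading and writing mass lists and RT databases.
##
## Two writable dialects keyed on file extension: tab-separated (.tsv/.txt)
## and comma-separated (.csv, the spreadsheet-compatible dialect). Files
## with an .xlsx extension can be read when the readxl package is
## available. All text IO is UTF-8 so omega suffixes with the Unicode minus
## round-trip losslessly.

.sepFor <- function(path) {
    ext <- tolower(tools::file_ext(path))
    switch(ext, tsv = "\t", txt = "\t", csv = ",",
           stop("unsupported file extension '.", ext,
                "'; use .tsv, .txt or .csv", call. = FALSE))
}

.writeTable <- function(x, path, headerLines = character()) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (length(headerLines)) writeLines(paste0("#! ", headerLines), con)
    utils::write.table(x, con, sep = .sepFor(path), row.names = FALSE,
                       quote = TRUE, qmethod = "double")
}

.readTable <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "xlsx") {
        if (!requireNamespace("readxl", quietly = TRUE))
            stop("reading .xlsx requires the readxl package", call. = FALSE)
        df <- as.data.frame(readxl::read_excel(path))
        return(list(table = df, header = character()))
    }
    lines <- readLines(path, encoding = "UTF-8")
    hdr <- grep("^#! ", lines, value = TRUE)
    body <- lines[!grepl("^#! ", lines)]
    df <- utils::read.table(text = body, sep = .sepFor(path), header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "\"", comment.char = "")
    list(table = df, header = sub("^#! ", "", hdr))
}

.requireCols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(what, " is missing mandatory column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    invisible(df)
}

.MASSLIST_COLS <- c("species_key", "lipid_class", "chains", "adduct",
                    "mz_theoretical", "label_codes", "n_heavy_atoms")

#' Write / read a mass list
#'
#' Lossless round trip of all mass-list columns through the delimited text
#' dialects; an empty list writes a valid header-only file.
#'
#' @param masslist Mass-list data.frame from [buildMassList()].
#' @param path Output (input) path ending in .tsv, .txt or .csv; `.xlsx` is
#'   additionally supported on read via readxl.
#' @return `writeMassList` returns `path` invisibly; `readMassList` returns
#'   the mass-list data.frame (schema-checked, missing mandatory columns
#'   are reported by name).
#' @export
writeMassList <- function(masslist, path) {
    .requireCols(masslist, .MASSLIST_COLS, "mass list")
    .writeTable(masslist[, .MASSLIST_COLS, drop = FALSE], path,
                "omegaRT mass list v1")
    invisible(path)
}

#' @rdname writeMassList
#' @export
readMassList <- function(path) {
    df <- .readTable(path)$table
    .requireCols(df, .MASSLIST_COLS, "mass list")
    df$label_codes[is.na(df$label_codes)] <- ""
    df
}

.RTDB_IO_COLS <- c("lipid_class", "species_key_omega", "chains",
                   "reference_rt_min", "batches", "evidence", "flags")

#' Write / read an RT database
#'
#' The text formats carry the gradient span and method identifier in
#' "#!"-prefixed header lines above the column header, so a write/read
#' round trip reproduces the database exactly. The written table doubles as
#' an omega-annotated mass list for the annotation step.
#'
#' @param db An [RTDB-class].
#' @param path Path ending in .tsv, .txt or .csv (read also accepts .xlsx).
#' @param gradientSpan,methodId Overrides used when reading files (e.g.
#'   .xlsx) that carry no header metadata; the span defaults to the data
#'   range padded by 0.5 min.
#' @return `writeRTDB` returns `path` invisibly; `readRTDB` an
#'   [RTDB-class].
#' @export
writeRTDB <- function(db, path) {
    e <- rtdbEntries(db)
    hdr <- c("omegaRT rtdb v1",
             paste0("method_id=", db@methodId),
             paste0("gradient_span_min=", db@gradientSpan[1L], ",",
                    db@gradientSpan[2L]))
    .writeTable(e[, .RTDB_IO_COLS, drop = FALSE], path, hdr)
    invisible(path)
}

#' @rdname writeRTDB
#' @export
readRTDB <- function(path, gradientSpan = NULL, methodId = NULL) {
    r <- .readTable(path)
    df <- .requireCols(r$table, setdiff(.RTDB_IO_COLS, "species_key_omega"),
                       "RT-DB")
    kv <- r$header[grepl("=", r$header, fixed = TRUE)]
    meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    if (is.null(methodId))
        methodId <- if ("method_id" %in% names(meta)) meta[["method_id"]]
                    else "unspecified"
    if (is.null(gradientSpan)) {
        if ("gradient_span_min" %in% names(meta)) {
            gradientSpan <- as.numeric(strsplit(meta[["gradient_span_min"]],
                                                ",")[[1L]])
        } else if (nrow(df)) {
            gradientSpan <- range(df$reference_rt_min) + c(-0.5, 0.5)
        } else {
            gradientSpan <- c(0, 1)
        }
    }
    df$flags[is.na(df$flags)] <- ""
    RTDB(df, gradientSpan = gradientSpan, methodId = methodId)
}
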