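# Readers and writers for external formats.

#' Read centroided MS1 spectra from an mzML file
#'
#' Loads all MS-level-1 spectra into the package's MS1 map layout, sorted by
#' retention time. Profile-mode spectra are rejected with guidance to
#' centroid first; files without MS1 scans yield an empty map with a
#' warning.
#'
#' @param path Path to an mzML file.
#' @return MS1 map tibble (`scan`, `rt`, `mz`, `intensity`); `rt` in minutes.
#' @export
read_ms1 <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Reading mzML requires the 'mzR' package.")
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) abort(paste0("Cannot parse '", path, "': ",
                                                      conditionMessage(e))))
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  ms1 <- hdr[hdr$msLevel == 1, , drop = FALSE]
  if (nrow(ms1) == 0) {
    warn("No MS1 spectra in file; returning an empty map.")
    return(tibble(scan = integer(), rt = numeric(), mz = numeric(), intensity = numeric()))
  }
  if (any(!is.na(ms1$centroided) & !ms1$centroided)) {
    abort("Profile-mode MS1 spectra found; centroid the data before reading.")
  }
  ms1 <- ms1[order(ms1$retentionTime), , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(ms1)), function(i) {
    pk <- mzR::peaks(handle, ms1$seqNum[i])
    if (nrow(pk) == 0) return(NULL)
    tibble(scan = i, rt = ms1$retentionTime[i] / 60,
           mz = pk[, 1], intensity = pk[, 2])
  })
  .check_ms1_map(out)
  out
}

#' Read / write an MS1 map as TSV
#'
#' The package's own plain-text spectrum format: one centroid per row with
#' columns `scan`, `rt`, `mz`, `intensity`. Round-trips exactly.
#'
#' @param ms1 MS1 map tibble.
#' @param path File path.
#' @return `read_ms1_tsv()` returns the map; `write_ms1_tsv()` returns
#'   `path` invisibly.
#' @export
write_ms1_tsv <- function(ms1, path) {
  .check_ms1_map(ms1)
  write_table_tsv(ms1, path)
}

#' @rdname write_ms1_tsv
#' @export
read_ms1_tsv <- function(path) {
  out <- as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  out$scan <- as.integer(out$scan)
  .check_ms1_map(out)
  out
}

#' Write a result table as TSV
#'
#' Deterministic plain-text serialisation: tab-separated with a header, full
#' double precision (17 significant digits), no quoting or row names.
#' Re-reading reproduces the in-memory values.
#'
#' @param table A data frame; list-columns are dropped with a notice.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  is_list <- vapply(table, is.list, logical(1))
  if (any(is_list)) {
    inform(paste0("Dropping list column(s) for TSV output: ",
                  paste(names(table)[is_list], collapse = ", ")))
    table <- table[!is_list]
  }
  table <- as.data.frame(table)
  for (col in names(table)) {
    if (is.double(table[[col]])) table[[col]] <- sprintf("%.17g", table[[col]])
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
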