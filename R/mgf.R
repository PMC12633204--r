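#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses BEGIN IONS/END IONS blocks as exported by MZmine/GNPS: precursor
#' m/z from the first number of `PEPMASS`, retention time from `RTINSECONDS`
#' (seconds), spectrum id from `TITLE` (falling back to `SCANS`, then block
#' index), and the feature-table link from `FEATURE_ID` (falling back to
#' `SCANS`). Peaks are re-sorted by ascending fragment m/z regardless of
#' file order; a missing retention time is kept as `NA`, not 0.
#'
#' @param path path to an MGF file.
#' @return list of [ms_spectrum] objects, one per block.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends <= begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    named <- stats::setNames(vals, keys)
    if (!"PEPMASS" %in% keys)
      stop(sprintf("MGF block %d: missing PEPMASS", b))
    pep <- suppressWarnings(
      as.numeric(strsplit(trimws(named[["PEPMASS"]]), "[ \t]+")[[1L]][1L]))
    if (is.na(pep))
      stop(sprintf("MGF block %d: non-numeric PEPMASS '%s'", b, named[["PEPMASS"]]))
    rt <- if ("RTINSECONDS" %in% keys) {
      v <- suppressWarnings(as.numeric(named[["RTINSECONDS"]]))
      if (is.na(v)) stop(sprintf("MGF block %d: non-numeric RTINSECONDS", b))
      v
    } else NA_real_
    id <- if ("TITLE" %in% keys) named[["TITLE"]]
          else if ("SCANS" %in% keys) named[["SCANS"]]
          else as.character(b)
    fid <- if ("FEATURE_ID" %in% keys) named[["FEATURE_ID"]]
           else if ("SCANS" %in% keys) named[["SCANS"]]
           else NA_character_
    pk <- block[!is_kv]
    if (!length(pk)) stop(sprintf("MGF block %d: no peak lines", b))
    parts <- strsplit(pk, "[ \t]+")
    if (any(lengths(parts) < 2L))
      stop(sprintf("MGF block %d: peak line with fewer than two fields", b))
    mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    it <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (anyNA(mz) || anyNA(it))
      stop(sprintf("MGF block %d: non-numeric peak line", b))
    out[[b]] <- ms_spectrum(id, pep, cbind(mz, it), retention_time = rt,
                            source_file = path, feature_id = fid)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Output is readable by [read_mgf]; round-trips preserve precursor and
#' fragment m/z within 1e-6 Da and intensities within a relative 1e-6.
#'
#' @param spectra list of [ms_spectrum] objects (each with >= 1 peak).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (!is.list(spectra)) stop("spectra must be a list of ms_spectrum objects")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    if (!inherits(s, "ms_spectrum")) stop("all elements must be ms_spectrum objects")
    if (nrow(s$peaks) < 1L)
      stop("refusing to write spectrum '", s$spectrum_id, "' with empty peak list")
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$retention_time))
      writeLines(sprintf("RTINSECONDS=%.6f", s$retention_time), con)
    if (!is.na(s$feature_id))
      writeLines(paste0("FEATURE_ID=", s$feature_id), con)
    writeLines(sprintf("%.6f %.10g", s$peaks[, 1L], s$peaks[, 2L]), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
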