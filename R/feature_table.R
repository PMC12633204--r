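#' Construct a feature table
#'
#' MS1 peak areas of aligned ion features (rows) across samples (columns).
#'
#' @param features data.frame with columns `feature_id`, `mz` (Da) and `rt`
#'   (seconds; `NA` allowed).
#' @param intensities numeric matrix, features x samples, non-negative.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   column names of `intensities`.
#' @return Object of class `feature_table` with elements `features`,
#'   `sample_ids` and `intensities` (dimnames set to feature and sample ids).
#' @export
feature_table <- function(features, intensities, sample_ids = colnames(intensities)) {
  if (!is.data.frame(features) || !all(c("feature_id", "mz", "rt") %in% names(features)))
    stop("features must be a data.frame with columns feature_id, mz, rt")
  features$feature_id <- as.character(features$feature_id)
  intensities <- as.matrix(intensities)
  if (is.null(sample_ids)) stop("sample_ids required (or name the matrix columns)")
  sample_ids <- as.character(sample_ids)
  if (nrow(intensities) != nrow(features) || ncol(intensities) != length(sample_ids))
    stop("intensity matrix must be n_features x n_samples")
  if (anyDuplicated(features$feature_id)) stop("duplicate feature_id")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_id")
  if (anyNA(intensities)) stop("intensities must not contain NA (impute on read)")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  dimnames(intensities) <- list(features$feature_id, sample_ids)
  structure(list(features = features, sample_ids = sample_ids,
                 intensities = intensities),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  invisible(x)
}

# per-sample total-ion-current normalization; all-zero samples stay zero
tic_normalize_matrix <- function(M, warn = TRUE) {
  tot <- colSums(M)
  zero <- tot == 0
  if (any(zero) && warn)
    warning(sum(zero), " sample(s) with zero total intensity left as zeros")
  tot[zero] <- 1
  sweep(M, 2L, tot, "/")
}

#' Read a feature table from CSV/TSV
#'
#' Two dialects are supported. `"wide-mzmine"` expects the MZmine export
#' layout: columns `row ID`, `row m/z`, `row retention time`, then one
#' peak-area column per sample (a trailing " Peak area" suffix is stripped
#' from sample names). `"long"` expects `feature_id`, `sample_id`,
#' `intensity` triples with optional `mz` and `rt` columns; absent triples
#' are zeros. The delimiter is auto-detected among comma/tab. Empty cells
#' are imputed to 0 with a warning reporting the count; negative intensities
#' are rejected.
#'
#' @param path input file.
#' @param dialect `"wide-mzmine"` or `"long"`.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, dialect = c("wide-mzmine", "long")) {
  dialect <- match.arg(dialect)
  df <- read_delim_auto(path)
  if (dialect == "wide-mzmine") {
    req <- c("row ID", "row m/z", "row retention time")
    if (!all(req %in% names(df)))
      stop("wide-mzmine dialect requires columns: ", paste(req, collapse = ", "))
    sample_cols <- setdiff(names(df), req)
    if (!length(sample_cols)) stop("no sample columns found")
    M <- as.matrix(df[, sample_cols, drop = FALSE])
    storage.mode(M) <- "double"
    n_missing <- sum(is.na(M))
    if (n_missing > 0) {
      warning(n_missing, " missing cell(s) imputed to 0")
      M[is.na(M)] <- 0
    }
    if (any(M < 0)) stop("negative intensities are not allowed")
    feats <- data.frame(feature_id = as.character(df[["row ID"]]),
                        mz = as.numeric(df[["row m/z"]]),
                        rt = as.numeric(df[["row retention time"]]),
                        stringsAsFactors = FALSE)
    if (anyDuplicated(feats$feature_id)) stop("duplicate feature_id in ", path)
    feature_table(feats, M, sub(" Peak area$", "", sample_cols))
  } else {
    req <- c("feature_id", "sample_id", "intensity")
    if (!all(req %in% names(df)))
      stop("long dialect requires columns: ", paste(req, collapse = ", "))
    df$feature_id <- as.character(df$feature_id)
    df$sample_id <- as.character(df$sample_id)
    if (anyDuplicated(df[c("feature_id", "sample_id")]))
      stop("duplicate (feature_id, sample_id) pair in ", path)
    n_missing <- sum(is.na(df$intensity))
    if (n_missing > 0) {
      warning(n_missing, " missing cell(s) imputed to 0")
      df$intensity[is.na(df$intensity)] <- 0
    }
    if (any(df$intensity < 0)) stop("negative intensities are not allowed")
    fids <- unique(df$feature_id)
    sids <- unique(df$sample_id)
    M <- matrix(0, length(fids), length(sids), dimnames = list(fids, sids))
    M[cbind(match(df$feature_id, fids), match(df$sample_id, sids))] <- df$intensity
    mz <- rep(NA_real_, length(fids))
    rt <- rep(NA_real_, length(fids))
    if ("mz" %in% names(df)) mz <- df$mz[match(fids, df$feature_id)]
    if ("rt" %in% names(df)) rt <- df$rt[match(fids, df$feature_id)]
    feature_table(data.frame(feature_id = fids, mz = mz, rt = rt,
                             stringsAsFactors = FALSE), M, sids)
  }
}

#' Write a feature table to CSV
#'
#' @param table a [feature_table].
#' @param path output file.
#' @param dialect see [read_feature_table].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, dialect = c("wide-mzmine", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "feature_table"))
  if (dialect == "wide-mzmine") {
    out <- data.frame(table$features$feature_id, table$features$mz,
                      table$features$rt, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(out) <- c("row ID", "row m/z", "row retention time")
    out <- cbind(out, as.data.frame(table$intensities, check.names = FALSE))
  } else {
    idx <- expand.grid(f = seq_len(nrow(table$intensities)),
                       s = seq_len(ncol(table$intensities)))
    out <- data.frame(feature_id = table$features$feature_id[idx$f],
                      sample_id = table$sample_ids[idx$s],
                      intensity = table$intensities[cbind(idx$f, idx$s)],
                      mz = table$features$mz[idx$f],
                      rt = table$features$rt[idx$f],
                      stringsAsFactors = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited table whose first column is the sample id (its name is
#' normalized to `sample_id`). Columns whose non-missing values are all
#' numeric are typed numeric; anything mixed stays categorical (character).
#'
#' @param path input CSV/TSV.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 1L) stop("metadata table has no columns")
  names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  for (j in setdiff(names(df), "sample_id")) {
    v <- df[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      ok <- is.na(v) | v == "" | !is.na(num)
      if (all(ok) && any(!is.na(num))) df[[j]] <- num
    }
  }
  df
}
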