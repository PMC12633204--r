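#' Link spectral matches to query feature-table rows
#'
#' Each matched query spectrum must be tied to one MS1 feature so its peak
#' areas can be extracted per sample. An explicit `feature_id` on the
#' spectrum takes priority; otherwise the nearest feature within both the
#' m/z and retention-time tolerances is used (nearest by m/z, ties by RT).
#' Spectra without a retention time are linked by m/z alone. Matches that
#' cannot be linked are dropped; the dropped count is attached as attribute
#' `"n_dropped"` and reported via a message.
#'
#' @param matches data.frame from [search_library].
#' @param query_table the query [feature_table].
#' @param query_spectra list of query [ms_spectrum].
#' @param mz_tol m/z tolerance in Da.
#' @param rt_tol retention-time tolerance in seconds.
#' @return named character vector: query_spectrum_id -> feature_id.
#' @export
link_matches_to_features <- function(matches, query_table, query_spectra,
                                     mz_tol = 0.01, rt_tol = 30) {
  stopifnot(inherits(query_table, "feature_table"))
  spec_by_id <- stats::setNames(query_spectra,
                                vapply(query_spectra, function(s) s$spectrum_id, ""))
  qids <- unique(matches$query_spectrum_id)
  feats <- query_table$features
  links <- character()
  dropped <- 0L
  for (qid in qids) {
    sp <- spec_by_id[[qid]]
    if (is.null(sp)) { dropped <- dropped + 1L; next }
    if (!is.na(sp$feature_id) && sp$feature_id %in% feats$feature_id) {
      links[qid] <- sp$feature_id
      next
    }
    dm <- abs(feats$mz - sp$precursor_mz)
    ok <- !is.na(dm) & dm <= mz_tol
    if (!is.na(sp$retention_time)) {
      dr <- abs(feats$rt - sp$retention_time)
      ok <- ok & !is.na(dr) & dr <= rt_tol
    }
    if (!any(ok)) { dropped <- dropped + 1L; next }
    cand <- which(ok)
    if (!is.na(sp$retention_time)) {
      dr <- abs(feats$rt - sp$retention_time)
      cand <- cand[order(dm[cand], dr[cand])]
    } else {
      cand <- cand[order(dm[cand])]
    }
    links[qid] <- feats$feature_id[cand[1L]]
  }
  if (dropped > 0)
    message(dropped, " matched spectrum(s) could not be linked to a feature and were dropped")
  attr(links, "n_dropped") <- dropped
  links
}

#' Per-sample, per-category dietary scores
#'
#' The dietary score of sample s for food category c is the mean MS1
#' intensity of c's library biomarkers in s. A biomarker contributes the
#' intensity of the query feature its reference spectrum matched; with
#' `fill = "zeros"` (default) biomarkers without a match contribute 0 and
#' the mean runs over all biomarkers of the category, with
#' `fill = "detected_only"` the mean runs over matched biomarkers only
#' (0 when none matched). When a biomarker's spectrum was matched by
#' several query spectra, the best-scoring match is used.
#'
#' With `matches = NULL` the library is instead joined to the query table
#' directly by `feature_id` (feature-id matching mode, for queries aligned
#' in the same feature space as the reference data; this is the only mode
#' in which spectrum-less library entries can contribute).
#'
#' @param query_table query [feature_table].
#' @param library a `biomarker_library`.
#' @param matches data.frame from [search_library] (or `NULL` for
#'   feature-id mode).
#' @param links named vector from [link_matches_to_features]; required when
#'   `matches` is given.
#' @param fill `"zeros"` or `"detected_only"`.
#' @param tic_normalize divide each query sample by its total intensity
#'   before scoring (recommended for fecal/urine matrices where loading
#'   varies; off by default so raw scores stay linear in intensity).
#' @return matrix of class `dietary_scores`, samples x categories, with
#'   attributes `levels` (named integer per category), `fill` and
#'   `normalized`.
#' @export
dietary_scores <- function(query_table, library, matches = NULL, links = NULL,
                           fill = c("zeros", "detected_only"),
                           tic_normalize = FALSE) {
  fill <- match.arg(fill)
  stopifnot(inherits(query_table, "feature_table"),
            inherits(library, "biomarker_library"))
  M <- query_table$intensities
  if (tic_normalize) M <- tic_normalize_matrix(M, warn = FALSE)
  cats <- library$categories
  if (!nrow(cats)) stop("library has no categories")
  entries <- library$entries

  # per-entry linked query feature (NA when undetected)
  if (is.null(matches)) {
    linked_feature <- ifelse(entries$feature_id %in% rownames(M),
                             entries$feature_id, NA_character_)
  } else {
    if (is.null(links)) stop("links are required when matches are given")
    best_by_lib <- list()
    if (nrow(matches)) {
      m <- matches[matches$query_spectrum_id %in% names(links), , drop = FALSE]
      if (nrow(m)) {
        m <- m[order(m$library_spectrum_id, -m$score, m$query_spectrum_id), , drop = FALSE]
        m <- m[!duplicated(m$library_spectrum_id), , drop = FALSE]
        best_by_lib <- stats::setNames(as.list(links[m$query_spectrum_id]),
                                       m$library_spectrum_id)
      }
    }
    linked_feature <- vapply(entries$reference_spectrum_id, function(rs) {
      if (is.na(rs)) return(NA_character_)
      f <- best_by_lib[[rs]]
      if (is.null(f) || is.na(f) || !(f %in% rownames(M))) NA_character_ else f
    }, "", USE.NAMES = FALSE)
  }

  scores <- matrix(0, ncol(M), nrow(cats),
                   dimnames = list(colnames(M), cats$category_id))
  for (k in seq_len(nrow(cats))) {
    idx <- which(entries$category_id == cats$category_id[k])
    if (!length(idx)) {
      warning("category '", cats$category_id[k], "' has no biomarkers; scores are 0")
      next
    }
    lf <- linked_feature[idx]
    det <- !is.na(lf)
    if (!any(det)) next
    contrib <- M[lf[det], , drop = FALSE]   # detected biomarkers x samples
    denom <- if (fill == "zeros") length(idx) else sum(det)
    scores[, k] <- colSums(contrib) / denom
  }
  structure(scores,
            levels = stats::setNames(as.integer(cats$level), cats$category_id),
            fill = fill, normalized = FALSE,
            class = c("dietary_scores", "matrix", "array"))
}

#' Convert raw dietary scores to within-level proportions
#'
#' Within each sample, scores of the categories at one ontology level are
#' divided by their sum, giving a proportional readout comparable across
#' samples; all-zero rows stay zero. Only categories of the requested level
#' are returned — mixing granularities across levels is not meaningful.
#'
#' @param scores a `dietary_scores` matrix.
#' @param level ontology level whose categories to normalize over.
#' @return `dietary_scores` matrix restricted to that level, rows summing
#'   to 1 (or 0).
#' @export
normalize_scores <- function(scores, level) {
  stopifnot(inherits(scores, "dietary_scores"))
  lv <- attr(scores, "levels")
  keep <- names(lv)[lv == level]
  if (!length(keep)) stop("no categories at ontology level ", level)
  sub <- unclass(scores)[, keep, drop = FALSE]
  rs <- rowSums(sub)
  nz <- rs > 0
  sub[nz, ] <- sub[nz, , drop = FALSE] / rs[nz]
  structure(sub, levels = lv[keep], fill = attr(scores, "fill"),
            normalized = TRUE, level = level,
            class = c("dietary_scores", "matrix", "array"))
}

#' @export
print.dietary_scores <- function(x, ...) {
  cat(sprintf("<dietary_scores> %d samples x %d categories (fill=%s%s)\n",
              nrow(x), ncol(x), attr(x, "fill"),
              if (isTRUE(attr(x, "normalized"))) ", proportions" else ""))
  print(utils::head(unclass(x), 5L))
  invisible(x)
}

#' Write / read a dietary score matrix (TSV + JSON sidecar)
#'
#' The sidecar records the fill mode, normalization state and category
#' levels so a reloaded matrix behaves identically.
#'
#' @param scores a `dietary_scores` matrix.
#' @param path TSV path; the sidecar goes to `<path>.json`.
#' @return `path` (write) or the `dietary_scores` matrix (read).
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "dietary_scores"))
  df <- data.frame(sample_id = rownames(scores), unclass(scores),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(levels = as.list(attr(scores, "levels")),
                  fill = attr(scores, "fill"),
                  normalized = attr(scores, "normalized"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  sidecar_path <- paste0(path, ".json")
  lv <- stats::setNames(rep(NA_integer_, ncol(m)), colnames(m))
  fill <- "zeros"; normalized <- FALSE
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    lv <- stats::setNames(as.integer(sc$levels[colnames(m)]), colnames(m))
    fill <- sc$fill %||% "zeros"
    normalized <- isTRUE(sc$normalized)
  }
  structure(m, levels = lv, fill = fill, normalized = normalized,
            class = c("dietary_scores", "matrix", "array"))
}
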