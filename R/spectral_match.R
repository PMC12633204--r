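# Candidate fragment pairings between two peak lists. Intensities are
# square-root transformed first (damps base-peak dominance, as in standard
# library search); a pair is admissible when the m/z difference is within
# the fragment tolerance either directly or after subtracting `shift` (the
# precursor mass difference, for modified cosine). Zero-weight pairs are
# dropped.
.candidate_pairs <- function(a, b, fragment_tol, shift = 0) {
  wa <- sqrt(a$peaks[, 2L])
  wb <- sqrt(b$peaks[, 2L])
  d <- outer(a$peaks[, 1L], b$peaks[, 1L], "-")
  ok <- abs(d) <= fragment_tol
  if (shift != 0) ok <- ok | abs(d - shift) <= fragment_tol
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(list(pairs = data.frame(i = integer(), j = integer(),
                                   weight = numeric(), resid = numeric()),
                norm = sqrt(sum(wa^2)) * sqrt(sum(wb^2))))
  }
  resid <- abs(d[idx])
  if (shift != 0) resid <- pmin(resid, abs(d[idx] - shift))
  pairs <- data.frame(i = idx[, 1L], j = idx[, 2L],
                      weight = wa[idx[, 1L]] * wb[idx[, 2L]],
                      resid = resid)
  pairs <- pairs[pairs$weight > 0, , drop = FALSE]
  list(pairs = pairs, norm = sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
}

# greedy one-to-one pairing by descending pair weight, ties broken by
# smaller m/z residual (deterministic)
.greedy_assignment <- function(pairs) {
  ord <- order(-pairs$weight, pairs$resid, pairs$i, pairs$j)
  used_i <- logical(0)
  used_j <- logical(0)
  total <- 0
  matched <- 0L
  for (r in ord) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (isTRUE(used_i[i]) || isTRUE(used_j[j])) next
    used_i[i] <- TRUE
    used_j[j] <- TRUE
    total <- total + pairs$weight[r]
    matched <- matched + 1L
  }
  list(weight = total, matched = matched)
}

# exact maximum-weight one-to-one pairing by branch-and-bound over the
# peaks of spectrum a; intended for small peak lists (<= 12 by default)
.exact_assignment <- function(pairs) {
  if (!nrow(pairs)) return(list(weight = 0, matched = 0L))
  by_i <- split(seq_len(nrow(pairs)), pairs$i)
  maxw <- vapply(by_i, function(r) max(pairs$weight[r]), 0)
  suffix <- c(rev(cumsum(rev(maxw))), 0)
  best_w <- -1
  best_n <- 0L
  used <- logical(max(pairs$j))
  rec <- function(k, acc_w, acc_n) {
    if (k > length(by_i)) {
      if (acc_w > best_w + 1e-15 ||
          (abs(acc_w - best_w) <= 1e-15 && acc_n > best_n)) {
        best_w <<- acc_w
        best_n <<- acc_n
      }
      return(invisible())
    }
    if (acc_w + suffix[k] < best_w - 1e-15) return(invisible())
    for (r in by_i[[k]]) {
      j <- pairs$j[r]
      if (!used[j]) {
        used[j] <<- TRUE
        rec(k + 1L, acc_w + pairs$weight[r], acc_n + 1L)
        used[j] <<- FALSE
      }
    }
    rec(k + 1L, acc_w, acc_n)  # leave peak k unmatched
  }
  rec(1L, 0, 0L)
  list(weight = max(best_w, 0), matched = best_n)
}

.pair_score <- function(a, b, fragment_tol, shift, method, exact_max_peaks = 12L) {
  if (!inherits(a, "ms_spectrum") || !inherits(b, "ms_spectrum"))
    stop("both arguments must be ms_spectrum objects")
  if (nrow(a$peaks) < 1L || nrow(b$peaks) < 1L)
    stop("cannot score an empty spectrum")
  if (fragment_tol <= 0) stop("fragment_tol must be > 0")
  cp <- .candidate_pairs(a, b, fragment_tol, shift)
  if (!nrow(cp$pairs)) return(list(score = 0, matched_peaks = 0L))
  use_exact <- switch(method,
                      exact = TRUE,
                      greedy = FALSE,
                      auto = nrow(a$peaks) <= exact_max_peaks &&
                             nrow(b$peaks) <= exact_max_peaks)
  res <- if (use_exact) .exact_assignment(cp$pairs) else .greedy_assignment(cp$pairs)
  score <- res$weight / cp$norm
  list(score = min(max(score, 0), 1), matched_peaks = res$matched)
}

#' Cosine similarity between two MS/MS spectra
#'
#' Fragment peaks within `fragment_tol` of each other are candidate pairs;
#' a one-to-one pairing maximizing the summed products of square-root
#' transformed intensities is chosen and normalized by the two spectra's
#' intensity norms, giving a score in [0, 1]. The default pairing is exact
#' (branch and bound) for spectra of up to 12 peaks and greedy by
#' descending pair weight above that.
#'
#' @param a,b [ms_spectrum] objects with at least one peak.
#' @param fragment_tol fragment m/z tolerance in Da.
#' @param method `"auto"`, `"greedy"` or `"exact"`.
#' @return list with `score` and `matched_peaks`.
#' @export
cosine_score <- function(a, b, fragment_tol = 0.02,
                         method = c("auto", "greedy", "exact")) {
  .pair_score(a, b, fragment_tol, shift = 0, method = match.arg(method))
}

#' Modified cosine similarity (analog matching)
#'
#' Like [cosine_score], but fragment pairs are also admissible when their
#' m/z difference equals the precursor mass difference between the two
#' spectra (within tolerance). This pairs a parent compound with host- or
#' microbially-modified derivatives (methylation, hydroxylation,
#' glucuronidation, ...) whose fragments shift with the modified moiety.
#' With equal precursors it reduces exactly to the plain cosine.
#'
#' @inheritParams cosine_score
#' @return list with `score` and `matched_peaks`.
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.02,
                            method = c("auto", "greedy", "exact")) {
  if (is.na(a$precursor_mz) || is.na(b$precursor_mz))
    stop("modified cosine requires precursor m/z on both spectra")
  .pair_score(a, b, fragment_tol, shift = a$precursor_mz - b$precursor_mz,
              method = match.arg(method))
}

#' Search query spectra against a biomarker library
#'
#' In `"cosine"` mode only pairs whose precursor m/z agree within
#' `precursor_tol` are compared; in `"modified_cosine"` (analog) mode the
#' precursor difference may be up to `analog_max_delta`. Matches are kept
#' when the score reaches `min_score` and at least `min_peaks` fragment
#' pairs matched; per query, matches are sorted by descending score.
#'
#' @param queries list of [ms_spectrum].
#' @param library a `biomarker_library` with reference spectra.
#' @param precursor_tol precursor tolerance (Da) for cosine mode.
#' @param fragment_tol fragment tolerance (Da).
#' @param min_peaks minimum matched peak count.
#' @param min_score minimum score in [0, 1].
#' @param mode `"cosine"` or `"modified_cosine"`.
#' @param analog_max_delta maximum |precursor delta| in analog mode (Da).
#' @return data.frame with columns `query_spectrum_id`,
#'   `library_spectrum_id`, `category_id` (semicolon-joined categories of
#'   the library entries carrying that spectrum), `score`, `matched_peaks`,
#'   `precursor_delta` (query - library), `mode`.
#' @export
search_library <- function(queries, library, precursor_tol = 0.01,
                           fragment_tol = 0.02, min_peaks = 4L,
                           min_score = 0.7,
                           mode = c("cosine", "modified_cosine"),
                           analog_max_delta = 200) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "biomarker_library"))
  if (!length(library$spectra)) stop("library has no reference spectra")
  lib_ids <- names(library$spectra)
  lib_prec <- vapply(library$spectra, function(s) s$precursor_mz, 0)
  cat_of <- vapply(lib_ids, function(id) {
    cats <- library$entries$category_id[
      !is.na(library$entries$reference_spectrum_id) &
        library$entries$reference_spectrum_id == id]
    paste(unique(cats), collapse = ";")
  }, "")
  max_delta <- if (mode == "cosine") precursor_tol else analog_max_delta
  rows <- list()
  for (q in queries) {
    dp <- q$precursor_mz - lib_prec
    cand <- which(abs(dp) <= max_delta)
    if (!length(cand)) next
    hits <- list()
    for (ci in cand) {
      lsp <- library$spectra[[ci]]
      res <- if (mode == "cosine") cosine_score(q, lsp, fragment_tol)
             else modified_cosine(q, lsp, fragment_tol)
      if (res$score >= min_score && res$matched_peaks >= min_peaks) {
        hits[[length(hits) + 1L]] <- data.frame(
          query_spectrum_id = q$spectrum_id,
          library_spectrum_id = lib_ids[ci],
          category_id = cat_of[[ci]],
          score = res$score,
          matched_peaks = res$matched_peaks,
          precursor_delta = dp[ci],
          mode = mode,
          stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) {
      hits <- do.call(rbind, hits)
      rows[[length(rows) + 1L]] <-
        hits[order(-hits$score, hits$library_spectrum_id), , drop = FALSE]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    query_spectrum_id = character(), library_spectrum_id = character(),
    category_id = character(), score = numeric(), matched_peaks = integer(),
    precursor_delta = numeric(), mode = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a spectral match table (TSV)
#'
#' The exported table is the interchange format consumed by the readout
#' stage, mirroring a "library matching results" input.
#'
#' @param matches data.frame from [search_library].
#' @param path TSV path.
#' @return `path` (write) or the match data.frame (read).
#' @export
write_matches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  req <- c("query_spectrum_id", "library_spectrum_id", "score", "matched_peaks")
  if (!all(req %in% names(df)))
    stop("match table requires columns: ", paste(req, collapse = ", "))
  df$query_spectrum_id <- as.character(df$query_spectrum_id)
  df$library_spectrum_id <- as.character(df$library_spectrum_id)
  df
}
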