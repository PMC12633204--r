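#' Per-feature fold-change enrichment
#'
#' Ratio of a feature's mean intensity in the target samples to its mean in
#' the rest, computed on TIC-normalized but UN-logged intensities (a
#' "6-fold enrichment" is a ratio statement on abundances, not on logs).
#' A pseudo-count epsilon is added to both means so features absent from
#' the rest give finite ratios.
#'
#' @param table a [feature_table].
#' @param positives,negatives disjoint, non-empty character vectors of
#'   sample ids.
#' @param epsilon pseudo-count; default is half the smallest nonzero
#'   TIC-normalized intensity in the table (scale-aware).
#' @return named numeric vector of ratios with attributes `mean_target`,
#'   `mean_rest` and `epsilon`.
#' @export
fold_change <- function(table, positives, negatives, epsilon = NULL) {
  stopifnot(inherits(table, "feature_table"))
  positives <- as.character(positives)
  negatives <- as.character(negatives)
  if (!length(positives) || !length(negatives))
    stop("positives and negatives must be non-empty")
  if (length(intersect(positives, negatives)))
    stop("positives and negatives must be disjoint")
  unknown <- setdiff(c(positives, negatives), table$sample_ids)
  if (length(unknown)) stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  M <- tic_normalize_matrix(table$intensities, warn = FALSE)
  if (is.null(epsilon)) {
    nz <- M[M > 0]
    epsilon <- if (length(nz)) min(nz) / 2 else 1e-12
  }
  if (!is_scalar_number(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  mp <- rowMeans(M[, positives, drop = FALSE])
  mn <- rowMeans(M[, negatives, drop = FALSE])
  fc <- (mp + epsilon) / (mn + epsilon)
  attr(fc, "mean_target") <- mp
  attr(fc, "mean_rest") <- mn
  attr(fc, "epsilon") <- epsilon
  fc
}

#' Apply the VIP and fold-change co-filter
#'
#' A feature is retained as a category biomarker iff its VIP score strictly
#' exceeds `vip_threshold`, its fold-change is at least `fold_threshold`
#' (inclusive), and the change is an enrichment (target mean above rest
#' mean, i.e. ratio > 1).
#'
#' @param vip named VIP vector from [vip_scores].
#' @param fc named fold-change vector from [fold_change], aligned to `vip`.
#' @param vip_threshold strict lower bound on VIP (default 4.0).
#' @param fold_threshold inclusive lower bound on enrichment (default 6).
#' @return character vector of selected feature ids.
#' @export
select_biomarkers <- function(vip, fc, vip_threshold = 4.0, fold_threshold = 6.0) {
  if (length(vip) != length(fc)) stop("vip and fc must have equal length")
  if (!is.null(names(vip)) && !is.null(names(fc)) && !identical(names(vip), names(fc)))
    stop("vip and fc must be aligned to the same features")
  keep <- (vip > vip_threshold) & (fc >= fold_threshold) & (fc > 1)
  names(vip)[which(keep)]
}

#' Learn a food-biomarker library from reference data
#'
#' For every one-vs-rest contrast enumerated from the ontology the pipeline
#' runs: preprocess -> OPLS-DA -> VIP -> fold-change -> co-filter, and
#' accumulates the selected (feature, category) entries together with each
#' feature's representative MS/MS spectrum. Features lacking a spectrum are
#' kept but flagged spectrum-less (usable only in feature-id matching).
#'
#' @param table reference [feature_table] (features x food samples).
#' @param ontology a [food_ontology] assigning those samples to leaves.
#' @param spectra list of [ms_spectrum] linked to features via their
#'   `feature_id` field (may be `NULL`).
#' @param vip_threshold,fold_threshold see [select_biomarkers].
#' @param preprocess_spec a [preprocess_spec] used before OPLS-DA.
#' @param scope,min_group_size see [enumerate_contrasts].
#' @param n_ortho orthogonal components per OPLS-DA fit.
#' @param epsilon fold-change pseudo-count; `NULL` for the scale-aware
#'   default.
#' @param verbose emit a per-run log message.
#' @return Object of class `biomarker_library`: `entries` data.frame,
#'   `spectra` (named list of referenced spectra), `categories` (all
#'   contrasted categories with levels), `parameters`, and a `run_log`
#'   data.frame of per-contrast sizes and selection counts.
#' @export
learn_library <- function(table, ontology, spectra = NULL,
                          vip_threshold = 4.0, fold_threshold = 6.0,
                          preprocess_spec = foodreadout::preprocess_spec(),
                          scope = c("global", "siblings"),
                          min_group_size = 3L, n_ortho = 1L,
                          epsilon = NULL, verbose = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "feature_table"), inherits(ontology, "food_ontology"))
  samples <- intersect(table$sample_ids, names(ontology$assignments))
  if (!length(samples)) stop("no table samples have ontology assignments")
  contrasts <- enumerate_contrasts(ontology, samples, scope = scope,
                                   min_group_size = min_group_size)
  # spectrum lookup: first spectrum per feature id
  spec_by_feature <- list()
  spectra <- spectra %||% list()
  for (s in spectra) {
    if (!is.na(s$feature_id) && is.null(spec_by_feature[[s$feature_id]]))
      spec_by_feature[[s$feature_id]] <- s
  }
  if (is.null(epsilon)) {
    M <- tic_normalize_matrix(table$intensities, warn = FALSE)
    nz <- M[M > 0]
    epsilon <- if (length(nz)) min(nz) / 2 else 1e-12
  }
  # preprocessing depends only on the sample set; cache across contrasts
  pp_cache <- new.env(parent = emptyenv())
  get_pp <- function(sample_set) {
    key <- paste(sort(sample_set), collapse = "\r")
    if (is.null(pp_cache[[key]]))
      pp_cache[[key]] <- preprocess(table, preprocess_spec, samples = sample_set)
    pp_cache[[key]]
  }
  entries <- list()
  log_rows <- list()
  for (ct in contrasts) {
    res <- tryCatch({
      sample_set <- c(ct$positives, ct$negatives)
      pp <- get_pp(sample_set)
      y <- ifelse(rownames(pp$matrix) %in% ct$positives, 1, -1)
      model <- fit_opls(pp$matrix, y, n_ortho = n_ortho)
      vip <- vip_scores(model)
      fc <- fold_change(table, ct$positives, ct$negatives, epsilon = epsilon)
      sel <- select_biomarkers(vip, fc, vip_threshold, fold_threshold)
      list(sel = sel, vip = vip, fc = fc)
    }, error = function(e) {
      stop(sprintf("contrast '%s' (level %d): %s",
                   ct$target_category, ct$level, conditionMessage(e)), call. = FALSE)
    })
    mt <- attr(res$fc, "mean_target")
    mr <- attr(res$fc, "mean_rest")
    if (length(res$sel)) {
      sp_ids <- vapply(res$sel, function(f) {
        sp <- spec_by_feature[[f]]
        if (is.null(sp)) NA_character_ else sp$spectrum_id
      }, "")
      entries[[length(entries) + 1L]] <- data.frame(
        feature_id = res$sel,
        category_id = ct$target_category,
        level = ct$level,
        vip = unname(res$vip[res$sel]),
        fold_change = unname(res$fc[res$sel]),
        mean_intensity_target = unname(mt[res$sel]),
        mean_intensity_rest = unname(mr[res$sel]),
        reference_spectrum_id = unname(sp_ids),
        annotation = "",
        stringsAsFactors = FALSE)
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      category_id = ct$target_category, level = ct$level,
      n_positives = length(ct$positives), n_negatives = length(ct$negatives),
      n_selected = length(res$sel), stringsAsFactors = FALSE)
  }
  entries <- if (length(entries)) do.call(rbind, entries) else data.frame(
    feature_id = character(), category_id = character(), level = integer(),
    vip = numeric(), fold_change = numeric(),
    mean_intensity_target = numeric(), mean_intensity_rest = numeric(),
    reference_spectrum_id = character(), annotation = character(),
    stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  run_log <- do.call(rbind, log_rows)
  ref_ids <- unique(stats::na.omit(entries$reference_spectrum_id))
  lib_spectra <- list()
  for (s in spec_by_feature) {
    if (s$spectrum_id %in% ref_ids) lib_spectra[[s$spectrum_id]] <- s
  }
  if (verbose)
    message(sprintf("learn_library: %d contrasts, %d entries, %d with spectra",
                    length(contrasts), nrow(entries), length(lib_spectra)))
  structure(list(
    entries = entries,
    spectra = lib_spectra,
    categories = unique(run_log[, c("category_id", "level")]),
    parameters = list(vip_threshold = vip_threshold,
                      fold_threshold = fold_threshold,
                      preprocess = unclass(preprocess_spec),
                      scope = scope, min_group_size = as.integer(min_group_size),
                      n_ortho = as.integer(n_ortho), epsilon = epsilon),
    run_log = run_log),
    class = "biomarker_library")
}

#' @export
print.biomarker_library <- function(x, ...) {
  cat(sprintf("<biomarker_library> %d entries across %d categories (%d reference spectra)\n",
              nrow(x$entries), length(unique(x$entries$category_id)), length(x$spectra)))
  cat(sprintf("  thresholds: VIP > %.2f, fold-change >= %.2f\n",
              x$parameters$vip_threshold, x$parameters$fold_threshold))
  invisible(x)
}

#' Write a biomarker library (JSON + companion MGF)
#'
#' @param library a `biomarker_library`.
#' @param path output JSON path; reference spectra go to `mgf_path`.
#' @param mgf_path companion MGF path (default: `path` with `.mgf`).
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, mgf_path = NULL) {
  stopifnot(inherits(library, "biomarker_library"))
  if (is.null(mgf_path)) mgf_path <- sub("(\\.json)?$", ".mgf", path)
  doc <- list(entries = library$entries,
              categories = library$categories,
              parameters = library$parameters,
              run_log = library$run_log,
              spectra_file = basename(mgf_path))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "rows")
  write_mgf(unname(library$spectra), mgf_path)
  invisible(path)
}

#' Read a biomarker library written by [write_library]
#'
#' Validates that every `reference_spectrum_id` resolves in the companion
#' MGF and audits each entry against the thresholds recorded in the file
#' (self-consistency check).
#'
#' @param path library JSON path.
#' @param mgf_path companion MGF; default is the file named inside the JSON,
#'   resolved next to `path`.
#' @return A `biomarker_library`.
#' @export
read_library <- function(path, mgf_path = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(mgf_path))
    mgf_path <- file.path(dirname(path), doc$spectra_file %||% sub("(\\.json)?$", ".mgf", basename(path)))
  spectra <- list()
  if (file.exists(mgf_path)) {
    for (s in read_mgf(mgf_path)) spectra[[s$spectrum_id]] <- s
  }
  entries <- as.data.frame(doc$entries, stringsAsFactors = FALSE)
  if (!nrow(entries)) {
    entries <- data.frame(feature_id = character(), category_id = character(),
                          level = integer(), vip = numeric(), fold_change = numeric(),
                          mean_intensity_target = numeric(), mean_intensity_rest = numeric(),
                          reference_spectrum_id = character(), annotation = character(),
                          stringsAsFactors = FALSE)
  } else {
    entries$level <- as.integer(entries$level)
    if (is.null(entries$reference_spectrum_id))
      entries$reference_spectrum_id <- NA_character_
  }
  pars <- doc$parameters
  ref <- stats::na.omit(entries$reference_spectrum_id)
  unresolved <- setdiff(ref, names(spectra))
  if (length(unresolved))
    stop("library references unresolved spectrum id(s): ",
         paste(utils::head(unresolved, 5L), collapse = ", "))
  bad <- nrow(entries) && any(entries$vip <= pars$vip_threshold |
                              entries$fold_change < pars$fold_threshold)
  if (isTRUE(bad))
    stop("library self-consistency audit failed: entries violate recorded thresholds")
  structure(list(entries = entries, spectra = spectra,
                 categories = as.data.frame(doc$categories, stringsAsFactors = FALSE),
                 parameters = pars,
                 run_log = as.data.frame(doc$run_log, stringsAsFactors = FALSE)),
            class = "biomarker_library")
}
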