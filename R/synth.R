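#' Configuration for the synthetic reference-food generator
#'
#' Defaults emulate a desk-scale reference food experiment: 8 leaf food
#' categories with 12 reference samples each, 40 category-specific ion
#' features planted at 10-fold enrichment over a shared background of 400
#' features, multiplicative lognormal intensity noise with 30% CV, and 10%
#' random dropout (non-detection). Each feature carries a reproducible
#' random MS/MS spectrum.
#'
#' @param n_categories number of leaf food categories.
#' @param ontology_depth 1 (root -> leaves) or 2 (root -> 2 branches ->
#'   leaves).
#' @param samples_per_category reference samples per leaf.
#' @param planted_per_category category-specific features per leaf.
#' @param background_features features common to all foods.
#' @param planted_fold enrichment multiplier of planted features in their
#'   home category (> 1).
#' @param intensity_cv lognormal coefficient of variation of intensities.
#' @param dropout_rate probability a measured intensity is zeroed, in
#'   [0, 1).
#' @param peaks_per_spectrum fragment peaks per synthetic spectrum.
#' @param fragment_mz_range m/z range the fragments are drawn from (Da).
#' @param branch_planted_per_branch extra features planted at
#'   `planted_fold` across every leaf of a depth-1 branch (depth 2 only);
#'   gives branch-level biomarkers.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_categories = 8L, ontology_depth = 1L,
                         samples_per_category = 12L,
                         planted_per_category = 40L,
                         background_features = 400L,
                         planted_fold = 10, intensity_cv = 0.3,
                         dropout_rate = 0.1, peaks_per_spectrum = 8L,
                         fragment_mz_range = c(50, 500),
                         branch_planted_per_branch = 0L, seed = 1L) {
  if (planted_fold <= 1) stop("planted_fold must be > 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (n_categories < 2L) stop("need at least 2 categories")
  if (samples_per_category < 1L) stop("samples_per_category must be >= 1")
  if (!ontology_depth %in% c(1L, 2L)) stop("ontology_depth must be 1 or 2")
  if (ontology_depth == 1L && branch_planted_per_branch > 0L)
    stop("branch-level markers require ontology_depth = 2")
  structure(list(n_categories = as.integer(n_categories),
                 ontology_depth = as.integer(ontology_depth),
                 samples_per_category = as.integer(samples_per_category),
                 planted_per_category = as.integer(planted_per_category),
                 background_features = as.integer(background_features),
                 planted_fold = planted_fold, intensity_cv = intensity_cv,
                 dropout_rate = dropout_rate,
                 peaks_per_spectrum = as.integer(peaks_per_spectrum),
                 fragment_mz_range = fragment_mz_range,
                 branch_planted_per_branch = as.integer(branch_planted_per_branch),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# lognormal sdlog from a coefficient of variation
.cv_sdlog <- function(cv) sqrt(log(1 + cv^2))

.random_spectrum <- function(id, precursor_mz, rt, feature_id, n_peaks, mz_range) {
  mz <- sort(stats::runif(n_peaks, mz_range[1L], mz_range[2L]))
  intensity <- stats::rexp(n_peaks, rate = 1e-4)  # peak heights ~ 1e4 scale
  ms_spectrum(id, precursor_mz, cbind(mz, intensity),
              retention_time = rt, feature_id = feature_id)
}

#' Simulate a reference food metabolomics dataset with planted ground truth
#'
#' Background features share one lognormal intensity profile across all
#' categories; planted features are multiplied by `planted_fold` in their
#' home category (or across a whole branch for branch-level markers).
#' Multiplicative lognormal noise and Bernoulli dropout are applied, and
#' every feature receives a reproducible random spectrum. The same seed
#' yields an identical dataset.
#'
#' @param config a [synth_config].
#' @return list of class `synth_reference`: `table` ([feature_table]),
#'   `ontology` ([food_ontology]), `spectra` (list of [ms_spectrum]),
#'   `truth` (planted map category -> feature ids) and `config`.
#' @export
simulate_reference <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  K <- config$n_categories
  leaves <- sprintf("cat_%02d", seq_len(K))
  if (config$ontology_depth == 1L) {
    nodes <- data.frame(category_id = c("food", leaves),
                        name = c("food", leaves),
                        parent_id = c(NA, rep("food", K)),
                        stringsAsFactors = FALSE)
    branch_of <- NULL
  } else {
    branches <- c("branch_1", "branch_2")
    branch_of <- rep(branches, c(ceiling(K / 2), floor(K / 2)))
    nodes <- data.frame(category_id = c("food", branches, leaves),
                        name = c("food", branches, leaves),
                        parent_id = c(NA, "food", "food", branch_of),
                        stringsAsFactors = FALSE)
  }
  n_per <- config$samples_per_category
  sample_ids <- as.vector(vapply(seq_len(K), function(k)
    sprintf("%s_s%02d", leaves[k], seq_len(n_per)), character(n_per)))
  assignments <- stats::setNames(rep(leaves, each = n_per), sample_ids)
  ontology <- food_ontology(nodes, assignments)

  n_branch_planted <- if (config$ontology_depth == 2L)
    2L * config$branch_planted_per_branch else 0L
  p <- config$background_features + K * config$planted_per_category + n_branch_planted
  n <- length(sample_ids)
  fids <- sprintf("F%04d", seq_len(p))

  # planted layout: leaf blocks first, then branch blocks, then background
  truth <- list()
  fold_mask <- matrix(1, p, n)
  pos <- 0L
  for (k in seq_len(K)) {
    idx <- pos + seq_len(config$planted_per_category)
    pos <- pos + config$planted_per_category
    truth[[leaves[k]]] <- fids[idx]
    fold_mask[idx, assignments[sample_ids] == leaves[k]] <- config$planted_fold
  }
  if (n_branch_planted > 0L) {
    for (br in unique(branch_of)) {
      idx <- pos + seq_len(config$branch_planted_per_branch)
      pos <- pos + config$branch_planted_per_branch
      truth[[br]] <- fids[idx]
      br_leaves <- leaves[branch_of == br]
      fold_mask[idx, assignments[sample_ids] %in% br_leaves] <- config$planted_fold
    }
  }

  base <- stats::rlnorm(p, meanlog = log(1e6), sdlog = 1)
  mz <- stats::runif(p, 100, 1000)
  rt <- stats::runif(p, 30, 900)
  noise <- matrix(stats::rlnorm(p * n, 0, .cv_sdlog(config$intensity_cv)), p, n)
  M <- base * fold_mask * noise
  if (config$dropout_rate > 0)
    M[matrix(stats::runif(p * n), p, n) < config$dropout_rate] <- 0

  feats <- data.frame(feature_id = fids, mz = mz, rt = rt, stringsAsFactors = FALSE)
  table <- feature_table(feats, M, sample_ids)
  spectra <- vector("list", p)
  for (j in seq_len(p)) {
    spectra[[j]] <- .random_spectrum(paste0("SP_", fids[j]), mz[j], rt[j],
                                     fids[j], config$peaks_per_spectrum,
                                     config$fragment_mz_range)
  }
  structure(list(table = table, ontology = ontology, spectra = spectra,
                 truth = truth, config = config),
            class = "synth_reference")
}

# shared mixture machinery (no seeding here; callers seed)
.mixture_tables <- function(reference, design, noise_cv, dropout_rate,
                            feature_prefix = "QF", spectrum_prefix = "QS") {
  ref_tab <- reference$table
  leaves <- ontology_leaves(reference$ontology)
  comps <- colnames(design)
  unknown <- setdiff(comps, leaves)
  if (length(unknown))
    stop("unknown mixture component(s): ", paste(unknown, collapse = ", "))
  if (any(abs(rowSums(design) - 1) > 1e-6))
    stop("mixture design rows must sum to 1")
  assign <- reference$ontology$assignments
  profiles <- vapply(comps, function(cid) {
    sids <- names(assign)[assign == cid]
    rowMeans(ref_tab$intensities[, sids, drop = FALSE])
  }, numeric(nrow(ref_tab$intensities)))
  M <- profiles %*% t(design)   # features x mixture samples
  if (noise_cv > 0)
    M <- M * matrix(stats::rlnorm(length(M), 0, .cv_sdlog(noise_cv)),
                    nrow(M), ncol(M))
  if (dropout_rate > 0)
    M[matrix(stats::runif(length(M)), nrow(M), ncol(M)) < dropout_rate] <- 0
  qfids <- paste0(feature_prefix, ref_tab$features$feature_id)
  feats <- data.frame(feature_id = qfids, mz = ref_tab$features$mz,
                      rt = ref_tab$features$rt, stringsAsFactors = FALSE)
  table <- feature_table(feats, M, rownames(design))
  present <- rowSums(M) > 0
  ref_spec_by_fid <- stats::setNames(reference$spectra,
                                     vapply(reference$spectra, function(s) s$feature_id, ""))
  spectra <- list()
  for (j in which(present)) {
    rs <- ref_spec_by_fid[[ref_tab$features$feature_id[j]]]
    if (is.null(rs)) next
    spectra[[length(spectra) + 1L]] <- ms_spectrum(
      paste0(spectrum_prefix, "_", qfids[j]), rs$precursor_mz, rs$peaks,
      retention_time = rs$retention_time, feature_id = qfids[j])
  }
  list(table = table, spectra = spectra)
}

#' Simulate known-fraction food mixtures
#'
#' Each mixture sample is a convex combination of the component foods' mean
#' reference intensity profiles, followed by multiplicative lognormal noise
#' and optional dropout. Spectra of features present in the mixtures are
#' carried over from the reference (same molecule, same fragmentation) but
#' re-keyed to fresh query feature ids.
#'
#' @param reference a `synth_reference`.
#' @param design numeric matrix, mixture samples x components; column names
#'   are reference leaf categories, rows sum to 1, row names become sample
#'   ids.
#' @param noise_cv multiplicative noise CV.
#' @param dropout_rate per-cell dropout probability.
#' @param seed RNG seed.
#' @return list with `table` (query [feature_table]), `spectra` and
#'   `design`.
#' @export
simulate_mixture <- function(reference, design, noise_cv = 0.2,
                             dropout_rate = 0, seed = 1L) {
  stopifnot(inherits(reference, "synth_reference"))
  design <- as.matrix(design)
  if (is.null(rownames(design)))
    rownames(design) <- sprintf("mix_%02d", seq_len(nrow(design)))
  set.seed(as.integer(seed))
  out <- .mixture_tables(reference, design, noise_cv, dropout_rate)
  out$design <- design
  out
}

#' Simulate a diet-group cohort
#'
#' Each subject's sample is a mixture draw from its group's category-weight
#' profile with a subject-level lognormal random effect on the weights
#' (between-subject variation in habitual diet), plus measurement noise.
#'
#' @param reference a `synth_reference`.
#' @param groups named list: group name -> named weight vector over
#'   reference leaf categories (weights are normalized to sum to 1).
#' @param n_per_group subjects per group.
#' @param between_subject_cv CV of the subject-level weight perturbation.
#' @param noise_cv measurement noise CV.
#' @param dropout_rate per-cell dropout probability.
#' @param seed RNG seed.
#' @return list with `table`, `spectra`, `metadata` (data.frame sample_id,
#'   group) and `design`.
#' @export
simulate_cohort <- function(reference, groups, n_per_group = 10L,
                            between_subject_cv = 0.3, noise_cv = 0.2,
                            dropout_rate = 0, seed = 1L) {
  stopifnot(inherits(reference, "synth_reference"))
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2L)
    stop("groups must be a named list with at least 2 groups")
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  comps <- unique(unlist(lapply(groups, names)))
  set.seed(as.integer(seed))
  rows <- list()
  meta <- list()
  for (gname in names(groups)) {
    w <- groups[[gname]]
    if (is.null(names(w)) || !length(w)) stop("group '", gname, "' has an empty profile")
    for (i in seq_len(n_per_group)) {
      wi <- stats::setNames(numeric(length(comps)), comps)
      pert <- w * stats::rlnorm(length(w), 0, .cv_sdlog(between_subject_cv))
      wi[names(w)] <- pert / sum(pert)
      sid <- sprintf("%s_subj%02d", gname, i)
      rows[[sid]] <- wi
      meta[[sid]] <- gname
    }
  }
  design <- do.call(rbind, rows)
  out <- .mixture_tables(reference, design, noise_cv, dropout_rate)
  out$metadata <- data.frame(sample_id = names(meta),
                             group = unlist(meta, use.names = FALSE),
                             stringsAsFactors = FALSE)
  out$design <- design
  out
}
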