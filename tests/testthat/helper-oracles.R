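# Independent oracles and small fixture builders shared across tests.

# quick feature table from a features x samples matrix
make_ft <- function(M, mz = NULL, rt = NULL) {
  p <- nrow(M)
  fids <- rownames(M) %||% sprintf("F%03d", seq_len(p))
  sids <- colnames(M) %||% sprintf("s%02d", seq_len(ncol(M)))
  feature_table(
    data.frame(feature_id = fids,
               mz = mz %||% seq(100, by = 1.3, length.out = p),
               rt = rt %||% seq(60, by = 5, length.out = p),
               stringsAsFactors = FALSE),
    unname(M), sids)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

rand_spectrum <- function(id, n_peaks = 5, mz_pool = NULL, precursor = NULL,
                          feature_id = NA_character_, rt = NA_real_) {
  mz <- if (is.null(mz_pool)) sort(runif(n_peaks, 50, 500))
        else sort(sample(mz_pool, n_peaks) + runif(n_peaks, -0.005, 0.005))
  ms_spectrum(id, precursor %||% runif(1, 100, 1000),
              cbind(mz, rexp(n_peaks) + 0.05),
              retention_time = rt, feature_id = feature_id)
}

# one-component NIPALS PLS, written from the textbook iteration and kept
# independent of the package's OPLS code path
nipals_pls1 <- function(X, y, tol = 1e-12, max_iter = 200) {
  u <- y
  w_prev <- NULL
  for (it in seq_len(max_iter)) {
    w <- drop(crossprod(X, u)) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t_sc <- drop(X %*% w)
    q <- sum(y * t_sc) / sum(t_sc^2)
    u <- y * q / q^2
    if (!is.null(w_prev) && sqrt(sum((w - w_prev)^2)) < tol) break
    w_prev <- w
  }
  list(w = w, t = t_sc, q = q)
}

# exhaustive maximum one-to-one peak pairing by full enumeration of all
# assignments (each peak of `a` paired with a candidate of `b` or left out)
exhaustive_pair_score <- function(a, b, fragment_tol, shift = 0) {
  wa <- sqrt(a$peaks[, 2]); wb <- sqrt(b$peaks[, 2])
  d <- outer(a$peaks[, 1], b$peaks[, 1], "-")
  ok <- abs(d) <= fragment_tol
  if (shift != 0) ok <- ok | abs(d - shift) <= fragment_tol
  cand <- lapply(seq_len(nrow(a$peaks)), function(i) c(0L, which(ok[i, ])))
  grid <- as.matrix(do.call(expand.grid, cand))
  best <- 0
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    assigned <- g > 0L
    if (anyDuplicated(g[assigned])) next
    tot <- sum(wa[assigned] * wb[g[assigned]])
    if (tot > best) best <- tot
  }
  min(best / (sqrt(sum(wa^2)) * sqrt(sum(wb^2))), 1)
}

# PERMANOVA sums of squares spelled out with explicit loops
brute_permanova_stats <- function(m, labels) {
  d <- as.matrix(dist(m))
  n <- nrow(m)
  labs <- as.character(labels)
  gs <- unique(labs)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in gs) {
    idx <- which(labs == g)
    s <- 0
    if (length(idx) >= 2)
      for (ii in seq_len(length(idx) - 1)) for (jj in (ii + 1):length(idx))
        s <- s + d[idx[ii], idx[jj]]^2
    ssw <- ssw + s / length(idx)
  }
  f <- ((sst - ssw) / (length(gs) - 1)) / (ssw / (n - length(gs)))
  list(f = f, r2 = (sst - ssw) / sst, ssw_frac = ssw / sst)
}

# exact two-group PERMANOVA p by brute force over all label assignments
brute_exact_p_2group <- function(m, labels) {
  labs <- as.character(labels)
  gs <- unique(labs)
  stopifnot(length(gs) == 2)
  n <- length(labs)
  n1 <- sum(labs == gs[1])
  obs <- brute_permanova_stats(m, labs)$f
  combos <- combn(n, n1)
  fs <- apply(combos, 2, function(idx) {
    l <- rep(gs[2], n)
    l[idx] <- gs[1]
    brute_permanova_stats(m, l)$f
  })
  mean(fs >= obs - 1e-12)
}

# hand-built biomarker library fixture (feature-id matching mode)
toy_library <- function(feature_ids, category = "catA", level = 1L,
                        spectra = list()) {
  entries <- data.frame(
    feature_id = feature_ids, category_id = category, level = level,
    vip = 5, fold_change = 10,
    mean_intensity_target = 1, mean_intensity_rest = 0.1,
    reference_spectrum_id = vapply(feature_ids, function(f) {
      hit <- Filter(function(s) identical(s$feature_id, f), spectra)
      if (length(hit)) hit[[1]]$spectrum_id else NA_character_
    }, ""),
    annotation = "", stringsAsFactors = FALSE)
  sp <- list()
  for (s in spectra) sp[[s$spectrum_id]] <- s
  structure(list(entries = entries, spectra = sp,
                 categories = data.frame(category_id = unique(category),
                                         level = level[1],
                                         stringsAsFactors = FALSE),
                 parameters = list(vip_threshold = 4, fold_threshold = 6),
                 run_log = NULL),
            class = "biomarker_library")
}

small_synth_config <- function(seed = 1L, ...) {
  synth_config(n_categories = 4L, samples_per_category = 6L,
               planted_per_category = 10L, background_features = 100L,
               seed = seed, ...)
}
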