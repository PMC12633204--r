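#' PCA of a dietary score matrix
#'
#' Singular-value decomposition of the column-centered (optionally
#' unit-scaled) score matrix. Component signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param scores samples x categories matrix (e.g. `dietary_scores`).
#' @param n_components number of components to return.
#' @param scale. unit-scale columns before decomposition.
#' @return list of class `pca_result`: `sample_scores`, `loadings`,
#'   `explained_variance_ratio` (fractions of total variance,
#'   non-increasing).
#' @export
score_pca <- function(scores, n_components = 2L, scale. = FALSE) {
  m <- as.matrix(unclass(scores))
  if (nrow(m) < 2L) stop("PCA requires at least 2 samples")
  if (all(m == 0)) stop("cannot run PCA on an all-zero matrix")
  if (scale.) {
    keep <- col_sds(m) > 0
    m <- m[, keep, drop = FALSE]
  }
  pr <- stats::prcomp(m, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pr$rotation))
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sco <- pr$x[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {
    if (rot[which.max(abs(rot[, a])), a] < 0) {
      rot[, a] <- -rot[, a]
      sco[, a] <- -sco[, a]
    }
  }
  structure(list(sample_scores = sco, loadings = rot,
                 explained_variance_ratio = evr[seq_len(k)]),
            class = "pca_result")
}

# pseudo-F for a grouping on a squared-distance matrix
.permanova_f <- function(d2, group_idx, g_sizes, n, g, ss_total) {
  ss_within <- 0
  for (k in seq_len(g)) {
    idx <- group_idx[[k]]
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * g_sizes[k])
  }
  ss_between <- ss_total - ss_within
  list(f = (ss_between / (g - 1)) / (ss_within / (n - g)),
       r2 = ss_between / ss_total)
}

# all distinct arrangements of a label vector (as integer codes), up to cap
.enumerate_label_perms <- function(codes, cap) {
  n <- length(codes)
  counts <- tabulate(codes)
  total <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
  if (total > cap + 0.5) return(NULL)
  out <- vector("list", round(total))
  pos <- 0L
  vec <- integer(n)
  rec <- function(i, remaining) {
    if (i > n) {
      pos <<- pos + 1L
      out[[pos]] <<- vec
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      if (remaining[k] > 0L) {
        vec[i] <<- k
        remaining[k] <- remaining[k] - 1L
        rec(i + 1L, remaining)
        remaining[k] <- remaining[k] + 1L
      }
    }
  }
  rec(1L, counts)
  out
}

#' One-factor PERMANOVA on dietary scores
#'
#' Permutational multivariate analysis of variance: total and within-group
#' sums of squared pairwise distances give a pseudo-F and R-squared; the
#' p-value is the fraction of label permutations with an F at least as
#' large, computed as (1 + #{F_perm >= F_obs}) / (1 + n_permutations). When
#' the requested permutation count reaches the number of distinct label
#' arrangements, the test switches to exact enumeration over all
#' arrangements (reported via a message).
#'
#' @param scores samples x categories matrix.
#' @param labels grouping vector/factor aligned to rows.
#' @param distance `"euclidean"` or `"braycurtis"`.
#' @param n_permutations random permutations (>= 99).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @return list of class `permanova_result`: `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations` (permutations actually used),
#'   `exact` flag, `seed`, `distance`.
#' @export
score_permanova <- function(scores, labels,
                            distance = c("euclidean", "braycurtis"),
                            n_permutations = 999L, seed) {
  distance <- match.arg(distance)
  if (missing(seed) || !is_scalar_number(seed)) stop("an integer seed is required")
  m <- as.matrix(unclass(scores))
  labels <- as.factor(labels)
  if (length(labels) != nrow(m)) stop("labels must align with score rows")
  g_sizes <- table(labels)
  if (length(g_sizes) < 2L) stop("need at least 2 groups")
  if (any(g_sizes < 2L)) stop("every group needs at least 2 samples")
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  d <- if (distance == "euclidean") stats::dist(m)
       else vegan::vegdist(m, method = "bray")
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  g <- length(g_sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  codes <- as.integer(labels)
  split_idx <- function(cd) split(seq_len(n), cd)
  obs <- .permanova_f(d2, split_idx(codes), as.integer(g_sizes), n, g, ss_total)

  perms <- .enumerate_label_perms(codes, cap = n_permutations)
  if (!is.null(perms)) {
    message("switching to exact enumeration over ", length(perms),
            " distinct label arrangements")
    f_all <- vapply(perms, function(cd)
      .permanova_f(d2, split_idx(cd), as.integer(g_sizes), n, g, ss_total)$f, 0)
    p <- mean(f_all >= obs$f - 1e-12)
    n_used <- length(perms)
    exact <- TRUE
  } else {
    set.seed(as.integer(seed))
    count <- 0L
    for (b in seq_len(n_permutations)) {
      cd <- sample(codes)
      fb <- .permanova_f(d2, split_idx(cd), as.integer(g_sizes), n, g, ss_total)$f
      if (fb >= obs$f - 1e-12) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_permutations)
    n_used <- as.integer(n_permutations)
    exact <- FALSE
  }
  structure(list(r_squared = obs$r2, pseudo_f = obs$f, p_value = p,
                 n_permutations = n_used, exact = exact,
                 seed = as.integer(seed), distance = distance),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): R2 = %.4f, pseudo-F = %.3f, p = %.4g (%s, %d perms)\n",
              x$distance, x$r_squared, x$pseudo_f, x$p_value,
              if (x$exact) "exact" else "permutation", x$n_permutations))
  invisible(x)
}

#' Pearson correlation of dietary scores with metadata variables
#'
#' For every (category, variable) pair, the sample Pearson coefficient with
#' a two-sided t-test p-value (pairwise-complete observations, per-pair n
#' recorded) and Benjamini-Hochberg q-values over the whole grid.
#' Zero-variance pairs or pairs with fewer than 3 complete observations are
#' emitted flagged with `NA` statistics and excluded from the BH
#' adjustment.
#'
#' @param scores samples x categories matrix with sample row names.
#' @param metadata data.frame with a `sample_id` column covering the score
#'   rows.
#' @param variables metadata columns to use; default all numeric columns.
#' @return data.frame of class `correlation_table` with columns `category`,
#'   `variable`, `r`, `p`, `q`, `n`, `flag`.
#' @export
score_correlate <- function(scores, metadata, variables = NULL) {
  m <- as.matrix(unclass(scores))
  if (!"sample_id" %in% names(metadata)) stop("metadata needs a sample_id column")
  missing_meta <- setdiff(rownames(m), metadata$sample_id)
  if (length(missing_meta))
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (is.null(variables)) {
    variables <- names(meta)[vapply(meta, is.numeric, TRUE)]
  } else {
    bad <- setdiff(variables, names(meta))
    if (length(bad)) stop("unknown metadata variable(s): ", paste(bad, collapse = ", "))
    nonnum <- variables[!vapply(meta[variables], is.numeric, TRUE)]
    if (length(nonnum)) stop("non-numeric variable(s): ", paste(nonnum, collapse = ", "))
  }
  if (!length(variables)) stop("no numeric metadata variables to correlate")
  grid <- expand.grid(category = colnames(m), variable = variables,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- m[, grid$category[i]]
    y <- meta[[grid$variable[i]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(category = grid$category[i], variable = grid$variable[i],
                        r = NA_real_, p = NA_real_, n = n, flag = "degenerate",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(category = grid$category[i], variable = grid$variable[i],
               r = unname(ct$estimate), p = ct$p.value, n = n, flag = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  usable <- out$flag == ""
  out$q[usable] <- stats::p.adjust(out$p[usable], method = "BH")
  out <- out[, c("category", "variable", "r", "p", "q", "n", "flag")]
  class(out) <- c("correlation_table", "data.frame")
  out
}
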