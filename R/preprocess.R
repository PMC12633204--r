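#' Preprocessing specification for discriminant analysis
#'
#' Defaults: per-sample TIC normalization, log10(x + 1) transform, then
#' column-wise centering with unit-variance scaling. LC-MS peak areas are
#' compositional (injection amount varies) and span orders of magnitude, so
#' the defaults normalize sample totals and stabilize the intensity spread;
#' every stage is configurable.
#'
#' @param tic_normalize divide each sample by its total intensity first.
#' @param log_transform `"log10"` for log10(x+1), `"log2"` for log2(x+1),
#'   or `"none"`.
#' @param scaling `"uv"` (center + unit variance), `"center"`, `"pareto"`
#'   (center + divide by sqrt(sd)), or `"none"`.
#' @return Object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(tic_normalize = TRUE,
                            log_transform = c("log10", "log2", "none"),
                            scaling = c("uv", "center", "pareto", "none")) {
  structure(list(tic_normalize = isTRUE(tic_normalize),
                 log_transform = match.arg(log_transform),
                 scaling = match.arg(scaling)),
            class = "preprocess_spec")
}

#' Preprocess a feature table for OPLS-DA
#'
#' Applies, in order: per-sample TIC normalization (rows of all-zero
#' samples are left as zeros with a warning), the log transform, then
#' per-feature centering/scaling. Features with zero variance get scale 1
#' and are flagged in the `zero_variance` element.
#'
#' @param table a [feature_table].
#' @param spec a [preprocess_spec].
#' @param samples optional subset of sample ids to use (default: all).
#' @return list with `matrix` (samples x features), `feature_means`,
#'   `feature_scales`, `zero_variance` (logical per feature) and `spec`.
#' @export
preprocess <- function(table, spec = preprocess_spec(), samples = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "preprocess_spec"))
  M <- table$intensities
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(M))
    if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    M <- M[, samples, drop = FALSE]
  }
  if (nrow(M) == 0L || ncol(M) == 0L) stop("empty feature table")
  if (spec$tic_normalize) M <- tic_normalize_matrix(M)
  X <- t(M)  # samples x features
  X <- switch(spec$log_transform,
              log10 = log10(X + 1),
              log2 = log2(X + 1),
              none = X)
  mu <- rep(0, ncol(X))
  sc <- rep(1, ncol(X))
  zv <- rep(FALSE, ncol(X))
  if (spec$scaling != "none") {
    mu <- colMeans(X)
    X <- sweep(X, 2L, mu)
    if (spec$scaling %in% c("uv", "pareto")) {
      s <- col_sds(X)
      zv <- s == 0
      s[zv] <- 1
      sc <- if (spec$scaling == "uv") s else sqrt(s)
      X <- sweep(X, 2L, sc, "/")
    }
  }
  names(mu) <- names(sc) <- names(zv) <- colnames(X)
  list(matrix = X, feature_means = mu, feature_scales = sc,
       zero_variance = zv, spec = spec)
}
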