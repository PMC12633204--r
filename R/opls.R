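#' Fit a one-vs-rest OPLS-DA model
#'
#' Orthogonal projections to latent structures for a single binary response,
#' following the classical O-PLS recursion: each orthogonal round computes
#' the PLS weight w from the current (deflated) matrix, extracts the part of
#' the loading orthogonal to w, and deflates the matrix by the resulting
#' orthogonal component; one final predictive PLS component is then fitted
#' on the deflated matrix. With `n_ortho = 0` the model is exactly a
#' one-component PLS. Every orthogonal score is uncorrelated with the class
#' vector by construction.
#'
#' Sign convention: within each component the weight element of largest
#' magnitude is made positive, so output is deterministic across runs.
#'
#' @param X preprocessed numeric matrix, samples x features; columns are
#'   (re-)centered internally.
#' @param y class vector coded +1 (target category) / -1 (rest); both
#'   classes must be present.
#' @param n_ortho number of orthogonal components to remove (default 1).
#'   If the data become perfectly predictive earlier, extraction stops and
#'   `early_stop` is set.
#' @return Object of class `opls_model` with predictive weights `w` (unit
#'   norm), scores `t`, loadings `p`, y-loading `q`, list `ortho` of
#'   orthogonal components (`w_o`, `t_o`, `p_o`), `n_ortho_achieved`, and
#'   the class encoding.
#' @export
fit_opls <- function(X, y, n_ortho = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(-1, 1))) stop("y must be coded +1 / -1")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (n_ortho < 0L) stop("n_ortho must be >= 0")
  if (nrow(X) < n_ortho + 2L) stop("need at least n_ortho + 2 samples")
  # column-center (idempotent when the matrix was already preprocessed);
  # centering makes every score mean-zero, so orthogonal scores are
  # uncorrelated with the class vector even for unbalanced classes
  X <- sweep(X, 2L, colMeans(X))

  flip_to_positive <- function(w) if (w[which.max(abs(w))] < 0) -1 else 1

  Xd <- X
  ortho <- list()
  early_stop <- FALSE
  for (k in seq_len(n_ortho)) {
    w <- unit_norm(drop(crossprod(Xd, y)) / sum(y^2))
    t_pred <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
    w_o <- p - sum(w * p) * w
    if (sqrt(sum(w_o^2)) < 1e-12) {
      early_stop <- TRUE
      break
    }
    w_o <- unit_norm(w_o)
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    s <- flip_to_positive(w_o)
    ortho[[k]] <- list(w_o = s * w_o, t_o = s * t_o, p_o = s * p_o)
  }
  w <- unit_norm(drop(crossprod(Xd, y)) / sum(y^2))
  t_pred <- drop(Xd %*% w)
  tt <- sum(t_pred^2)
  if (tt < 1e-24) stop("degenerate model: predictive scores are all zero")
  p <- drop(crossprod(Xd, t_pred)) / tt
  q <- sum(y * t_pred) / tt
  s <- flip_to_positive(w)
  structure(list(w = s * w, t = s * t_pred, p = s * p, q = s * q,
                 ortho = ortho, n_ortho = as.integer(n_ortho),
                 n_ortho_achieved = length(ortho),
                 early_stop = early_stop,
                 class_encoding = c(positive = 1, negative = -1),
                 feature_names = colnames(X)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> %d features, 1 predictive + %d orthogonal component(s)%s\n",
              length(x$w), x$n_ortho_achieved,
              if (x$early_stop) " (early stop: perfectly predictive)" else ""))
  invisible(x)
}

#' Variable Importance in Projection (VIP) scores
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a ) with
#' SSY_a = q_a^2 t_a't_a, summed over the predictive component(s) only —
#' orthogonal variation is excluded, so the VIP threshold acts on the
#' between-class axis. The squared VIPs average to 1 over features.
#'
#' @param model a fitted [fit_opls] model.
#' @return named non-negative numeric vector aligned to the model features.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  tt <- sum(model$t^2)
  if (tt < 1e-24) stop("degenerate model: predictive scores are all zero")
  ssy <- model$q^2 * tt                       # single predictive component
  p_feat <- length(model$w)
  vip <- sqrt(p_feat * (model$w^2 / sum(model$w^2)) * ssy / ssy)
  names(vip) <- model$feature_names
  vip
}
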