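#' Construct an MS/MS spectrum
#'
#' A spectrum represents the fragmentation of one ion feature: a precursor
#' m/z and a peak list. One molecule can yield several ion features (adducts,
#' multimers, in-source fragments), so spectra are identified by ion feature,
#' not by compound.
#'
#' @param spectrum_id character scalar identifying the scan.
#' @param precursor_mz precursor mass-to-charge in Da, > 0.
#' @param peaks two-column numeric matrix (or coercible) of fragment m/z in
#'   Da and non-negative intensity. Peaks are stored sorted by ascending m/z.
#' @param retention_time retention time in seconds, or `NA` if unknown.
#' @param source_file optional path the spectrum was read from.
#' @param feature_id optional link into a feature table.
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(spectrum_id, precursor_mz, peaks,
                        retention_time = NA_real_,
                        source_file = NA_character_,
                        feature_id = NA_character_) {
  if (!is.character(spectrum_id) || length(spectrum_id) != 1L || !nzchar(spectrum_id))
    stop("spectrum_id must be a non-empty character scalar")
  if (!is_scalar_number(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number")
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L || nrow(peaks) < 1L || !is.numeric(peaks))
    stop("peaks must be a numeric matrix with columns (mz, intensity) and >= 1 row")
  if (anyNA(peaks)) stop("peaks must not contain NA")
  if (any(peaks[, 2L] < 0)) stop("peak intensities must be non-negative")
  if (any(peaks[, 1L] <= 0)) stop("fragment m/z must be positive")
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  dimnames(peaks) <- list(NULL, c("mz", "intensity"))
  if (!is.na(retention_time) && retention_time < 0)
    stop("retention_time must be >= 0 seconds")
  structure(
    list(spectrum_id = spectrum_id,
         precursor_mz = as.numeric(precursor_mz),
         retention_time = as.numeric(retention_time),
         peaks = peaks,
         source_file = as.character(source_file),
         feature_id = as.character(feature_id)),
    class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum %s> precursor %.4f Da, %d peaks",
              x$spectrum_id, x$precursor_mz, nrow(x$peaks)))
  if (!is.na(x$retention_time)) cat(sprintf(", RT %.1f s", x$retention_time))
  if (!is.na(x$feature_id)) cat(sprintf(", feature %s", x$feature_id))
  cat("\n")
  invisible(x)
}

n_peaks <- function(x) nrow(x$peaks)
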