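`%||%` <- function(x, y) if (is.null(x)) y else x

# delimiter auto-detection among tab/comma on the first line
detect_delim <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(first) && grepl("\t", first)) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.table(path, sep = detect_delim(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "", fileEncoding = "UTF-8")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

unit_norm <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector")
  v / nv
}

# column sd without apply() overhead
col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  sqrt(colSums(sweep(X, 2L, mu)^2) / (n - 1L))
}
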