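# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop_config("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  invisible(df)
}

# Deterministic string hash mapped to (0, 1).  Two Lehmer-style mixing
# rounds over a base-31 polynomial hash; all arithmetic stays below 2^53
# so the result is exact in double precision and platform independent.
hash_unit <- function(x) {
  m <- 2147483647 # 2^31 - 1
  vapply(x, function(s) {
    h <- 7
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
    h <- (h * 48271) %% m
    h <- (h * 16807) %% m
    (h + 0.5) / m
  }, numeric(1))
}

# Moore-Penrose pseudoinverse via SVD; used when a log-rank covariance
# matrix is singular (e.g. duplicated groups).
pseudo_inverse <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 1e-300)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# TSV I/O with fixed conventions (no quoting surprises, NA = "")
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop_config("input file does not exist: %s", path)
  utils::read.delim(path, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

split_ids <- function(x) strsplit(ifelse(is.na(x) | x == "", NA, x), ",")
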