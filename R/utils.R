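# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a component seed from a master seed
#'
#' One master seed drives a deterministic per-component stream: component
#' `k` runs under `seed * 1009 + k`, kept inside the 32-bit integer range
#' R's RNG accepts. Used by the simulator, the consensus resampler and the
#' pipeline so sub-results are independently reproducible.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer component/stream index.
#' @return an integer seed.
#' @keywords internal
m6a_seed <- function(seed, offset = 0L) {
  s <- (as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483647
  as.integer(s)
}

#' Significance stars at the conventional thresholds
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' relabeling), ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels over the same items.
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Polynomial rolling hash of a character scalar; stable across sessions,
# used for config hashes in run reports (no cryptographic intent).
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Write a data.frame as tab-delimited UTF-8 with header, no quoting.
.write_tsv <- function(df, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                rownames_col),
                as.data.frame(df, stringsAsFactors = FALSE))
    rownames(df) <- NULL
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
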