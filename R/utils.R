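#' @keywords internal
"_PACKAGE"

# Population SD (divisor n). Fixed convention for bit-reproducible filter
# thresholds; R's sd() uses n - 1.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Deterministic 32-bit sub-stream seed derived from a master seed and a
# stage name, so each pipeline stage draws from its own stream.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(name)
  h <- 0
  for (i in seq_along(codes)) h <- (h * 131 + codes[i]) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single finite value in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok)
    stop(sprintf("'%s' must be a single finite %s value", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}

#' Write a data frame as tab-separated text
#'
#' Plain TSV writer used for all tabular stage outputs (shot tables, filter
#' decisions, per-bin metrics, distance matrices).
#'
#' @param x data frame.
#' @param path output file path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_table()]
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
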