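# Internal helpers shared across modules.

#' Derive a stream-specific seed from a master seed
#'
#' One master seed fans out to the independent random streams of a run
#' (simulation, weight initialization, minibatch shuffling, graph
#' construction, region sampling).  Derived seeds stay within the 32-bit
#' integer range.
#'
#' @param seed master seed (single integer).
#' @param stream character tag naming the consumer.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # cheap string hash, stable across platforms
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

#' Run an expression with a temporarily-set RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# consistent argument checking with informative messages
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# write a data.frame as TSV without quoting/rownames (the package's
# canonical plain-text output format)
write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}
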