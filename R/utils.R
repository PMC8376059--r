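# Internal helpers: seed streams, error classes, TSV I/O.

#' Derive a deterministic sub-seed for a named random stream
#'
#' All stochastic operations in the package draw from streams derived from a
#' single user-supplied integer seed, keyed by the operation name, so that
#' adding randomness to one stage never perturbs another stage's draws.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(stream)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629)
}

# Evaluate `expr` under a named stream of `seed`, restoring the caller's RNG.
with_stream <- function(seed, stream, expr) {
  withr::with_seed(stream_seed(seed, stream), expr)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("ydegen_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ydegen_config_error", "error")))
}

read_tsv_cols <- function(path, required) {
  if (!file.exists(path)) stop_data("input file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_data("file ", path, " lacks required column(s): ",
              paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
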