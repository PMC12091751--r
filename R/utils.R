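#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Write a data frame as plain TSV
#'
#' Tab-separated, no quoting, no row names; the on-disk layout used for every
#' tabular artefact the pipeline emits.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

# Derive a child RNG seed from a master seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is_count_scalar(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((seed * 1009 + h * 9176) %% 2147483647L)
}
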