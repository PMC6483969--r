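#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed and a stage tag
#'
#' A single master seed is fanned out to per-stage (or per-k) seeds by a fixed
#' integer hash of the tag, so that stages are individually reproducible and
#' never share an RNG stream.
#'
#' @param master integer master seed.
#' @param tag character scalar naming the consumer (e.g. `"null_k12"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(master) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483646 + 1)
}

stop_arg <- function(...) stop(..., call. = FALSE)

# Write a data.frame as TSV without quoting or row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
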