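#' Canonicalize gene symbols
#'
#' Uppercases and strips surrounding whitespace so that symbols from
#' resources with mixed conventions (matrisome tables, TF lists, STRING
#' exports) join reliably.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @examples
#' canonicalizeSymbols(c(" col2a1", "Acan\t"))
#' @export
canonicalizeSymbols <- function(x) {
  toupper(trimws(as.character(x)))
}

## Deterministic child seed for permutation r of a run seeded with `seed`.
## Kept below 2^31 so it is always a valid R integer seed.
childSeed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 1e6) * 1999 + 7919 * as.numeric(r)) %% .Machine$integer.max
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))

## strict numeric column coercion: reject rather than silently NA-coerce
numericColumn <- function(x, col, file = "input") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(as.character(x)) != "NA")
  if (length(bad) > 0L) {
    stopf("%s: column '%s' contains non-numeric value '%s' (row %d)",
          file, col, as.character(x[bad[1L]]), bad[1L])
  }
  out
}
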