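# internal helpers shared across modules

# geometric mean; x must be strictly positive
geomean <- function(x) exp(mean(log(x)))

#' Assign stability ranks with documented tie-breaking
#'
#' Ranks ascending by `primary` (lower = more stable). Ties are broken by
#' `secondary` (if given) and finally by gene symbol in C-locale
#' lexicographic order, so rankings are reproducible across platforms.
#'
#' @param primary numeric statistic, lower is better.
#' @param genes character gene symbols, same length as `primary`.
#' @param secondary optional numeric tie-break statistic, lower is better.
#' @return integer vector of ranks, a permutation of `1:length(primary)`.
#' @export
rank_stability <- function(primary, genes, secondary = NULL) {
  stopifnot(length(primary) == length(genes))
  if (is.null(secondary)) {
    ord <- order(primary, genes, method = "radix")
  } else {
    stopifnot(length(secondary) == length(primary))
    ord <- order(primary, secondary, genes, method = "radix")
  }
  r <- integer(length(primary))
  r[ord] <- seq_along(ord)
  r
}

# stop() with a consistent prefix, no call noise
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
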