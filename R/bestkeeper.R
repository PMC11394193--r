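#' BestKeeper descriptive stability on raw Cq
#'
#' Unlike geNorm and NormFinder, BestKeeper works on the raw Cq scale:
#' per gene it reports the arithmetic mean Cq, a dispersion (sample SD by
#' default, or the mean absolute deviation from the mean as in the
#' original BestKeeper spreadsheet), `CV = 100 * dispersion / mean`, and
#' the Pearson correlation of the gene's Cq with the BestKeeper index —
#' the per-sample geometric mean Cq over all candidate genes. Ranks are
#' ascending by dispersion, ties broken by CV and then gene symbol; the
#' correlation is reported but not part of the ranking key.
#'
#' @param x a collapsed, complete [cq_table()] with >= 2 samples.
#' @param dispersion `"sd"` (default) or `"mad"` (mean absolute deviation).
#' @return object of class `bestkeeper_result`: list with `gene`,
#'   `mean_cq`, `sd` (the chosen dispersion), `cv_pct`, `r` (vs index),
#'   `index` (per-sample), `statistic` (= `sd`), `rank`,
#'   `method = "bestkeeper"`.
#' @export
bestkeeper <- function(x, dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  stopifnot(inherits(x, "cq_table"))
  .require_collapsed(x, "bestkeeper()")
  if (anyNA(x$values)) abort("missing Cq entries are not allowed")
  v <- x$values
  if (ncol(v) < 2) abort("need >= 2 samples")
  mean_cq <- rowMeans(v)
  disp <- switch(dispersion,
                 sd = apply(v, 1, stats::sd),
                 mad = rowMeans(abs(v - mean_cq)))
  cv <- 100 * disp / mean_cq
  index <- apply(v, 2, geomean)
  r <- suppressWarnings(apply(v, 1, function(row) stats::cor(row, index)))
  structure(list(gene = rownames(v), mean_cq = unname(mean_cq),
                 sd = unname(disp), cv_pct = unname(cv), r = unname(r),
                 index = index, dispersion = dispersion,
                 statistic = unname(disp),
                 rank = rank_stability(disp, rownames(v), secondary = cv),
                 method = "bestkeeper"),
            class = c("bestkeeper_result", "stability_result"))
}

#' Comparative delta-Ct stability
#'
#' For every gene j, the mean over all partner genes k of the SD over
#' samples of the pairwise difference `Cq_j - Cq_k`. A gene that keeps a
#' constant offset to every other gene scores 0. Same algebra as the
#' geNorm M value but applied to raw, un-anchored Cq differences.
#'
#' @param x a collapsed, complete [cq_table()] with >= 3 genes.
#' @return object of class `deltact_result`: list with `gene`, `statistic`
#'   (mean pairwise SD), `rank`, `method = "delta_ct"`.
#' @export
delta_ct_method <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  .require_collapsed(x, "delta_ct_method()")
  if (anyNA(x$values)) abort("missing Cq entries are not allowed")
  v <- x$values
  if (nrow(v) < 3) abort("need >= 3 genes")
  cv <- stats::cov(t(v))
  sd2 <- outer(diag(cv), diag(cv), "+") - 2 * cv
  sd2[sd2 < 0] <- 0
  pair_sd <- sqrt(sd2)
  diag(pair_sd) <- 0
  stat <- rowSums(pair_sd) / (nrow(v) - 1)
  structure(list(gene = rownames(v), statistic = unname(stat),
                 rank = rank_stability(stat, rownames(v)),
                 method = "delta_ct"),
            class = c("deltact_result", "stability_result"))
}
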