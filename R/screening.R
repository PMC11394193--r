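#' Per-gene coefficient of variation of an expression matrix
#'
#' CV = 100 * SD / mean per gene, SD with the n-1 denominator. Genes whose
#' mean is not strictly positive have no defined CV and are reported as
#' excluded with a reason instead of propagating NaN.
#'
#' @param x an [expression_matrix()] or numeric genes x samples matrix.
#' @return data.frame with `gene`, `mean_fpkm`, `cv_pct` (NA when
#'   undefined) and `excluded_reason` (NA when defined).
#' @export
gene_cv <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2) abort("need a matrix with >= 2 samples")
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  cv <- ifelse(m > 0, 100 * s / m, NA_real_)
  data.frame(gene = rownames(x), mean_fpkm = m, cv_pct = cv,
             excluded_reason = ifelse(m > 0, NA_character_,
                                      "non-positive mean expression"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen candidate reference genes from an RNA-seq matrix
#'
#' A gene passes when its aggregated FPKM strictly exceeds `fpkm_min` and
#' its CV is strictly below `cv_max`; passers are ranked ascending by CV
#' (ties by gene symbol) and the top `top_k` returned. If fewer than
#' `top_k` genes pass, all passers are returned with a warning.
#'
#' @param x an [expression_matrix()].
#' @param fpkm_min expression threshold (strict `>`), FPKM units.
#' @param cv_max variability threshold (strict `<`), percent.
#' @param top_k maximum number of candidates.
#' @param fpkm_agg aggregation across samples for the expression criterion;
#'   `"mean"` (default, the conventional reading), `"min"` or `"median"`.
#' @return object of class `screening_result`: list with `stats` (per-gene
#'   table including pass/fail per criterion) and `candidates` (data.frame
#'   `gene`, `mean_fpkm`, `cv_pct`, `rank`, ascending CV).
#' @export
screen_candidates <- function(x, fpkm_min = 100, cv_max = 10, top_k = 8,
                              fpkm_agg = c("mean", "min", "median")) {
  fpkm_agg <- match.arg(fpkm_agg)
  if (fpkm_min <= 0 || cv_max <= 0 || top_k <= 0)
    abort("thresholds must be strictly positive")
  stats_df <- gene_cv(x)
  agg <- switch(fpkm_agg,
                mean = rowMeans(x),
                min = apply(x, 1, min),
                median = apply(x, 1, stats::median))
  stats_df$agg_fpkm <- agg
  stats_df$pass_fpkm <- agg > fpkm_min
  stats_df$pass_cv <- !is.na(stats_df$cv_pct) & stats_df$cv_pct < cv_max
  pass <- stats_df[stats_df$pass_fpkm & stats_df$pass_cv, , drop = FALSE]
  ord <- order(pass$cv_pct, pass$gene, method = "radix")
  pass <- pass[ord, , drop = FALSE]
  if (nrow(pass) < top_k)
    warning("only ", nrow(pass), " gene(s) pass screening (top_k = ",
            top_k, ")", call. = FALSE)
  cand <- utils::head(pass, top_k)
  candidates <- data.frame(gene = cand$gene, mean_fpkm = cand$mean_fpkm,
                           cv_pct = cand$cv_pct,
                           rank = seq_len(nrow(cand)),
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(stats = stats_df, candidates = candidates,
                 fpkm_min = fpkm_min, cv_max = cv_max, top_k = top_k,
                 fpkm_agg = fpkm_agg),
            class = "screening_result")
}
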