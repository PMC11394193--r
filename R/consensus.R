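#' Geometric mean of per-method stability ranks
#'
#' The comprehensive "mean rank" of a gene is the geometric mean of its
#' ranks across methods: `(prod ranks)^(1/m)`. With m methods all ranking
#' a gene r-th the mean rank is exactly r.
#'
#' @param ranks numeric matrix (genes x methods) of ranks (>= 1), rownames
#'   = gene symbols and colnames = method names; or a numeric vector of
#'   one gene's ranks.
#' @return named numeric vector of geometric-mean ranks, full precision
#'   (round to 2 decimals for reporting).
#' @export
geometric_mean_rank <- function(ranks) {
  if (is.vector(ranks)) ranks <- matrix(ranks, nrow = 1)
  if (anyNA(ranks)) {
    bad <- which(is.na(ranks), arr.ind = TRUE)[1, ]
    abort("gene '", rownames(ranks)[bad[1]] %||% bad[1],
          "' has no rank from method '",
          colnames(ranks)[bad[2]] %||% bad[2], "'")
  }
  if (any(ranks < 1)) abort("ranks must be >= 1")
  stats::setNames(apply(ranks, 1, geomean), rownames(ranks))
}

#' Comprehensive consensus ranking across stability methods
#'
#' Aggregates two or more per-method rankings (geNorm, NormFinder,
#' BestKeeper, comparative delta-Ct, ...) by the geometric mean of ranks;
#' the final comprehensive rank is the ascending order of the mean rank,
#' ties broken by the gene's best single-method rank and then by gene
#' symbol. Aggregation is symmetric in method order.
#'
#' @param results list of `stability_result` objects (or a matrix of
#'   ranks, genes x methods) over an identical gene set.
#' @return object of class `consensus_result`: data.frame with `gene`,
#'   one `rank_<method>` column per method, `mean_rank` (full precision),
#'   `mean_rank_2dp`, `comprehensive_rank`; ordered by comprehensive
#'   rank. The method set is attached as attribute `methods`.
#' @export
comprehensive_ranking <- function(results) {
  if (is.matrix(results)) {
    rank_mat <- results
  } else {
    if (!is.list(results) || length(results) < 2)
      abort("need >= 2 stability methods to aggregate")
    genes <- results[[1]]$gene
    methods <- vapply(results, function(r) r$method %||% "unknown",
                      character(1))
    if (anyDuplicated(methods))
      methods <- make.unique(methods, sep = "_")
    rank_mat <- matrix(NA_real_, length(genes), length(results),
                       dimnames = list(genes, methods))
    for (i in seq_along(results)) {
      r <- results[[i]]
      if (!setequal(r$gene, genes))
        abort("method '", methods[i], "' ranks a different gene set")
      rank_mat[, i] <- r$rank[match(genes, r$gene)]
    }
  }
  if (ncol(rank_mat) < 2) abort("need >= 2 stability methods to aggregate")
  gm <- geometric_mean_rank(rank_mat)
  best <- apply(rank_mat, 1, min)
  comp <- rank_stability(gm, rownames(rank_mat), secondary = best)
  out <- data.frame(gene = rownames(rank_mat), rank_mat,
                    mean_rank = unname(gm),
                    mean_rank_2dp = round(unname(gm), 2),
                    comprehensive_rank = comp,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  names(out)[1 + seq_len(ncol(rank_mat))] <- paste0("rank_",
                                                    colnames(rank_mat))
  out <- out[order(out$comprehensive_rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, methods = colnames(rank_mat),
            class = c("consensus_result", "data.frame"))
}

#' Compare target-gene fold changes across groups per normalizer
#'
#' For each fold-change table (one per normalizer choice), computes
#' per-group mean fold change with standard error, a one-way ANOVA across
#' groups, and pairwise group comparisons via Tukey's HSD with
#' significance labels at 0.05 ("*") and 0.01 ("**"), "ns" otherwise.
#' This is how an unstable normalizer reveals itself: a real group
#' difference in the target is attenuated or distorted when the
#' normalizer itself shifts between groups.
#'
#' @param fold_tables a single [ddct_fold_change()] result or a list of
#'   them, optionally named by normalizer.
#' @return list of `group_comparison` objects (one per table): list with
#'   `normalizer`, `target`, `groups` (data.frame `group`, `n`,
#'   `mean_fold`, `sem`), `anova` (`f`, `p`, `df`), `pairwise`
#'   (data.frame `comparison`, `diff`, `p_adj`, `label`).
#' @export
compare_normalizations <- function(fold_tables) {
  if (inherits(fold_tables, "fold_change_table"))
    fold_tables <- list(fold_tables)
  out <- lapply(fold_tables, function(ft) {
    stopifnot(inherits(ft, "fold_change_table"))
    df <- ft$data
    tab <- table(df$group)
    if (length(tab) < 2) abort("need >= 2 groups")
    if (any(tab < 2)) abort("every group needs >= 2 biological replicates")
    df$group <- factor(df$group)
    agg <- do.call(rbind, lapply(split(df$fold, df$group), function(v)
      data.frame(n = length(v), mean_fold = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)))))
    agg <- data.frame(group = rownames(agg), agg, row.names = NULL,
                      stringsAsFactors = FALSE)
    fit <- stats::aov(fold ~ group, data = df)
    an <- summary(fit)[[1]]
    f <- an[1, "F value"]
    p <- an[1, "Pr(>F)"]
    tuk <- stats::TukeyHSD(fit)$group
    label <- ifelse(tuk[, "p adj"] < 0.01, "**",
                    ifelse(tuk[, "p adj"] < 0.05, "*", "ns"))
    pairwise <- data.frame(comparison = rownames(tuk),
                           diff = tuk[, "diff"], p_adj = tuk[, "p adj"],
                           label = label, row.names = NULL,
                           stringsAsFactors = FALSE)
    structure(list(normalizer = paste(ft$refs, collapse = "+"),
                   target = ft$target, groups = agg,
                   anova = list(f = f, p = p,
                                df = unname(an[, "Df"])),
                   pairwise = pairwise),
              class = "group_comparison")
  })
  names(out) <- names(fold_tables) %||%
    vapply(out, function(x) x$normalizer, character(1))
  out
}
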