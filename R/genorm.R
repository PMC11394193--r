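#' Pairwise-variation matrix of a quantity panel
#'
#' For each gene pair (j, k), `A_jk(s) = log2(Q_j(s) / Q_k(s))` and
#' `V_jk = SD over samples of A_jk` (n-1 denominator). The matrix is
#' symmetric with zero diagonal; `V_jk = 0` means the two genes are
#' perfectly co-regulated (constant ratio).
#'
#' @param q a [relative_quantity()] result or positive Q matrix
#'   (genes x samples).
#' @param log_base ratio log base, default 2.
#' @return symmetric numeric matrix (genes x genes).
#' @export
pairwise_variation_matrix <- function(q, log_base = 2) {
  qm <- .as_q(q)
  if (nrow(qm) < 2 || ncol(qm) < 2) abort("need >= 2 genes and >= 2 samples")
  a <- log(qm, base = log_base)
  # V_jk = sd(a_j - a_k); expand via the sample covariance matrix
  cv <- stats::cov(t(a))
  v2 <- outer(diag(cv), diag(cv), "+") - 2 * cv
  v2[v2 < 0] <- 0  # guard tiny negative round-off
  v <- sqrt(v2)
  diag(v) <- 0
  dimnames(v) <- list(rownames(qm), rownames(qm))
  v
}

#' geNorm M values
#'
#' The expression-stability measure `M_j` is the arithmetic mean of gene
#' j's pairwise variations `V_jk` with all other genes; lower M = more
#' stable.
#'
#' @inheritParams pairwise_variation_matrix
#' @return named numeric vector of M values.
#' @export
m_values <- function(q, log_base = 2) {
  qm <- .as_q(q)
  if (nrow(qm) < 2) abort("M values need >= 2 genes")
  v <- pairwise_variation_matrix(qm, log_base)
  rowSums(v) / (nrow(v) - 1)
}

#' geNorm stepwise-exclusion ranking
#'
#' Iteratively computes M on the surviving gene set and removes the gene
#' with the largest M (ties broken by taking the lexicographically first
#' tied symbol, recorded in the trace) until two genes remain. The removed
#' gene at each step receives rank = current set size. geNorm cannot
#' separate the final pair (their M values coincide on a two-gene set), so
#' ranks 1 and 2 are assigned by the pair's full-panel M values, ties by
#' gene symbol.
#'
#' @inheritParams pairwise_variation_matrix
#' @return object of class `genorm_result`: list with `gene`, `m`
#'   (full-panel M), `rank`, `statistic` (= `m`), `method = "genorm"` and
#'   `trace` (data.frame per step: `step`, `removed`, `m_removed`,
#'   `mean_m`, `tie`).
#' @export
genorm_ranking <- function(q, log_base = 2) {
  qm <- .as_q(q)
  k <- nrow(qm)
  if (k < 3) abort("stepwise ranking needs >= 3 genes")
  full_m <- m_values(qm, log_base)
  current <- rownames(qm)
  rank <- stats::setNames(integer(k), rownames(qm))
  trace <- list()
  step <- 0L
  while (length(current) > 2) {
    step <- step + 1L
    m <- m_values(qm[current, , drop = FALSE], log_base)
    worst <- max(m)
    tied <- sort(names(m)[m == worst])
    out <- tied[1]
    rank[out] <- length(current)
    trace[[step]] <- data.frame(step = step, removed = out,
                                m_removed = unname(m[out]),
                                mean_m = mean(m),
                                tie = length(tied) > 1,
                                stringsAsFactors = FALSE)
    current <- setdiff(current, out)
  }
  # final pair: ordered by full-panel M, ties lexicographic
  pair <- current[order(full_m[current], current, method = "radix")]
  rank[pair] <- c(1L, 2L)
  structure(list(gene = rownames(qm), m = unname(full_m[rownames(qm)]),
                 statistic = unname(full_m[rownames(qm)]),
                 rank = unname(rank[rownames(qm)]),
                 method = "genorm",
                 trace = do.call(rbind, trace)),
            class = c("genorm_result", "stability_result"))
}

#' geNorm pairwise-variation curve V(n/n+1)
#'
#' `NF_n(s)` is the per-sample geometric mean of Q over the n most stable
#' genes (by the stepwise ranking); `V_{n/n+1}` is the SD over samples of
#' `log2(NF_n / NF_{n+1})`. The optimal number of reference genes is the
#' smallest n with `V_{n/n+1} < threshold` (default 0.15, strict); when no
#' n qualifies, all k genes are recommended with a warning.
#'
#' @inheritParams pairwise_variation_matrix
#' @param ranking a [genorm_ranking()] result for the same panel; computed
#'   if omitted.
#' @param threshold V cutoff, default 0.15.
#' @return list with `v` (data.frame `n`, `v`, `below_threshold`),
#'   `optimal_n`, `threshold`.
#' @export
v_curve <- function(q, ranking = NULL, threshold = 0.15, log_base = 2) {
  qm <- .as_q(q)
  k <- nrow(qm)
  if (k < 3) abort("the V curve needs >= 3 genes")
  ranking <- ranking %||% genorm_ranking(qm, log_base)
  ord <- ranking$gene[order(ranking$rank)]
  if (!setequal(ord, rownames(qm)))
    abort("ranking does not match the panel's genes")
  a <- log(qm[ord, , drop = FALSE], base = log_base)
  # log NF_n per sample = mean of the top-n genes' log quantities
  ns <- 2:(k - 1)
  v <- vapply(ns, function(n) {
    stats::sd(colMeans(a[seq_len(n), , drop = FALSE]) -
              colMeans(a[seq_len(n + 1), , drop = FALSE]))
  }, numeric(1))
  below <- v < threshold
  if (any(below)) {
    optimal_n <- ns[which(below)[1]]
  } else {
    warning("no V(n/n+1) below ", threshold, "; recommending all ", k,
            " genes", call. = FALSE)
    optimal_n <- k
  }
  list(v = data.frame(n = ns, v = v, below_threshold = below),
       optimal_n = optimal_n, threshold = threshold)
}

#' Full geNorm analysis
#'
#' Convenience wrapper running [genorm_ranking()] and [v_curve()].
#'
#' @inheritParams v_curve
#' @return `genorm_result` with the `v_curve` output attached as `$v`.
#' @export
genorm <- function(q, threshold = 0.15, log_base = 2) {
  res <- genorm_ranking(q, log_base)
  res$v <- v_curve(q, ranking = res, threshold = threshold,
                   log_base = log_base)
  res
}
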