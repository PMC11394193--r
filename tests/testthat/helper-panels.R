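# shared fixture builders and independent brute-force oracles

# collapsed cq_table from a plain matrix; bio_rep numbered within group
make_cq <- function(values, groups = rep("A", ncol(values)),
                    genes = NULL) {
  if (!is.null(genes)) rownames(values) <- genes
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  bio <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  meta <- data.frame(sample_id = paste0(groups, "_", bio),
                     group = groups, bio_rep = bio, tech_rep = 1L,
                     stringsAsFactors = FALSE)
  colnames(values) <- meta$sample_id
  cq_table(values, meta)
}

# random positive Q-scale panel (genes x samples)
random_q_panel <- function(k, n, seed) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(k * n, sd = runif(1, 0.2, 1.5)), k, n)
  })
  q <- 2^(a - apply(a, 1, max))  # anchor max at 1 like relative_quantity
  rownames(q) <- sprintf("g%02d", seq_len(k))
  colnames(q) <- sprintf("s%02d", seq_len(n))
  q
}

# random plausible Cq panel (genes x samples)
random_cq_panel <- function(k, n, seed) {
  withr::with_seed(seed, {
    v <- matrix(runif(k, 15, 25) + rnorm(k * n, sd = 0.5), k, n)
  })
  make_cq(v)
}

# ---- brute-force oracles (independent of the package's code paths) ----

# pairwise variation: explicit double loop over gene pairs
oracle_pairwise_v <- function(qm) {
  k <- nrow(qm)
  v <- matrix(0, k, k, dimnames = list(rownames(qm), rownames(qm)))
  for (j in seq_len(k)) for (l in seq_len(k)) {
    if (j == l) next
    v[j, l] <- stats::sd(log2(qm[j, ] / qm[l, ]))
  }
  v
}

oracle_m <- function(qm) {
  v <- oracle_pairwise_v(qm)
  sapply(seq_len(nrow(qm)), function(j) mean(v[j, -j]))
}

# V(n/n+1) from scratch: explicit geometric-mean normalization factors
oracle_v_curve <- function(qm, gene_order) {
  qo <- qm[gene_order, , drop = FALSE]
  k <- nrow(qo)
  nf <- function(n) apply(qo[seq_len(n), , drop = FALSE], 2,
                          function(col) prod(col)^(1 / n))
  sapply(2:(k - 1), function(n) stats::sd(log2(nf(n) / nf(n + 1))))
}

# comparative delta-Ct: double loop over partner genes
oracle_delta_ct <- function(v) {
  k <- nrow(v)
  sapply(seq_len(k), function(j)
    mean(sapply(setdiff(seq_len(k), j), function(l)
      stats::sd(v[j, ] - v[l, ]))))
}
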