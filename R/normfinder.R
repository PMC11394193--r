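#' NormFinder-style model-based stability
#'
#' Decomposes the variation of log2 quantities into intragroup variance
#' and intergroup differences, per gene, and combines both into a single
#' stability value (lower = more stable).
#'
#' With `y_igj` = log2 Q of gene i, group g, sample j:
#' \enumerate{
#'   \item sample-center: `z_igj = y_igj - mean_i y_igj`, which removes
#'     sample-loading effects exactly;
#'   \item `s2_ig` = sample variance of `z_igj` over j. Centering biases
#'     these: `E[s2_ig] = sigma2_ig (1 - 2/k) + sigma2bar_g / k` for k
#'     genes, so the group-average level is recovered as
#'     `sigma2bar_g = (k/(k-1)) * mean_i s2_ig` and the per-gene variance
#'     as `sigma2_ig = max(0, (s2_ig - sigma2bar_g/k) / (1 - 2/k))`;
#'   \item group differences `d_ig = zbar_ig - mean_g zbar_ig` (summing to
#'     0 over groups per gene);
#'   \item intergroup variance (moment estimator)
#'     `gamma2_i = max(0, sum_g d_ig^2/(G-1) - mean_g sigma2_ig/n_g)`;
#'   \item shrunken differences
#'     `dtilde_ig = d_ig * gamma2_i / (gamma2_i + sigma2_ig/n_g)`;
#'   \item stability `rho_i = mean_g [ |dtilde_ig| +
#'     sqrt(gamma2_i (sigma2_ig/n_g) / (gamma2_i + sigma2_ig/n_g)) ]`
#'     (both terms 0 when the denominator is 0).
#' }
#' Variance estimates are clamped at zero and never surface negative.
#'
#' @param q a [relative_quantity()] result or positive Q matrix
#'   (genes x samples); needs >= 3 genes.
#' @param groups group label per sample; taken from the `rel_quant`
#'   metadata when omitted. With fewer than 2 groups the function falls
#'   back to [normfinder_ungrouped()] with a warning.
#' @param log_base log base for the quantity scale, default 2.
#' @return object of class `normfinder_result`: list with `gene`,
#'   `statistic` (rho), `rank`, `method = "normfinder"`, and per-group
#'   matrices `sigma2` (intragroup variances), `d` and `d_shrunk`
#'   (intergroup differences), plus `gamma2` per gene.
#' @export
normfinder_stability <- function(q, groups = NULL, log_base = 2) {
  qm <- .as_q(q)
  k <- nrow(qm)
  if (k <= 2) abort("the variance decomposition needs >= 3 genes")
  groups <- .q_groups(q, groups)
  if (length(groups) != ncol(qm))
    abort("`groups` must have one label per sample")
  glev <- unique(groups)
  if (length(glev) < 2) {
    warning("fewer than 2 groups; falling back to ungrouped mode",
            call. = FALSE)
    return(normfinder_ungrouped(q, log_base = log_base))
  }
  ng <- table(factor(groups, levels = glev))
  if (any(ng < 2)) abort("every group needs >= 2 samples")
  y <- log(qm, base = log_base)
  z <- sweep(y, 2, colMeans(y))                     # sample-centering
  G <- length(glev)
  s2 <- matrix(NA_real_, k, G, dimnames = list(rownames(qm), glev))
  zbar <- s2
  for (g in glev) {
    zg <- z[, groups == g, drop = FALSE]
    zbar[, g] <- rowMeans(zg)
    s2[, g] <- apply(zg, 1, stats::var)
  }
  sigma2bar <- (k / (k - 1)) * colMeans(s2)
  # pmax(x, 0) keeps x's dim; pmax(0, x) would drop it
  sigma2 <- pmax(sweep(s2, 2, sigma2bar / k) / (1 - 2 / k), 0)
  d <- zbar - rowMeans(zbar)
  n_g <- as.numeric(ng)[match(glev, names(ng))]
  sig_over_n <- sweep(sigma2, 2, n_g, "/")
  gamma2 <- pmax(0, rowSums(d^2) / (G - 1) - rowMeans(sig_over_n))
  denom <- gamma2 + sig_over_n                      # recycles gamma2 by row
  shrink <- ifelse(denom > 0, gamma2 / denom, 0)
  d_shrunk <- d * shrink
  var_term <- ifelse(denom > 0, gamma2 * sig_over_n / denom, 0)
  rho <- rowMeans(abs(d_shrunk) + sqrt(var_term))
  structure(list(gene = rownames(qm), statistic = unname(rho),
                 rank = rank_stability(rho, rownames(qm)),
                 method = "normfinder",
                 sigma2 = sigma2, d = d, d_shrunk = d_shrunk,
                 gamma2 = stats::setNames(gamma2, rownames(qm)),
                 groups = glev, n_g = stats::setNames(n_g, glev)),
            class = c("normfinder_result", "stability_result"))
}

#' NormFinder stability without group structure
#'
#' All samples are treated as one group: the same sample-centering and
#' variance deconvolution as [normfinder_stability()] with G = 1, and the
#' stability value is the pooled intragroup SD `sqrt(sigma2_i)`.
#'
#' @inheritParams normfinder_stability
#' @return `normfinder_result` with `method = "normfinder"`, `statistic` =
#'   per-gene SD estimate, `gamma2` all zero.
#' @export
normfinder_ungrouped <- function(q, log_base = 2) {
  qm <- .as_q(q)
  k <- nrow(qm)
  if (k <= 2) abort("the variance decomposition needs >= 3 genes")
  y <- log(qm, base = log_base)
  z <- sweep(y, 2, colMeans(y))
  s2 <- apply(z, 1, stats::var)
  sigma2bar <- (k / (k - 1)) * mean(s2)
  sigma2 <- pmax((s2 - sigma2bar / k) / (1 - 2 / k), 0)
  rho <- sqrt(sigma2)
  structure(list(gene = rownames(qm), statistic = unname(rho),
                 rank = rank_stability(rho, rownames(qm)),
                 method = "normfinder",
                 sigma2 = matrix(sigma2, ncol = 1,
                                 dimnames = list(rownames(qm), "all")),
                 d = NULL, d_shrunk = NULL,
                 gamma2 = stats::setNames(rep(0, k), rownames(qm)),
                 groups = "all",
                 n_g = c(all = ncol(qm))),
            class = c("normfinder_result", "stability_result"))
}
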