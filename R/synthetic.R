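#' Ground truth for a simulated Cq panel
#'
#' Describes the generative model behind [simulate_cq_panel()]:
#' `Cq[g, well] = base[g] + group_effect[g, group(well)] + loading[well] + eps`,
#' with `eps ~ N(0, noise_sd^2)` per well and gene, and
#' `loading[well] ~ N(0, loading_sd^2)` shared by every gene in the well —
#' exactly the sample-loading variation reference-gene normalization is
#' meant to remove. A gene labelled stable must have all group effects 0.
#'
#' @param base named numeric vector of baseline Cq per gene (cycles).
#' @param group_effects numeric matrix (genes x groups) of additive Cq
#'   shifts; rownames must match `names(base)`, colnames are group labels.
#' @param loading_sd SD of the per-well loading effect, cycles (>= 0).
#' @param noise_sd SD of the per-well measurement noise, cycles (>= 0).
#'   Default 0.15, a typical qPCR technical noise level.
#' @param stable character vector of gene symbols declared stable.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(base, group_effects, loading_sd = 0.3, noise_sd = 0.15,
                      stable = character()) {
  if (is.null(names(base))) abort("`base` must be a named vector")
  if (!is.matrix(group_effects) ||
      !identical(rownames(group_effects), names(base)))
    abort("`group_effects` must be a matrix with rownames matching `base`")
  if (loading_sd < 0 || noise_sd < 0) abort("noise SDs must be >= 0")
  bad <- stable[rowSums(abs(group_effects[stable, , drop = FALSE])) > 0]
  if (length(bad))
    abort("gene(s) labelled stable but with non-zero group effects: ",
          paste(bad, collapse = ", "))
  structure(list(base = base, group_effects = group_effects,
                 loading_sd = loading_sd, noise_sd = noise_sd,
                 stable = stable, loading = NULL, seed = NULL),
            class = "sim_truth")
}

#' Simulate a Cq panel from known ground truth
#'
#' Draws a full wells-level panel under the model documented in
#' [sim_truth()]. Groups are taken from the columns of
#' `truth$group_effects` (first `n_groups` of them). Reproducible for a
#' fixed seed; the returned truth records the drawn loading effects.
#'
#' @param truth a [sim_truth()].
#' @param n_groups,n_bio,n_tech numbers of groups, biological replicates
#'   per group and technical replicates per biological sample (all >= 1).
#' @param seed integer seed.
#' @return list with `table` (a [cq_table()], one column per well, sample
#'   ids `<group>_<bio>_t<tech>`) and `truth` (input truth with `$loading`
#'   and `$seed` filled in).
#' @export
simulate_cq_panel <- function(truth, n_groups = NULL, n_bio = 3, n_tech = 3,
                              seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  groups <- colnames(truth$group_effects)
  n_groups <- n_groups %||% length(groups)
  if (n_groups < 1 || n_bio < 1 || n_tech < 1) abort("counts must be >= 1")
  if (n_groups > length(groups))
    abort("truth defines only ", length(groups), " group(s)")
  groups <- groups[seq_len(n_groups)]
  genes <- names(truth$base)
  meta <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      group = groups, stringsAsFactors = FALSE)
  meta <- meta[, c("group", "bio_rep", "tech_rep")]
  meta$sample_id <- paste0(meta$group, "_", meta$bio_rep, "_t", meta$tech_rep)
  n_wells <- nrow(meta)
  withr::with_seed(seed, {
    loading <- stats::rnorm(n_wells, 0, truth$loading_sd)
    eps <- matrix(stats::rnorm(length(genes) * n_wells, 0, truth$noise_sd),
                  nrow = length(genes))
  })
  vals <- truth$base +
    truth$group_effects[, meta$group, drop = FALSE] +
    matrix(loading, length(genes), n_wells, byrow = TRUE) + eps
  dimnames(vals) <- list(genes, meta$sample_id)
  names(loading) <- meta$sample_id
  truth$loading <- loading
  truth$seed <- as.integer(seed)
  list(table = cq_table(vals, meta[, c("sample_id", "group", "bio_rep",
                                       "tech_rep")]),
       truth = truth)
}

#' Simulate a study-like ten-gene reference panel
#'
#' Emulates a typical reference-gene validation design in muscle satellite
#' cells: 10 candidate genes measured over 3 culture phases (GM =
#' proliferation, DM1/DM5 = differentiation days 1 and 5) x 3 biological x
#' 3 technical replicates = 90 wells. Eight genes are truly stable (zero
#' group effect), a GAPDH-like gene carries a moderate differentiation
#' effect (up to 0.8 cycles) and an ACTB-like gene a large one (>= 1.2
#' cycles between phases). Baseline Cq values are drawn uniformly in
#' [15.3, 20.7], the range typical of abundant transcripts; loading SD 0.3
#' and noise SD 0.15 cycles.
#'
#' @param seed integer seed.
#' @return list with `table` and `truth`, as [simulate_cq_panel()].
#' @export
simulate_paper_like_panel <- function(seed = 1L) {
  genes <- c("HSPA9", "DDOST", "RPL5", "CAPNS1", "YBX1", "EEF1G",
             "RPS15A", "RPL14", "GAPDH", "ACTB")
  groups <- c("GM", "DM1", "DM5")
  base <- withr::with_seed(seed, stats::runif(length(genes), 15.3, 20.7))
  names(base) <- genes
  eff <- matrix(0, length(genes), length(groups),
                dimnames = list(genes, groups))
  eff["GAPDH", ] <- c(0, 0.5, 0.8)
  eff["ACTB", ] <- c(0, 1.2, 2.4)
  truth <- sim_truth(base, eff, loading_sd = 0.3, noise_sd = 0.15,
                     stable = genes[1:8])
  # offset the panel seed so base-Cq and well-level draws are independent
  panel_seed <- as.integer((as.numeric(seed) + 10000) %% .Machine$integer.max)
  simulate_cq_panel(truth, n_groups = 3, n_bio = 3, n_tech = 3,
                    seed = panel_seed)
}

#' Simulate an FPKM matrix with a known candidate set
#'
#' Generates a log-normal-shaped expression matrix in which exactly
#' `n_candidates` genes satisfy the screening criteria (mean FPKM > 100 and
#' CV < 10%) and every other gene violates at least one of them. Each
#' gene's realized sample mean and CV are pinned exactly by standardizing
#' the drawn shape, so the pass/fail truth is guaranteed, not merely
#' likely. Violators alternate between low expression (mean FPKM in
#' [5, 80]) and high variability (CV in [12, 25]%).
#'
#' @param n_genes total genes (> `n_candidates`).
#' @param n_samples samples (>= 3).
#' @param n_candidates genes that must pass screening.
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene`, `is_candidate`, `target_mean`, `target_cv`).
#' @export
simulate_fpkm_matrix <- function(n_genes = 40, n_samples = 9,
                                 n_candidates = 8, seed = 1L) {
  if (n_candidates >= n_genes) abort("`n_candidates` must be < `n_genes`")
  if (n_samples < 3) abort("need >= 3 samples")
  # exact-CV construction keeps values positive only while cv * sqrt(n-1) < 100
  cv_cap <- 90 / sqrt(n_samples - 1)
  if (cv_cap <= 12)
    abort("infeasible: too many samples for the high-CV violator construction")
  genes <- sprintf("G%03d", seq_len(n_genes))
  is_cand <- c(rep(TRUE, n_candidates), rep(FALSE, n_genes - n_candidates))
  withr::with_seed(seed, {
    target_mean <- ifelse(is_cand,
                          exp(stats::runif(n_genes, log(150), log(2000))),
                          NA_real_)
    target_cv <- ifelse(is_cand, stats::runif(n_genes, 2, 8), NA_real_)
    n_viol <- n_genes - n_candidates
    low_expr <- rep(c(TRUE, FALSE), length.out = n_viol)
    target_mean[!is_cand] <- ifelse(low_expr,
                                    stats::runif(n_viol, 5, 80),
                                    exp(stats::runif(n_viol, log(150), log(2000))))
    target_cv[!is_cand] <- ifelse(low_expr,
                                  stats::runif(n_viol, 5, min(30, cv_cap)),
                                  stats::runif(n_viol, 12, min(25, cv_cap)))
    shape <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  })
  # standardize each row to mean 0 / sd 1, then rescale to the exact targets
  z <- t(scale(t(shape)))
  vals <- target_mean + z * (target_mean * target_cv / 100)
  dimnames(vals) <- list(genes, sprintf("S%02d", seq_len(n_samples)))
  if (any(vals <= 0)) abort("internal error: non-positive FPKM generated")
  truth <- data.frame(gene = genes, is_candidate = is_cand,
                      target_mean = target_mean, target_cv = target_cv,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals), truth = truth)
}

#' Simulate a qPCR dilution series
#'
#' Standard-curve model: `Cq = intercept + slope * log10(input)` with
#' `slope = -1 / log10(1 + E_true)`, relative input descending in
#' `dilution_factor`-fold steps from 1.
#'
#' @param E_true true amplification efficiency as a fraction in (0, 1.2]
#'   (1 = perfect doubling).
#' @param intercept Cq at relative input 1.
#' @param n_points number of dilution points (>= 3).
#' @param n_reps technical replicates per point.
#' @param noise_sd Cq noise SD (0 = exact points).
#' @param dilution_factor fold-change between consecutive points (> 1).
#' @param seed integer seed.
#' @return object of class `dilution_series`: list with `data` (data.frame
#'   `input`, `rep`, `cq`), `E_true`, `intercept`, `slope`.
#' @export
simulate_dilution_series <- function(E_true, intercept = 20, n_points = 5,
                                     n_reps = 3, noise_sd = 0,
                                     dilution_factor = 10, seed = 1L) {
  if (E_true <= 0 || E_true > 1.2)
    abort("`E_true` must lie in (0, 1.2]")
  if (n_points < 3) abort("need >= 3 dilution points")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (dilution_factor <= 1) abort("`dilution_factor` must exceed 1")
  input <- dilution_factor^-(seq_len(n_points) - 1)
  slope <- -1 / log10(1 + E_true)
  grid <- expand.grid(rep = seq_len(n_reps), input = input)[, c("input", "rep")]
  cq <- intercept + slope * log10(grid$input)
  if (noise_sd > 0)
    cq <- cq + withr::with_seed(seed, stats::rnorm(length(cq), 0, noise_sd))
  structure(list(data = data.frame(input = grid$input, rep = grid$rep,
                                   cq = cq),
                 E_true = E_true, intercept = intercept, slope = slope),
            class = "dilution_series")
}
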