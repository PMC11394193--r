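test_that("geometric mean rank matches hand values and rejects gaps", {
  expect_equal(round(unname(geometric_mean_rank(c(1, 1, 4))), 2), 1.59)
  expect_equal(unname(geometric_mean_rank(c(10, 10, 10))), 10)
  for (r in c(1, 3, 7))
    expect_equal(unname(geometric_mean_rank(c(r, r, r))), r)
  m <- matrix(c(1, 2, NA, 3), 2, 2,
              dimnames = list(c("A", "B"), c("genorm", "bestkeeper")))
  expect_error(geometric_mean_rank(m), "gene 'A'.*method 'bestkeeper'")
  expect_error(geometric_mean_rank(c(0, 2)), ">= 1")
})

test_that("aggregation is symmetric in method order and monotone in ranks", {
  m <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3, 3, 4, 1, 2), 4, 3,
              dimnames = list(paste0("G", 1:4), c("a", "b", "c")))
  r1 <- comprehensive_ranking(m)
  r2 <- comprehensive_ranking(m[, c(3, 1, 2)])
  expect_equal(r1$mean_rank[match(paste0("G", 1:4), r1$gene)],
               r2$mean_rank[match(paste0("G", 1:4), r2$gene)])
  expect_equal(r1$comprehensive_rank[match(r1$gene, r1$gene)],
               r2$comprehensive_rank[match(r1$gene, r2$gene)])
  # improving one method's rank never worsens the mean rank
  m2 <- m
  m2["G4", "a"] <- 1
  r3 <- comprehensive_ranking(m2)
  expect_lte(r3$mean_rank[r3$gene == "G4"], r1$mean_rank[r1$gene == "G4"])
})

test_that("consensus rejects single methods and inconsistent gene sets", {
  sim <- simulate_paper_like_panel(seed = 5)
  col <- collapse_technical_replicates(sim$table)$table
  q <- relative_quantity(col)
  g <- genorm_ranking(q)
  expect_error(comprehensive_ranking(list(g)), ">= 2")
  bk <- bestkeeper(col)
  bk$gene[1] <- "NOT_A_GENE"
  expect_error(comprehensive_ranking(list(g, bk)), "different gene set")
})

test_that("four-method consensus on the designed panel isolates the worst gene", {
  sim <- simulate_paper_like_panel(seed = 41)
  col <- collapse_technical_replicates(sim$table)$table
  q <- relative_quantity(col)
  cons <- comprehensive_ranking(list(genorm_ranking(q),
                                     normfinder_stability(q),
                                     bestkeeper(col),
                                     delta_ct_method(col)))
  expect_setequal(cons$comprehensive_rank, 1:10)
  expect_equal(cons$gene[cons$comprehensive_rank == 10], "ACTB")
  expect_true(all(cons$mean_rank >= 1 - 1e-9 & cons$mean_rank <= 10 + 1e-9))
})

test_that("group comparison reports ANOVA, SEM and pairwise labels", {
  # identical group means with within-group spread: F = 0, p = 1
  mk_fc <- function(folds, groups) {
    structure(list(data = data.frame(sample_id = seq_along(folds),
                                     group = groups, delta_ct = 0,
                                     ddct = 0, fold = folds),
                   target = "T", refs = "R", calibrator = groups[1]),
              class = "fold_change_table")
  }
  null_fc <- mk_fc(rep(c(0.8, 1.0, 1.2), 3), rep(c("GM", "DM1", "DM5"), each = 3))
  gc <- compare_normalizations(null_fc)[[1]]
  expect_lt(gc$anova$f, 1e-10)
  expect_gt(gc$anova$p, 0.999)
  expect_true(all(gc$pairwise$label == "ns"))
  expect_true(all(gc$groups$sem >= 0))

  # two groups: ANOVA F equals the squared pooled t statistic
  folds <- c(1.0, 1.1, 0.9, 2.0, 2.2, 1.9)
  groups <- rep(c("GM", "DM1"), each = 3)
  gc2 <- compare_normalizations(mk_fc(folds, groups))[[1]]
  tt <- t.test(folds[4:6], folds[1:3], var.equal = TRUE)
  expect_equal(gc2$anova$f, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(gc2$anova$p, tt$p.value, tolerance = 1e-9)
})

test_that("run_pipeline drives every stage and writes deterministic CSVs", {
  sim <- simulate_paper_like_panel(seed = 13)
  fpkm <- simulate_fpkm_matrix(seed = 13)$matrix
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- run_pipeline(sim$table, fpkm = fpkm,
                      targets = list(val = list(target = "RPL5",
                                                refs = c("RPL14", "RPS15A"),
                                                calibrator = "GM")),
                      out_dir = d1)
  expect_equal(nrow(res$consensus), 10)
  stable_ranks <- res$consensus$comprehensive_rank[
    res$consensus$gene %in% sim$truth$stable]
  expect_setequal(stable_ranks, 1:8)
  expect_true(file.exists(file.path(d1, "consensus.csv")))
  run_pipeline(sim$table, fpkm = fpkm,
               targets = list(val = list(target = "RPL5",
                                         refs = c("RPL14", "RPS15A"),
                                         calibrator = "GM")),
               out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("run_pipeline falls back to ungrouped NormFinder for one group", {
  genes <- paste0("G", 1:5)
  base <- stats::setNames(16:20, genes)
  eff <- matrix(0, 5, 1, dimnames = list(genes, "GM"))
  tr <- sim_truth(base, eff, loading_sd = 0.2, noise_sd = 0.1)
  sim <- simulate_cq_panel(tr, n_bio = 6, n_tech = 2, seed = 3)
  res <- run_pipeline(sim$table)
  expect_equal(res$results$normfinder$groups, "all")
  expect_equal(nrow(res$consensus), 5)
})
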