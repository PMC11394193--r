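base3 <- c(A = 18, B = 20, C = 22)
eff0 <- matrix(0, 3, 3, dimnames = list(names(base3), c("GM", "DM1", "DM5")))

test_that("degenerate generator (no noise, no loading, no effects) is constant", {
  tr <- sim_truth(base3, eff0, loading_sd = 0, noise_sd = 0)
  sim <- simulate_cq_panel(tr, n_bio = 2, n_tech = 2, seed = 5)
  expect_true(all(sim$table$values == base3))
})

test_that("a fixed seed reproduces the panel exactly and is recorded", {
  tr <- sim_truth(base3, eff0, loading_sd = 0.4, noise_sd = 0.2)
  a <- simulate_cq_panel(tr, seed = 42)
  b <- simulate_cq_panel(tr, seed = 42)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth$loading, b$truth$loading)
  expect_equal(a$truth$seed, 42)
  c <- simulate_cq_panel(tr, seed = 43)
  expect_false(identical(a$table$values, c$table$values))
})

test_that("sample-loading effects cancel in gene ratios", {
  tr <- sim_truth(base3, eff0, loading_sd = 1.0, noise_sd = 0)
  sim <- simulate_cq_panel(tr, n_bio = 3, n_tech = 2, seed = 9)
  v <- sim$table$values
  for (j in 1:2) for (l in (j + 1):3)
    expect_lt(stats::sd(v[j, ] - v[l, ]), 1e-12)
  # consequence: geNorm M is exactly 0 whatever the loading SD
  q <- relative_quantity(collapse_technical_replicates(sim$table)$table)
  expect_true(all(m_values(q) < 1e-9))
})

test_that("negative noise SDs are rejected", {
  expect_error(sim_truth(base3, eff0, loading_sd = -0.1), ">= 0")
  expect_error(sim_truth(base3, eff0, noise_sd = -1), ">= 0")
})

test_that("study-like panel has the designed shape and worst gene", {
  sim <- simulate_paper_like_panel(seed = 21)
  expect_equal(dim(sim$table$values), c(10, 27))
  expect_setequal(sim$truth$stable,
                  setdiff(rownames(sim$table$values), c("GAPDH", "ACTB")))
  rng <- apply(sim$table$values, 1, function(x) diff(range(x)))
  expect_equal(names(which.max(rng)), "ACTB")
  expect_true(all(sim$table$values > 13 & sim$table$values < 25))
})

test_that("FPKM generator pins the candidate set exactly", {
  sim <- simulate_fpkm_matrix(n_genes = 40, n_samples = 9,
                              n_candidates = 8, seed = 2)
  scr <- screen_candidates(sim$matrix, top_k = 8)
  expect_setequal(scr$candidates$gene,
                  sim$truth$gene[sim$truth$is_candidate])
  expect_true(all(diff(scr$candidates$cv_pct) >= 0))
  expect_error(simulate_fpkm_matrix(n_genes = 5, n_candidates = 5),
               "n_candidates")
})

test_that("dilution series follows the closed-form standard curve", {
  d <- simulate_dilution_series(E_true = 1.0, n_points = 5, n_reps = 1,
                                noise_sd = 0)
  expect_equal(diff(d$data$cq), rep(1 / log10(2), 4), tolerance = 1e-12)
  a <- simulate_dilution_series(0.95, noise_sd = 0.1, seed = 7)
  b <- simulate_dilution_series(0.95, noise_sd = 0.1, seed = 7)
  expect_identical(a$data$cq, b$data$cq)
  expect_error(simulate_dilution_series(1.5), "\\(0, 1.2\\]")
  expect_error(simulate_dilution_series(0.9, n_points = 2), ">= 3")
})

test_that("growing a gene's group effect never improves its stability statistics", {
  prev <- NULL
  for (e in c(0, 0.5, 1, 2)) {
    eff <- eff0
    eff["C", ] <- c(0, e, 1.5 * e)
    tr <- sim_truth(base3 + c(0, 0, 0), eff, loading_sd = 0.2,
                    noise_sd = 0.15)
    col <- collapse_technical_replicates(
      simulate_cq_panel(tr, n_bio = 3, n_tech = 3, seed = 31)$table)$table
    q <- relative_quantity(col)
    cur <- c(m = unname(m_values(q)["C"]),
             rho = normfinder_stability(q)$statistic[3],
             bk = bestkeeper(col)$sd[3])
    if (!is.null(prev)) expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("the uniquely worst gene is recovered as least stable across seeds", {
  eff <- eff0
  genes <- c("A", "B", "C", "D", "E")
  base5 <- c(A = 17, B = 18, C = 19, D = 20, E = 21)
  eff5 <- matrix(0, 5, 3, dimnames = list(genes, c("GM", "DM1", "DM5")))
  eff5["E", ] <- c(0, 1.0, 1.5)  # >= 5x the 0.15-cycle noise SD
  tr <- sim_truth(base5, eff5, loading_sd = 0.2, noise_sd = 0.15)
  n_ok <- 0L
  for (s in 1:50) {
    col <- collapse_technical_replicates(
      simulate_cq_panel(tr, n_bio = 3, n_tech = 3, seed = s)$table)$table
    q <- relative_quantity(col)
    worst_everywhere <-
      genorm_ranking(q)$rank[5] == 5 &&
      normfinder_stability(q)$rank[5] == 5 &&
      bestkeeper(col)$rank[5] == 5
    cons <- comprehensive_ranking(list(genorm_ranking(q),
                                       normfinder_stability(q),
                                       bestkeeper(col),
                                       delta_ct_method(col)))
    n_ok <- n_ok + (worst_everywhere &&
                      cons$gene[cons$comprehensive_rank == 5] == "E")
  }
  expect_gte(n_ok, 48)  # >= 95% of 50 seeded runs
})
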