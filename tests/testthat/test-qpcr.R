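test_that("efficiency fit recovers the closed-form standard-curve relations", {
  # perfect doubling: slope -1/log10(2) = -3.32193, E = 100%
  d <- simulate_dilution_series(1.0, n_points = 5, n_reps = 3, noise_sd = 0)
  f <- fit_efficiency(d)
  expect_equal(f$efficiency_pct, 100, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_true(f$valid && f$in_band)

  # noiseless round trip of the generating slope/intercept
  d9 <- simulate_dilution_series(0.9, intercept = 24, n_points = 6,
                                 noise_sd = 0)
  f9 <- fit_efficiency(d9)
  expect_equal(f9$efficiency_pct, 90, tolerance = 1e-6)
  expect_equal(f9$slope, d9$slope, tolerance = 1e-9)
  expect_equal(f9$intercept, 24, tolerance = 1e-9)

  # slope -3.1 sits above the default 90-110% band and is flagged
  df <- data.frame(input = 10^-(0:3), cq = 20 + -3.1 * log10(10^-(0:3)))
  f31 <- fit_efficiency(df)
  expect_equal(f31$efficiency_pct, 100 * (10^(1 / 3.1) - 1),
               tolerance = 1e-9)
  expect_false(f31$in_band)
  expect_true(f31$valid)
})

test_that("degenerate dilution inputs are rejected or flagged", {
  expect_error(fit_efficiency(data.frame(input = c(1, 0.1, 1, 0.1),
                                         cq = c(20, 23, 20, 23))),
               "3 distinct")
  f <- fit_efficiency(data.frame(input = 10^-(0:3), cq = c(20, 18, 16, 14)))
  expect_false(f$valid)  # Cq decreasing with dilution: positive slope
  expect_true(is.na(f$efficiency_pct))
})

test_that("relative quantities anchor each gene's maximum at exactly 1", {
  t <- make_cq(rbind(A = c(15, 16, 17), B = c(20, 20, 20)))
  q <- relative_quantity(t)
  expect_equal(unname(q$values["A", ]), c(1, 0.5, 0.25))
  expect_equal(unname(q$values["B", ]), c(1, 1, 1))
  expect_true(all(apply(q$values, 1, max) == 1))  # exact, not approximate

  # per-gene additive Cq shifts leave Q untouched (min shifts along)
  t2 <- make_cq(rbind(A = c(15, 16, 17) + 2, B = c(20, 20, 20)))
  expect_identical(relative_quantity(t2)$values, q$values)
})

test_that("relative_quantity refuses uncollapsed or incomplete tables", {
  meta <- data.frame(sample_id = c("w1", "w2"), group = "GM",
                     bio_rep = 1L, tech_rep = 1:2)
  wells <- cq_table(matrix(c(20, 21, 22, 23), 2, 2,
                           dimnames = list(c("A", "B"), c("w1", "w2"))),
                    meta)
  expect_error(relative_quantity(wells), "collapse")
})

test_that("delta-delta-Ct satisfies its self-normalization contracts", {
  v <- rbind(T1 = c(20, 20, 19, 19), REF = c(20, 20, 20, 20))
  t <- make_cq(v, groups = c("GM", "GM", "DM1", "DM1"))
  # target one cycle below the reference in DM1, equal in GM -> fold 2
  fc <- ddct_fold_change(t, "T1", "REF", calibrator = "GM")
  expect_equal(fc$data$fold, c(1, 1, 2, 2))

  # target identical to the reference: all folds 1
  v2 <- rbind(T1 = c(21, 20, 19, 18), REF = c(21, 20, 19, 18))
  fc2 <- ddct_fold_change(make_cq(v2, groups = c("GM", "GM", "DM1", "DM1")),
                          "T1", "REF", calibrator = "GM")
  expect_equal(fc2$data$fold, rep(1, 4))

  # calibrator group's geometric-mean fold change is 1 by construction
  t3 <- random_cq_panel(4, 9, seed = 12)
  t3$meta$group <- rep(c("GM", "DM1", "DM5"), each = 3)
  fc3 <- ddct_fold_change(t3, "g01", c("g02", "g03"), calibrator = "GM")
  cal <- fc3$data$fold[fc3$data$group == "GM"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)

  expect_error(ddct_fold_change(t, "T1", character(0), "GM"), "empty")
  expect_error(ddct_fold_change(t, "T1", "REF", "DM9"), "no samples")
})

test_that("multi-reference ddCt equals the mean-Cq pseudo-gene construction", {
  t <- random_cq_panel(5, 8, seed = 33)
  t$meta$group <- rep(c("GM", "DM1"), each = 4)
  two <- ddct_fold_change(t, "g01", c("g02", "g04"), calibrator = "GM")
  pseudo <- t$values
  pseudo <- rbind(pseudo, PSEUDO = colMeans(t$values[c("g02", "g04"), ]))
  tp <- cq_table(pseudo, t$meta)
  one <- ddct_fold_change(tp, "g01", "PSEUDO", calibrator = "GM")
  expect_equal(two$data$fold, one$data$fold, tolerance = 1e-12)
})
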