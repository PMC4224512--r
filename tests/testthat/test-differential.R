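test_that("undetected substitution caps at the final cycle and keeps actual Ct", {
  expect_equal(substitute_undetected(NA, 40), 40)
  expect_equal(substitute_undetected(37.2, 40), 37.2)
  expect_equal(substitute_undetected(41.3, 40), 40)
  expect_equal(substitute_undetected(c(NA, 39.9, 40, 40.1)), c(40, 39.9, 40, 40))
  expect_error(substitute_undetected(30, cap = -1), "positive")
})

test_that("relative quantitation follows 2^-ddCt with exact log identities", {
  rq0 <- relative_quantitation(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rq0$mean_ddct, 0)
  expect_equal(rq0$rq, 1)
  expect_equal(rq0$log10_rq, 0)

  rq1 <- relative_quantitation(c(0, 0), c(1, 1))   # one cycle earlier = doubling
  expect_equal(rq1$rq, 2)
  expect_equal(rq1$log10_rq, log10(2), tolerance = 1e-12)

  # magnitude matching a strongly induced target: ddCt -6.611 -> log10 RQ 1.99
  rq2 <- relative_quantitation(c(-6.611), c(0))
  expect_equal(rq2$log10_rq, 6.611 * log10(2), tolerance = 1e-12)
  expect_equal(round(rq2$log10_rq, 2), 1.99)

  # reciprocity: rq(d) * rq(-d) = 1
  for (d in c(-3.2, -1, -0.25, 0.5, 2, 7))
    expect_equal(relative_quantitation(d, 0)$rq *
                   relative_quantitation(-d, 0)$rq, 1, tolerance = 1e-12)

  expect_error(relative_quantitation(numeric(0), 1), "empty")
})

test_that("group-difference test matches stats::t.test in both variants", {
  set.seed(6)
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, -2, 2))
    expect_equal(test_group_difference(x, y),
                 t.test(x, y)$p.value, tolerance = 1e-12)
    expect_equal(test_group_difference(x, y, var_equal = TRUE),
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(test_group_difference(1, c(1, 2)), "two replicates")
})

test_that("degenerate-variance comparisons return guarded p-values with a warning", {
  expect_warning(p_eq <- test_group_difference(c(2, 2, 2), c(2, 2, 2)),
                 "zero variance")
  expect_equal(p_eq, 1)
  expect_warning(p_ne <- test_group_difference(c(40, 40, 40), c(30, 30, 30)),
                 "zero variance")
  expect_lt(p_ne, 1e-100)
  expect_gt(p_ne, 0)
})

test_that("t-test p-values agree with the exhaustive permutation oracle's ordering", {
  pairs <- toy_pairs_3v3()
  p_t <- vapply(pairs, function(p) test_group_difference(p$x, p$y), numeric(1))
  p_perm <- vapply(pairs, function(p) perm_t_p(p$x, p$y), numeric(1))
  # every strict ordering under the permutation oracle is preserved
  for (i in seq_along(pairs))
    for (j in seq_along(pairs))
      if (p_perm[i] < p_perm[j]) expect_lt(p_t[i], p_t[j])
  # and the clear-cut cases land on the right side of 0.05
  expect_gt(p_t[1], 0.05)   # interleaved triples: not significant
  expect_lt(p_t[2], 0.01)   # well-separated groups
})

test_that("significance calls require both the fold and the p threshold", {
  thr <- de_thresholds()
  c1 <- call_significant(0.58, 1.82e-3, thr)
  expect_true(c1$significant); expect_equal(c1$direction, "up")
  c2 <- call_significant(-0.85, 2.16e-2, thr)
  expect_true(c2$significant); expect_equal(c2$direction, "down")
  # tiny fold is never significant no matter how small the p
  c3 <- call_significant(0.10, 1e-4, thr)
  expect_false(c3$significant); expect_equal(c3$direction, "none")
  # the fold boundary itself passes (>= with representation guard)
  expect_true(call_significant(log10(1.5), 0.01, thr)$significant)
  expect_true(call_significant(-log10(1.5), 0.01, thr)$significant)
})

test_that("significance calling is monotone in |fold| and anti-monotone in p", {
  thr <- de_thresholds()
  folds <- seq(0, 1, by = 0.05)
  sig_by_fold <- call_significant(folds, rep(0.01, length(folds)), thr)$significant
  expect_true(all(diff(sig_by_fold) >= 0))
  ps <- c(1e-6, 1e-3, 0.01, 0.049, 0.05, 0.2, 0.9)
  sig_by_p <- call_significant(rep(0.5, length(ps)), ps, thr)$significant
  expect_true(all(diff(sig_by_p) <= 0))
})

test_that("run_de recovers a spiked target and classifies absent targets", {
  set.seed(9)
  n <- 40
  base <- runif(n, 20, 30)
  ct <- matrix(rep(base, 12), n, 12) + rnorm(n * 12, sd = 0.2)
  rownames(ct) <- paste0("t", 1:n); colnames(ct) <- paste0("s", 1:12)
  ct[1, 7:12] <- ct[1, 7:12] - 2          # 4-fold up in the injured half
  ct[2, 1:6] <- NA                        # absent in sham
  ct[3, 7:12] <- NA                       # absent in injured
  m <- ct_matrix(ct)
  d <- make_design(m, 6)
  res <- run_de(m, d, "inj")

  r1 <- res[res$target == "t1", ]
  expect_equal(r1$ct_status, "valid")
  expect_true(r1$significant); expect_equal(r1$direction, "up")

  r2 <- res[res$target == "t2", ]
  expect_equal(r2$ct_status, "calibrator_not_detected")
  expect_gt(r2$log10_rq, 0)               # cap 40 in sham forces positive fold
  r3 <- res[res$target == "t3", ]
  expect_equal(r3$ct_status, "target_not_detected")
  expect_lt(r3$log10_rq, 0)

  # internal consistency of the quantities
  expect_equal(res$rq, 2^(-res$mean_ddct), tolerance = 1e-12)
  expect_equal(res$log10_rq, log10(res$rq), tolerance = 1e-12)
  expect_error(run_de(m, d, "sham"), "calibrator")
  expect_error(run_de(m, d, "nope"), "unknown or empty group")
})

test_that("null simulations produce near-uniform p-values for valid targets", {
  sim <- simulate_ct_experiment(sim_config(effect_targets = 0, seed = 21))
  de <- run_de(sim$matrix, sim$design, "IS2")
  p <- de$p_value[de$ct_status == "valid"]
  expect_gt(length(p), 300)
  # Kolmogorov-Smirnov against uniform should not reject wildly
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.001)
  # empirical type-I (p < 0.05 alone) within binomial 99.9% bounds
  rate <- mean(p < 0.05)
  bound <- 3.29 * sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(rate - 0.05), bound + 0.001)
})
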