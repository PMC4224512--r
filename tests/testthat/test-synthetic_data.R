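test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_ct_experiment(sim_config(seed = 77))
  b <- simulate_ct_experiment(sim_config(seed = 77))
  expect_identical(a$matrix$ct, b$matrix$ct)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_ct_experiment(sim_config(seed = 78))
  expect_false(identical(a$matrix$ct, c_$matrix$ct))
  expect_error(sim_config(n_targets = 0), "positive")
})

test_that("simulated structure matches the configured design", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_ct_experiment(cfg)
  expect_equal(dim(sim$matrix), c(368L, 30L))
  expect_equal(sim$design$calibrator, "sham")
  expect_equal(sort(unique(unname(sim$design$assignment))),
               sort(c("sham", paste0("IS", 1:4))))
  expect_equal(table(sim$matrix$panel)[["A"]], 184L)
  # one truth record per matrix target
  expect_setequal(sim$truth$target, rownames(sim$matrix$ct))
  expect_equal(sum(sim$truth$is_stable), 5L)
  # stable targets: zero shift, abundant baseline
  st <- sim$truth[sim$truth$is_stable, ]
  expect_true(all(st$shift_IS4 == 0))
  expect_true(all(st$baseline >= 15 & st$baseline <= 16))
  # graded magnitudes per group on effect targets
  eff <- sim$truth[sim$truth$orientation != 0, ]
  expect_equal(nrow(eff), round(0.1 * 368))
  expect_equal(abs(eff$shift_IS2) / abs(eff$shift_IS1), rep(2, nrow(eff)))
  expect_equal(abs(eff$shift_IS4) / abs(eff$shift_IS3), rep(4.5 / 4, nrow(eff)))
  # no realized Ct at or above the dropout ceiling
  expect_true(all(sim$matrix$ct < 36, na.rm = TRUE))
})

test_that("graded effects yield monotone significant-call counts in expectation", {
  counts <- sapply(1:15, function(s) {
    sim <- simulate_ct_experiment(sim_config(seed = 900 + s))
    vapply(run_de_all(sim$matrix, sim$design), function(d)
      sum(d$significant), integer(1))
  })
  avg <- rowMeans(counts)
  # power rises steeply over the unsaturated severities; the two strongest
  # effect grades (4- and 4.5-fold) both sit near complete recovery
  expect_true(all(diff(avg[paste0("IS", 1:3)]) > 0))
  expect_gte(avg[["IS4"]], avg[["IS3"]] - 3)
})

test_that("recovery scoring handles perfect, empty and scrambled calls", {
  sim <- simulate_ct_experiment(sim_config(seed = 55, noise_sd = 0.3,
                                           effect_logfc = rep(-2, 4)))
  de <- run_de(sim$matrix, sim$design, "IS1")

  perfect <- de
  truth_shift <- sim$truth$shift_IS1[match(de$target, sim$truth$target)]
  perfect$significant <- abs(truth_shift) >= log2(1.5)
  perfect$direction <- ifelse(!perfect$significant, "none",
                              ifelse(truth_shift < 0, "up", "down"))
  r <- evaluate_recovery(perfect, sim$truth)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$fdr, 0)
  expect_equal(r$direction_accuracy, 1)

  none <- de; none$significant <- FALSE; none$direction <- "none"
  r0 <- evaluate_recovery(none, sim$truth)
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$fdr, 0)
  expect_false(r0$fdr_defined)

  # scrambling directions on a strong-effect simulation halves accuracy
  set.seed(1)
  accs <- replicate(40, {
    scram <- perfect
    scram$direction[scram$significant] <-
      sample(c("up", "down"), sum(scram$significant), replace = TRUE)
    evaluate_recovery(scram, sim$truth)$direction_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  bad <- de; bad$target[1] <- "not-a-target"
  expect_error(evaluate_recovery(bad, sim$truth), "unknown to the truth")
})

test_that("a written simulation reloads into the same matrix and design", {
  sim <- simulate_ct_experiment(sim_config(n_targets = 30, seed = 2,
                                           baseline_range = c(14, 38)))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  m <- read_ct_long(file.path(dir, "ct_long.csv"))
  expect_identical(m$ct[rownames(sim$matrix$ct), colnames(sim$matrix$ct)],
                   sim$matrix$ct)
  d <- read_group_design(file.path(dir, "metadata.tsv"), "sham")
  expect_identical(d$assignment, sim$design$assignment)
})
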