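test_that("partition_flows reproduces hand-worked electron budgets", {
  # non-photorespiratory identity: jt = 4 (a + rl)
  p0 <- partition_flows(jt = 4 * 21, a = 20, rl = 1)
  expect_equal(p0$pr, 0)
  expect_equal(p0$jo, 0)
  expect_equal(p0$jc, p0$jt)
  expect_match(p0$flags, "jo_zero")

  p1 <- partition_flows(jt = 117.333, a = 20, rl = 1)
  expect_equal(p1$jc, (117.333 + 8 * 21) / 3, tolerance = 1e-12)  # 95.111
  expect_equal(p1$jo, 2 * (117.333 - 84) / 3, tolerance = 1e-12)  # 22.222
  expect_equal(p1$pr, (117.333 - 84) / 12, tolerance = 1e-12)     # 2.7778
  expect_equal(p1$jc + p1$jo, p1$jt, tolerance = 1e-12)
  expect_equal(p1$jo, 8 * p1$pr, tolerance = 1e-12)

  p2 <- partition_flows(jt = 100, a = 15, rl = 1)
  expect_equal(p2$pr, 3)
  expect_equal(p2$jo, 24)
  expect_equal(p2$jc, 76)
  expect_equal(p2$a_gross, 19)
  expect_equal(p2$pr_over_agross, 3 / 19, tolerance = 1e-9)
  expect_equal(p2$jc_over_jo, 76 / 24, tolerance = 1e-9)
})

test_that("negative photorespiration is reported as-is and flagged", {
  p <- partition_flows(jt = 60, a = 20, rl = 1)   # jt < 4 (a + rl)
  expect_lt(p$pr, 0)
  expect_lt(p$jo, 0)
  expect_match(p$flags, "negative_oxygenation")
  expect_error(partition_flows(Inf, 1, 1), class = "leafflow_domain_error")
})

test_that("run_leaf reproduces ground truth exactly on a noise-free leaf", {
  cfg <- exact_config(phi_ox = 0.25, seed = 5)
  ex <- simulate_leaf_experiment(cfg)
  out <- run_leaf(ex$calibration, ex$measurement, rd = ex$rd_true, mode = "gross")
  gt <- ground_truth(cfg, o2_fraction = 0.21, light = 1000)
  expect_equal(out$result$k, cfg$k_true, tolerance = 1e-10)
  expect_equal(out$result$b, cfg$b_true, tolerance = 1e-10)
  expect_equal(out$result$pr, gt$pr, tolerance = 1e-8)
  expect_equal(out$result$jc, gt$jc, tolerance = 1e-8)
  expect_equal(out$result$jo, gt$jo, tolerance = 1e-8)
  expect_equal(out$result$pr_over_agross, gt$pr_over_agross, tolerance = 1e-8)
  expect_equal(out$result$jc_over_jo, 1 / 0.25, tolerance = 1e-8)
  expect_equal(out$result$flags, "")
})

test_that("a leaf with zero ambient oxygenation yields Pr ~ 0 without flags", {
  cfg <- leaf_sim_config(noise_phi_psii = 0, noise_a = 0, phi_ox = 0,
                         phi_ox_low_o2 = 0, seed = 2)
  ex <- simulate_leaf_experiment(cfg)
  out <- run_leaf(ex$calibration, ex$measurement, rd = ex$rd_true, mode = "gross")
  expect_equal(out$result$pr, 0, tolerance = 1e-8)
  expect_false(grepl("negative_oxygenation", out$result$flags))
})

test_that("run_leaf errors carry the leaf id and stage", {
  ex <- simulate_leaf_experiment(exact_config(seed = 9), plant_id = "GD_3")
  err <- expect_error(run_leaf(ex$calibration[0, ], ex$measurement, rd = 1),
                      class = "leafflow_insufficient_data")
  expect_match(conditionMessage(err), "GD_3")
  few <- ex$calibration[ex$calibration$I > 900, ]
  err2 <- expect_error(run_leaf(few, ex$measurement, rd = 1),
                       class = "leafflow_insufficient_data")
  expect_match(conditionMessage(err2), "calibration")
})

test_that("partition_leaves handles several leaves and soft-fails bad ones", {
  cfgA <- exact_config(phi_ox = 0.25, seed = 21)
  cfgB <- exact_config(phi_ox = 0.10, seed = 22)
  exA <- simulate_leaf_experiment(cfgA, plant_id = "A1", genotype = "WT")
  exB <- simulate_leaf_experiment(cfgB, plant_id = "B1", genotype = "OX")
  calib <- dplyr::bind_rows(exA$calibration, exB$calibration)
  meas <- dplyr::bind_rows(exA$measurement, exB$measurement)
  # B1 gets no calibration curve -> soft failure row
  res <- partition_leaves(calib[calib$plant_id == "A1", ], meas,
                          rd = c(A1 = 1, B1 = 1))
  expect_equal(nrow(res), 2L)
  okA <- res[res$leaf_id == "A1", ]
  expect_equal(okA$pr_over_agross, 0.125, tolerance = 1e-8)
  expect_equal(okA$genotype, "WT")
  bad <- res[res$leaf_id == "B1", ]
  expect_true(is.na(bad$pr))
  expect_match(bad$flags, "error")

  # full data: both leaves recovered, jc/jo = 1/phi
  res2 <- partition_leaves(calib, meas, rd = c(A1 = 1, B1 = 1))
  expect_equal(res2$jc_over_jo[res2$leaf_id == "A1"], 4, tolerance = 1e-8)
  expect_equal(res2$jc_over_jo[res2$leaf_id == "B1"], 10, tolerance = 1e-8)
})

test_that("estimated ratios move monotonically with the oxygenation fraction", {
  phis <- c(0.1, 0.2, 0.3, 0.4)
  est <- vapply(phis, function(phi) {
    cfg <- exact_config(phi_ox = phi, seed = 31)
    ex <- simulate_leaf_experiment(cfg)
    r <- run_leaf(ex$calibration, ex$measurement, rd = ex$rd_true, mode = "gross")$result
    c(r$pr_over_agross, r$jc_over_jo)
  }, numeric(2))
  expect_true(all(diff(est[1, ]) > 0))   # Pr/A_gross increasing in phi
  expect_true(all(diff(est[2, ]) < 0))   # Jc/Jo decreasing in phi
})
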