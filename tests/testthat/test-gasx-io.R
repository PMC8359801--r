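test_that("read_gasx parses a Li-cor-style export and maps columns", {
  path <- write_licor_fixture()
  df <- read_gasx(path, licor6400_dialect())
  expect_equal(nrow(df), 3L)
  expect_equal(df$A, c(12.1, 12.0, 12.2))
  expect_equal(df$gs, c(0.21, 0.20, 0.21))
  expect_equal(df$I, rep(1000, 3))
  expect_equal(df$Fm_prime, c(1480, 1478, 1482))
  expect_true(all(df$qc_flags == ""))
})

test_that("read_gasx errors name the missing required column", {
  rows <- data.frame(Photo = 1:3, Cond = 0.2, Fs = 500)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  err <- expect_error(read_gasx(path, licor6400_dialect()),
                      class = "leafflow_config_error")
  expect_match(conditionMessage(err), "\\bI\\b")
})

test_that("read_gasx flags physically suspect rows instead of dropping them", {
  rows <- data.frame(Photo = c(10, 10), Cond = 0.2, PARi = 1000,
                     Fs = c(400, 1200), `Fm.` = c(0, 1000), check.names = FALSE)
  names(rows)[5] <- "Fm'"
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  expect_warning(df <- read_gasx(path, licor6400_dialect()), "quality flags")
  expect_equal(nrow(df), 2L)
  expect_match(df$qc_flags[1], "fm_nonpos")
  expect_match(df$qc_flags[2], "fs_gt_fm")
})

test_that("unparseable numeric cells report the offending row", {
  rows <- data.frame(Photo = c("10", "oops"), Cond = "0.2", PARi = "1000")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  err <- expect_error(read_gasx(path, licor6400_dialect()),
                      class = "leafflow_data_error")
  expect_match(conditionMessage(err), "row 2")
})

test_that("gas-exchange files round-trip through write_gasx/read_gasx", {
  df <- simulate_leaf(leaf_sim_config(seed = 7), o2_fraction = 0.02)
  path <- tempfile(fileext = ".csv")
  write_gasx(df, path)
  back <- read_gasx(path, gasx_dialect())
  for (v in c("A", "gs", "Ci", "E", "I", "Fs", "Fm_prime", "o2_fraction")) {
    expect_equal(back[[v]], df[[v]], tolerance = 1e-12, label = v)
  }
  expect_equal(back$plant_id, df$plant_id)
})

test_that("steady_state_average finds the first stable window", {
  recs <- canon_records(a = c(10, 10, 10, 20))
  avg <- steady_state_average(recs, window = 3, rel_tol = 0.02)
  expect_equal(avg$A, 10)
  expect_equal(attr(avg, "window_start"), 1L)

  # identical records return themselves exactly
  ident <- canon_records(a = c(8.5, 8.5, 8.5))
  avg2 <- steady_state_average(ident)
  expect_equal(avg2$A, 8.5)
  expect_equal(avg2$Fs, 450)

  # idempotence: averaging an averaged window returns itself
  three <- dplyr::bind_rows(avg2, avg2, avg2)
  expect_equal(steady_state_average(three)$A, avg2$A)
})

test_that("a monotone ramp has no steady state and reports the best window", {
  recs <- canon_records(a = 1:10)
  err <- expect_error(steady_state_average(recs, rel_tol = 0.01),
                      class = "leafflow_no_steady_state")
  expect_true(is.numeric(err$best_window))
})

test_that("unstable early readings are skipped for a later stable window", {
  recs <- canon_records(a = c(5, 9, 12, 12.1, 12.0, 12.05))
  avg <- steady_state_average(recs, rel_tol = 0.02)
  expect_equal(attr(avg, "window_start"), 3L)
  expect_equal(avg$A, mean(c(12, 12.1, 12.0)))
})

test_that("dark_respiration negates dark A readings into a magnitude", {
  recs <- dplyr::bind_rows(canon_records(a = 12),
                           canon_records(a = c(-1.1, -1.3, -1.2), i = 0))
  expect_equal(dark_respiration(recs), 1.2)
  expect_error(dark_respiration(canon_records(a = 12)),
               class = "leafflow_insufficient_data")
})

test_that("trait tables round-trip losslessly and reject duplicate keys", {
  tbl <- small_trait_table()
  path <- tempfile(fileext = ".csv")
  write_trait_table(tbl, path)
  back <- read_trait_table(path)
  expect_equal(back$value, tbl$value, tolerance = 1e-12)
  expect_identical(back[c("genotype", "replicate", "trait")],
                   tbl[c("genotype", "replicate", "trait")])

  dup <- dplyr::bind_rows(tbl, tbl[1, ])
  expect_error(write_trait_table(dup, tempfile()), class = "leafflow_data_error")

  empty <- tbl[0, ]
  p2 <- tempfile(fileext = ".csv")
  write_trait_table(empty, p2)
  expect_equal(nrow(read_trait_table(p2)), 0L)
})

test_that("dialects can be round-tripped through YAML", {
  path <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(A = "Photo", gs = "Cond", I = "PARi"), path)
  d <- read_dialect(path)
  expect_s3_class(d, "gasx_dialect")
  expect_equal(unname(d["A"]), "Photo")
  expect_error(gasx_dialect(nonsense = "x"), class = "leafflow_config_error")
})
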