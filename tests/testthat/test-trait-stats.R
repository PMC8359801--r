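test_that("percent_change is the plain relative difference on the percent scale", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(11.6, 10), 16)
  expect_error(percent_change(5, 0), class = "leafflow_domain_error")
  # invariant under common rescaling of units
  expect_equal(percent_change(11.6 * 1e3, 10 * 1e3), percent_change(11.6, 10))
})

test_that("the pooled t-test matches the closed form", {
  # closed-form pooled t computed independently of t.test
  a <- c(13, 14, 15); b <- c(10, 11, 12)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_cf <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_cf <- 2 * pt(-abs(t_cf), df = 4)

  res <- two_sample_t(a, b, variant = "pooled")
  expect_equal(res$t_stat, t_cf, tolerance = 1e-12)
  expect_equal(abs(res$t_stat), 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, p_cf, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0213, tolerance = 2e-3)

  ident <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t_stat, 0)
  expect_equal(ident$p_value, 1)

  expect_error(two_sample_t(5, c(1, 2)), class = "leafflow_insufficient_data")
})

test_that("swapping equal-size groups negates t and preserves p", {
  set.seed(14)
  a <- rnorm(6, 10); b <- rnorm(6, 11)
  r1 <- two_sample_t(a, b)
  r2 <- two_sample_t(b, a)
  expect_equal(r1$t_stat, -r2$t_stat)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("assumption checks are reported but never gate the test", {
  set.seed(3)
  skewed <- exp(rnorm(20, 0, 2))       # grossly non-normal
  normal <- rnorm(20, 5, 0.1)          # very different variance
  res <- two_sample_t(skewed, normal)
  expect_true(res$normality_check %in% c("pass", "fail"))
  expect_true(res$variance_check %in% c("pass", "fail"))
  expect_false(is.na(res$p_value))
})

test_that("standardized PCA has unit-trace eigenstructure and fixed signs", {
  tbl <- small_trait_table()
  pca <- pca_traits(tbl)
  expect_equal(sum(pca$eigenvalues), 3)              # trace of 3x3 correlation
  expect_equal(sum(pca$variance_explained), 1)
  # orthonormal loadings
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: per component, largest-|loading| entry is positive
  for (j in 1:3) {
    lj <- pca$loadings[, j]
    expect_gt(lj[which.max(abs(lj))], 0)
  }
})

test_that("PCA matches a direct eigendecomposition of the correlation matrix", {
  set.seed(3)
  X <- matrix(rnorm(24 * 11), 24, 11)
  tbl <- dplyr::bind_rows(lapply(1:24, function(i) {
    tibble::tibble(genotype = paste0("G", (i - 1) %/% 6 + 1),
                   replicate = (i - 1) %% 6 + 1,
                   trait = paste0("t", 1:11), value = X[i, ])
  }))
  pca <- pca_traits(tbl)
  eig <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(pca$eigenvalues, eig, tolerance = 1e-10)
  expect_true(all(pca$eigenvalues > 0.2 & pca$eigenvalues < 2.5))
})

test_that("two perfectly correlated traits load entirely on PC1", {
  tbl <- dplyr::bind_rows(lapply(1:6, function(r) {
    tibble::tibble(genotype = "WT", replicate = r,
                   trait = c("x", "y"), value = c(r, 2 * r + 1))
  }))
  pca <- pca_traits(tbl)
  expect_equal(pca$variance_explained[1], 1, tolerance = 1e-12)
})

test_that("PCA variance explained is invariant to trait order and affine rescaling", {
  tbl <- small_trait_table()
  base <- pca_traits(tbl, traits = c("A", "gs", "dry_weight"))
  perm <- pca_traits(tbl, traits = c("dry_weight", "A", "gs"))
  expect_equal(base$variance_explained, perm$variance_explained, tolerance = 1e-12)
  scaled <- tbl
  scaled$value[scaled$trait == "A"] <- 100 * scaled$value[scaled$trait == "A"] + 7
  resc <- pca_traits(scaled, traits = c("A", "gs", "dry_weight"))
  expect_equal(base$variance_explained, resc$variance_explained, tolerance = 1e-12)
})

test_that("PCA rejects constant traits and names them", {
  tbl <- small_trait_table()
  tbl$value[tbl$trait == "gs"] <- 0.25
  err <- expect_error(pca_traits(tbl), class = "leafflow_degenerate_fit")
  expect_match(conditionMessage(err), "gs")
})

test_that("germination index has ratio and time-weighted modes", {
  expect_equal(germination_index(c(10, 30, 40), c(10, 30, 40)), 100)
  expect_equal(germination_index(c(10, 20, 30), c(15, 30, 40)), 75)
  expect_error(germination_index(c(1, 2), c(0, 0)), class = "leafflow_domain_error")
  # timed mode rewards early germination
  early <- germination_index(c(30, 35, 40), c(10, 20, 40), method = "timed")
  late <- germination_index(c(5, 10, 40), c(10, 20, 40), method = "timed")
  expect_gt(early, late)
  expect_equal(germination_index(c(20, 40), c(20, 40), method = "timed"), 100)
})

test_that("study_report compares every genotype to the reference", {
  tbl <- small_trait_table()
  rep <- study_report(tbl, reference = "WT")
  expect_s3_class(rep, "study_report")
  expect_equal(sort(unique(rep$comparisons$trait)), c("A", "dry_weight", "gs"))
  expect_equal(unique(rep$comparisons$genotype), "GD")
  a_row <- rep$comparisons[rep$comparisons$trait == "A", ]
  expect_gt(a_row$percent_change, 5)     # configured +16% effect, cv 5%
  expect_false(is.null(rep$pca))
  expect_true(any(grepl("PCA", rep$summary)))

  expect_error(study_report(tbl, reference = "ZZ"), class = "leafflow_config_error")
  solo <- tbl[tbl$genotype == "WT", ]
  rep2 <- study_report(solo, reference = "WT")
  expect_equal(nrow(rep2$comparisons), 0L)
})

test_that("report bundles are written as delimited text", {
  tbl <- small_trait_table()
  dir <- file.path(tempdir(), "report_bundle")
  rep <- study_report(tbl)
  write_study_report(rep, dir)
  expect_true(file.exists(file.path(dir, "comparisons.tsv")))
  expect_true(file.exists(file.path(dir, "pca_loadings.tsv")))
  expect_true(file.exists(file.path(dir, "pca_variance.tsv")))
  expect_true(file.exists(file.path(dir, "summary.txt")))
  back <- readr::read_tsv(file.path(dir, "comparisons.tsv"), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep$comparisons))
})
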