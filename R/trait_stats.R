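#' Percent change versus a reference mean
#'
#' `100 * (mean_t - mean_ref) / mean_ref`, the reporting convention used for
#' genotype-vs-wild-type comparisons throughout the package.
#'
#' @param mean_t Treatment (e.g. transgenic line) mean. Vectorized.
#' @param mean_ref Reference (e.g. wild type) mean; must be nonzero.
#' @return Percent change (a plain number on the percent scale).
#' @examples
#' percent_change(11.6, 10)  # 16
#' @export
percent_change <- function(mean_t, mean_ref) {
  if (any(!is.na(mean_ref) & mean_ref == 0)) {
    abort("`mean_ref` must be nonzero.", class = "leafflow_domain_error")
  }
  100 * (mean_t - mean_ref) / mean_ref
}

#' Two-sample t-test with assumption checks
#'
#' Two-sided two-sample t-test of `group` against `reference`, pooled
#' (equal-variance Student) by default or Welch. Normality (Shapiro-Wilk on
#' each group) and variance homogeneity (Levene) are checked and reported
#' alongside the test but never gate it: the columns record whether the
#' classical assumptions looked tenable, the p-value is always that of the
#' requested test.
#'
#' @param group Numeric values for the comparison group (>= 2).
#' @param reference Numeric values for the reference group (>= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param check_alpha Significance level for the assumption checks
#'   (default 0.05).
#' @return A one-row tibble: `mean_t`, `mean_ref`, `percent_change`,
#'   `t_stat`, `df`, `p_value`, `variance_check`, `normality_check`
#'   (`"pass"`/`"fail"`, `NA` when a check cannot run).
#' @examples
#' two_sample_t(c(13, 14, 15), c(10, 11, 12))
#' @export
two_sample_t <- function(group, reference, variant = c("pooled", "welch"),
                         check_alpha = 0.05) {
  variant <- match.arg(variant)
  group <- group[!is.na(group)]
  reference <- reference[!is.na(reference)]
  if (length(group) < 2L || length(reference) < 2L) {
    abort("Both groups need at least 2 values.",
          class = "leafflow_insufficient_data")
  }
  tt <- t.test(group, reference, var.equal = (variant == "pooled"))
  normality <- tryCatch({
    p1 <- if (sd(group) > 0) shapiro.test(group)$p.value else NA_real_
    p2 <- if (sd(reference) > 0) shapiro.test(reference)$p.value else NA_real_
    if (is.na(p1) || is.na(p2)) NA_character_
    else if (min(p1, p2) > check_alpha) "pass" else "fail"
  }, error = function(e) NA_character_)
  variance <- tryCatch({
    dat <- data.frame(y = c(group, reference),
                      g = factor(rep(c("t", "ref"), c(length(group), length(reference)))))
    p <- car::leveneTest(y ~ g, data = dat)[["Pr(>F)"]][1]
    if (is.na(p)) NA_character_ else if (p > check_alpha) "pass" else "fail"
  }, error = function(e) NA_character_)
  tibble::tibble(
    mean_t = mean(group), mean_ref = mean(reference),
    percent_change = percent_change(mean(group), mean(reference)),
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    variance_check = variance, normality_check = normality
  )
}

#' Standardized PCA over a trait table
#'
#' Principal component analysis of the correlation matrix (traits z-scored),
#' with observations either individual replicates (default) or genotype
#' means. Rows with missing cells among the selected traits are dropped with
#' a warning; a constant trait is an error because it cannot be
#' standardized. Because an eigenvector's sign is arbitrary, each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param table A trait table (`genotype`, `replicate`, `trait`, `value`).
#' @param traits Traits to include; default all traits present.
#' @param observation_unit `"replicate"` or `"genotype_mean"`.
#' @return An object of class `trait_pca`: `loadings` (trait x component
#'   matrix), `eigenvalues`, `variance_explained` (fractions summing to 1),
#'   `scores` (tibble with identifiers), `observation_unit`,
#'   `sign_convention`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
pca_traits <- function(table, traits = NULL,
                       observation_unit = c("replicate", "genotype_mean")) {
  observation_unit <- match.arg(observation_unit)
  table <- validate_trait_table(table)
  traits <- traits %||% unique(table$trait)
  missing_tr <- setdiff(traits, unique(table$trait))
  if (length(missing_tr)) {
    abort(paste0("Trait(s) not in table: ", paste(missing_tr, collapse = ", ")),
          class = "leafflow_config_error")
  }
  table <- table[table$trait %in% traits, , drop = FALSE]
  if (observation_unit == "genotype_mean") {
    table <- table |>
      dplyr::group_by(.data$genotype, .data$trait) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(replicate = 1L)
  }
  wide <- tidyr::pivot_wider(table, id_cols = c("genotype", "replicate"),
                             names_from = "trait", values_from = "value")
  wide <- wide[, c("genotype", "replicate", traits)]
  complete <- stats::complete.cases(wide[traits])
  if (!all(complete)) {
    warn(paste0(sum(!complete), " observation(s) dropped for missing trait values."))
    wide <- wide[complete, , drop = FALSE]
  }
  if (nrow(wide) < 2L) {
    abort("PCA needs at least 2 complete observations.",
          class = "leafflow_insufficient_data")
  }
  X <- as.matrix(wide[traits])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant trait(s) cannot be standardized: ",
                 paste(traits[sds == 0], collapse = ", ")),
          class = "leafflow_degenerate_fit")
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- pc$sdev^2
  structure(list(
    loadings = load,
    eigenvalues = eig,
    variance_explained = eig / sum(eig),
    scores = dplyr::bind_cols(wide[c("genotype", "replicate")],
                              tibble::as_tibble(scores)),
    observation_unit = observation_unit,
    sign_convention = "largest-|loading| trait positive per component",
    n_obs = nrow(wide), traits = traits
  ), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Standardized trait PCA (", x$observation_unit, " level, n = ",
      x$n_obs, ", ", length(x$traits), " traits)\n", sep = "")
  ve <- round(100 * x$variance_explained[1:min(3, length(x$variance_explained))], 1)
  cat("  variance explained:", paste0("PC", seq_along(ve), " ", ve, "%", collapse = ", "), "\n")
  cat("  loadings:\n")
  print(round(x$loadings[, seq_len(min(3, ncol(x$loadings))), drop = FALSE], 3))
  invisible(x)
}

#' @rdname pca_traits
#' @param x A `trait_pca` object.
#' @param ... Unused.
#' @export
tidy.trait_pca <- function(x, ...) {
  tibble::tibble(
    trait = rep(rownames(x$loadings), ncol(x$loadings)),
    component = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' @rdname pca_traits
#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_traits = length(x$traits),
    eigenvalue_sum = sum(x$eigenvalues),
    pc1_var = x$variance_explained[1],
    pc2_var = if (length(x$variance_explained) > 1) x$variance_explained[2] else NA_real_,
    observation_unit = x$observation_unit
  )
}

#' Germination stress-tolerance index
#'
#' Summarizes a germination time course under stress relative to control.
#' Method `"ratio"` (default) is 100 x final germinated under stress over
#' final germinated in control. Method `"timed"` weights earlier
#' germination more, as a promptness-index ratio with weights 1/time:
#' 100 x sum(stress_i / t_i) / sum(control_i / t_i) over the common
#' observation times.
#'
#' @param germinated_stress,germinated_control Cumulative germinated counts
#'   at the same observation times.
#' @param method `"ratio"` or `"timed"`.
#' @param times Observation times (days); defaults to 1, 2, ... Only used by
#'   `"timed"`.
#' @return The index (dimensionless, 100 = no stress effect).
#' @examples
#' germination_index(c(10, 20, 30), c(15, 30, 40))  # 75
#' @export
germination_index <- function(germinated_stress, germinated_control,
                              method = c("ratio", "timed"), times = NULL) {
  method <- match.arg(method)
  if (length(germinated_stress) != length(germinated_control)) {
    abort("Stress and control counts must share observation times.",
          class = "leafflow_config_error")
  }
  if (any(germinated_stress < 0) || any(germinated_control < 0)) {
    abort("Counts must be non-negative.", class = "leafflow_domain_error")
  }
  n <- length(germinated_control)
  if (!n || germinated_control[n] == 0) {
    abort("Final control count must be > 0.", class = "leafflow_domain_error")
  }
  if (method == "ratio") {
    100 * germinated_stress[n] / germinated_control[n]
  } else {
    times <- times %||% seq_len(n)
    if (any(times <= 0)) {
      abort("`times` must be positive.", class = "leafflow_domain_error")
    }
    100 * sum(germinated_stress / times) / sum(germinated_control / times)
  }
}

#' Study-level comparison report
#'
#' For every (trait, genotype) other than the reference genotype, runs
#' [two_sample_t()] against the reference and reports the percent change;
#' optionally adds a standardized PCA over the traits. This is the
#' study-level summary a genotype-comparison experiment reports: per-trait
#' means, percent change vs wild type, t statistics, and the trait loadings
#' of the leading principal components.
#'
#' @param table A trait table.
#' @param reference Reference genotype (default `"WT"`).
#' @param traits Traits to analyze; default all.
#' @param t_variant `"pooled"` or `"welch"`.
#' @param p_adjust Multiple-testing adjustment method for [stats::p.adjust()]
#'   (default `"none"`, matching per-trait testing at P < 0.05; `"holm"`
#'   available).
#' @param pca Logical; include [pca_traits()] output (default `TRUE`, skipped
#'   with a message when fewer than 2 genotypes or observations).
#' @param pca_unit Observation unit for the PCA.
#' @return A list of class `study_report`: `comparisons` (tibble with
#'   `trait`, `genotype`, `reference`, the [two_sample_t()] columns and
#'   `p_adjusted`), `pca` (a `trait_pca` or `NULL`), `reference`, `summary`
#'   (character lines).
#' @export
study_report <- function(table, reference = "WT", traits = NULL,
                         t_variant = c("pooled", "welch"),
                         p_adjust = "none", pca = TRUE,
                         pca_unit = c("replicate", "genotype_mean")) {
  t_variant <- match.arg(t_variant)
  pca_unit <- match.arg(pca_unit)
  table <- validate_trait_table(table)
  traits <- traits %||% unique(table$trait)
  genos <- unique(table$genotype)
  if (!reference %in% genos) {
    abort(paste0("Reference genotype `", reference, "` not present in the table."),
          class = "leafflow_config_error")
  }
  others <- setdiff(genos, reference)
  comps <- list()
  for (tr in traits) {
    ref_vals <- table$value[table$genotype == reference & table$trait == tr]
    for (g in others) {
      g_vals <- table$value[table$genotype == g & table$trait == tr]
      row <- two_sample_t(g_vals, ref_vals, variant = t_variant)
      comps[[length(comps) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(trait = tr, genotype = g,
                                        reference = reference), row)
    }
  }
  comparisons <- if (length(comps)) dplyr::bind_rows(comps) else
    tibble::tibble(trait = character(), genotype = character(),
                   reference = character(), mean_t = double(),
                   mean_ref = double(), percent_change = double(),
                   t_stat = double(), df = double(), p_value = double(),
                   variance_check = character(), normality_check = character())
  comparisons$p_adjusted <- if (nrow(comparisons)) {
    stats::p.adjust(comparisons$p_value, method = p_adjust)
  } else double()
  pca_res <- NULL
  if (isTRUE(pca)) {
    pca_res <- tryCatch(pca_traits(table, traits, observation_unit = pca_unit),
                        error = function(e) {
                          message("PCA skipped: ", conditionMessage(e))
                          NULL
                        })
  }
  structure(list(comparisons = comparisons, pca = pca_res,
                 reference = reference,
                 summary = report_summary_lines(comparisons, pca_res, reference)),
            class = "study_report")
}

report_summary_lines <- function(comparisons, pca_res, reference) {
  lines <- paste0("Study report (reference genotype: ", reference, ")")
  if (nrow(comparisons)) {
    for (i in seq_len(nrow(comparisons))) {
      r <- comparisons[i, ]
      lines <- c(lines, sprintf(
        "  %s, %s vs %s: %+.1f%% (t = %.3f, df = %.3g, P = %.4g)%s",
        r$trait, r$genotype, r$reference, r$percent_change, r$t_stat, r$df,
        r$p_value, if (!is.na(r$p_value) && r$p_value < 0.05) " *" else ""))
    }
  } else {
    lines <- c(lines, "  (no non-reference genotypes: no comparisons)")
  }
  if (!is.null(pca_res)) {
    ve <- pca_res$variance_explained
    lines <- c(lines, sprintf(
      "  PCA (%s level): PC1 %.1f%%, PC2 %s of variance",
      pca_res$observation_unit, 100 * ve[1],
      if (length(ve) > 1) sprintf("%.1f%%", 100 * ve[2]) else "-"))
  }
  lines
}

#' @export
print.study_report <- function(x, ...) {
  writeLines(x$summary)
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Writes `comparisons.tsv`, `summary.txt`, and (when a PCA is present)
#' `pca_loadings.tsv` and `pca_variance.tsv` into `dir`.
#'
#' @param report A [study_report()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$comparisons, file.path(dir, "comparisons.tsv"))
  if (!is.null(report$pca)) {
    readr::write_tsv(tidy(report$pca), file.path(dir, "pca_loadings.tsv"))
    readr::write_tsv(
      tibble::tibble(component = colnames(report$pca$loadings),
                     eigenvalue = report$pca$eigenvalues,
                     variance_explained = report$pca$variance_explained),
      file.path(dir, "pca_variance.tsv"))
  }
  writeLines(report$summary, file.path(dir, "summary.txt"))
  invisible(dir)
}
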