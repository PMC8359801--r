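#' Calibrate the PSII-CO2 quantum-efficiency relation
#'
#' Under non-photorespiratory conditions (2% O2), essentially all linear
#' electron flow serves carboxylation, so the PSII operating efficiency is a
#' linear function of the quantum efficiency of CO2 fixation:
#' \deqn{\Phi_{PSII} = k\,\Phi_{CO2} + b = \tfrac{k}{4}\,\Phi_{e^-} + b}
#' with 4 electrons per CO2 fixed. This fits that line per leaf by ordinary
#' least squares of `phi_psii` on `phi_co2` across the light-response steps,
#' giving the slope `k` and intercept `b` used later to invert observed
#' \eqn{\Phi_{PSII}} into \eqn{\Phi_{e^-}} under ambient (21% O2) air.
#'
#' @param df Tibble with columns `phi_co2` and `phi_psii` (one calibration
#'   point per row; typically one row per light step). A column `I` is used,
#'   if present, to record the light levels.
#' @param leaf_id Identifier stored with the fit; defaults to the `plant_id`
#'   column when present.
#' @param mode The [phi_co2()] convention the points were computed with;
#'   recorded as provenance.
#' @return An object of class `phi_calibration` with elements `leaf_id`, `k`
#'   (slope), `b` (intercept), `n_points`, `r_squared`, `residual_sd`,
#'   `light_levels_used`, `mode`, and the underlying `lm` fit. A
#'   non-positive slope is physically meaningless and is flagged
#'   (`flag = "nonpositive_slope"`), not rejected.
#' @examples
#' pts <- tibble::tibble(phi_co2 = c(0.01, 0.03, 0.06, 0.08),
#'                       phi_psii = 9 * c(0.01, 0.03, 0.06, 0.08) + 0.05)
#' fit <- fit_phi_relation(pts)
#' glance(fit)
#' @export
fit_phi_relation <- function(df, leaf_id = NULL, mode = "gross") {
  if (!all(c("phi_co2", "phi_psii") %in% names(df))) {
    abort("`df` must have columns `phi_co2` and `phi_psii`.",
          class = "leafflow_config_error")
  }
  df <- df[stats::complete.cases(df[c("phi_co2", "phi_psii")]), , drop = FALSE]
  if (nrow(df) < 3L) {
    abort(paste0("Calibration needs >= 3 points, got ", nrow(df), "."),
          class = "leafflow_insufficient_data")
  }
  if (sd(df$phi_co2) == 0) {
    abort("Degenerate calibration: zero variance in phi_co2.",
          class = "leafflow_degenerate_fit")
  }
  leaf_id <- leaf_id %||% (if ("plant_id" %in% names(df)) as.character(df$plant_id[1]) else NA_character_)
  fit <- lm(phi_psii ~ phi_co2, data = df)
  k <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  # exact (noise-free) calibrations are a supported case: silence lm's
  # perfect-fit warning only
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  flag <- if (k <= 0) "nonpositive_slope" else character(0)
  if (length(flag)) warn(paste0("Calibration slope k = ", signif(k, 4),
                                " is not positive (leaf ", leaf_id, ")."))
  structure(list(
    leaf_id = leaf_id, k = k, b = b, n_points = nrow(df),
    r_squared = sm$r.squared, residual_sd = sm$sigma,
    light_levels_used = if ("I" %in% names(df)) sort(unique(df$I), decreasing = TRUE) else numeric(0),
    mode = mode, flag = flag, fit = fit, data = tibble::as_tibble(df)
  ), class = "phi_calibration")
}

#' @export
print.phi_calibration <- function(x, ...) {
  cat("Phi_PSII ~ Phi_CO2 calibration", if (!is.na(x$leaf_id)) paste0("(leaf ", x$leaf_id, ")"), "\n")
  cat(sprintf("  k = %.5g, b = %.5g  (n = %d, R2 = %.4f, resid sd = %.3g)\n",
              x$k, x$b, x$n_points, x$r_squared, x$residual_sd))
  cat("  phi_co2 mode:", x$mode, "\n")
  if (length(x$flag)) cat("  flags:", paste(x$flag, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_phi_relation
#' @param x A `phi_calibration` object.
#' @param ... Unused.
#' @export
tidy.phi_calibration <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("b (intercept)", "k (slope)"),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' @rdname fit_phi_relation
#' @export
glance.phi_calibration <- function(x, ...) {
  tibble::tibble(
    leaf_id = x$leaf_id, k = x$k, b = x$b, n_points = x$n_points,
    r_squared = x$r_squared, residual_sd = x$residual_sd,
    phi_co2_mode = x$mode,
    flags = paste(x$flag, collapse = ",")
  )
}

#' Quantum efficiency of linear electron flow
#'
#' Inverts the calibrated line: \eqn{\Phi_{e^-} = 4(\Phi_{PSII} - b)/k}.
#'
#' @param phi_psii Observed PSII operating efficiency (vectorized).
#' @param fit A `phi_calibration`, or anything with elements `k` and `b`.
#' @return Dimensionless quantum efficiency of linear electron flow.
#' @export
phi_e <- function(phi_psii, fit) {
  k <- if (is.list(fit)) fit$k else fit
  b <- if (is.list(fit)) fit$b else 0
  if (is.na(k) || k == 0) {
    abort("Calibration slope k must be nonzero.", class = "leafflow_domain_error")
  }
  4 * (phi_psii - b) / k
}

#' Total linear electron flow
#'
#' \deqn{J_T = I\,\alpha_{leaf}\,\Phi_{e^-}}
#'
#' @param i Incident photon flux density, umol m-2 s-1 (>= 0).
#' @param phi_e Quantum efficiency of linear electron flow.
#' @param consts A [fluoro_constants()] object.
#' @return J_T in umol electrons m-2 s-1.
#' @export
total_electron_flow <- function(i, phi_e, consts = fluoro_constants()) {
  consts <- as_fluoro_constants(consts)
  if (any(!is.na(i) & i < 0)) {
    abort("Photon flux `i` must be >= 0.", class = "leafflow_domain_error")
  }
  i * consts$alpha_leaf * phi_e
}

#' Partition electron flow into carboxylation and oxygenation
#'
#' Given total linear electron flow J_T, net assimilation A and day
#' respiration R_l, solves the electron-flow budget
#' \eqn{J_T = J_C + J_O}, \eqn{J_C = 4(A + R_l + Pr)}, \eqn{J_O = 8 Pr}
#' (4 electrons per CO2 fixed; one CO2 released per two RuBP oxygenations)
#' for the flows attributable to carboxylation and oxygenation:
#' \deqn{J_C = \tfrac13\,[J_T + 8(A + R_l)]}
#' \deqn{J_O = \tfrac23\,[J_T - 4(A + R_l)]}
#' \deqn{Pr = \tfrac1{12}\,[J_T - 4(A + R_l)]}
#' and reports gross photosynthesis \eqn{A_{gross} = A + R_l + Pr} with the
#' ratios Pr/A_gross and J_C/J_O.
#'
#' Negative Pr (possible under measurement noise when J_T < 4(A + R_l)) is
#' reported as-is with flag `negative_oxygenation`, never clipped, so group
#' statistics computed downstream stay unbiased. J_O = 0 yields an infinite
#' J_C/J_O with flag `jo_zero`; A_gross = 0 yields flag `agross_zero`.
#'
#' @param jt Total electron flow, umol e- m-2 s-1 (vectorized).
#' @param a Net assimilation, umol CO2 m-2 s-1.
#' @param rl Respiration in the light, umol CO2 m-2 s-1.
#' @return A tibble with columns `jt`, `jc`, `jo`, `pr`, `a_gross`,
#'   `pr_over_agross`, `jc_over_jo`, `flags`.
#' @examples
#' partition_flows(jt = 100, a = 15, rl = 1)
#' @export
partition_flows <- function(jt, a, rl) {
  if (any(!is.finite(jt)) || any(!is.finite(a)) || any(!is.finite(rl))) {
    abort("`jt`, `a`, `rl` must be finite.", class = "leafflow_domain_error")
  }
  anr <- a + rl
  jc <- (jt + 8 * anr) / 3
  jo <- 2 * (jt - 4 * anr) / 3
  pr <- (jt - 4 * anr) / 12
  a_gross <- a + rl + pr
  pr_over_agross <- ifelse(a_gross == 0, NA_real_, pr / a_gross)
  jc_over_jo <- ifelse(jo == 0, Inf, jc / jo)
  flags <- mapply(function(p, o, ag) {
    f <- character(0)
    if (p < 0 || o < 0) f <- c(f, "negative_oxygenation")
    if (o == 0) f <- c(f, "jo_zero")
    if (ag == 0) f <- c(f, "agross_zero")
    paste(f, collapse = ",")
  }, pr, jo, a_gross)
  tibble::tibble(jt = jt, jc = jc, jo = jo, pr = pr, a_gross = a_gross,
                 pr_over_agross = pr_over_agross, jc_over_jo = jc_over_jo,
                 flags = unname(flags))
}

#' Run the full partition chain for one leaf
#'
#' Composes the whole per-leaf analysis: fluorometry on the 2%-O2
#' light-response records, per-leaf calibration of the
#' \eqn{\Phi_{PSII}}-\eqn{\Phi_{CO2}} line ([fit_phi_relation()]), inversion
#' of the ambient-air (21% O2) steady state into \eqn{\Phi_{e^-}} and J_T,
#' and the carboxylation/oxygenation partition ([partition_flows()]).
#'
#' Calibration readings sharing a light level are averaged before the fit by
#' default (`average_per_light = TRUE`); the ambient-air records are averaged
#' into a single steady state. Both phases use the same R_l = `rl_factor` x
#' `rd`, measured once per leaf in darkness at ambient O2.
#'
#' @param calib Tibble of gas-exchange records for the 2%-O2 light curve
#'   (columns `A`, `I`, `Fs`, `Fm_prime`, optionally `plant_id`).
#' @param meas Tibble (one or more readings) of the ambient-air steady state.
#' @param rd Dark respiration magnitude for this leaf.
#' @param consts A [fluoro_constants()] object.
#' @param mode [phi_co2()] convention used for the calibration regressor.
#'   Default `"gross"`: with A + R_l equal to carboxylation minus the
#'   photorespiratory release, the calibration points lie exactly on the
#'   assumed line; the `"as_printed"` net form adds a light-dependent
#'   respiration term that curves them (see vignette).
#' @param rl_factor Light-suppression factor for respiration (default 0.5).
#' @param average_per_light Average calibration readings per light step
#'   before fitting.
#' @return A list of class `leaf_partition`: `calibration` (the
#'   `phi_calibration`) and `result`, a one-row tibble with `leaf_id`, `k`,
#'   `b`, `r_squared`, `phi_psii`, `phi_e`, and the [partition_flows()]
#'   columns.
#' @export
run_leaf <- function(calib, meas, rd, consts = fluoro_constants(),
                     mode = c("gross", "as_printed"), rl_factor = 0.5,
                     average_per_light = TRUE) {
  mode <- match.arg(mode)
  consts <- as_fluoro_constants(consts)
  leaf_id <- if ("plant_id" %in% names(meas)) as.character(meas$plant_id[1]) else NA_character_
  if (is.null(calib) || !nrow(calib)) {
    abort(paste0("Leaf ", leaf_id, ": no calibration records."),
          class = "leafflow_insufficient_data")
  }
  if (!nrow(meas)) {
    abort(paste0("Leaf ", leaf_id, ": no ambient-air measurement records."),
          class = "leafflow_insufficient_data")
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("Leaf ", leaf_id, " [", name, "]: ", conditionMessage(e)),
              class = class(e)[1], parent = e)
      }),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  calib_fl <- stage("fluorometry", derive_fluorometry(calib, rd, consts, mode, rl_factor))
  if (average_per_light && "I" %in% names(calib_fl)) {
    calib_fl <- calib_fl |>
      dplyr::group_by(.data$I) |>
      dplyr::summarise(phi_co2 = mean(.data$phi_co2),
                       phi_psii = mean(.data$phi_psii), .groups = "drop")
  }
  fit <- stage("calibration", fit_phi_relation(calib_fl, leaf_id = leaf_id, mode = mode))
  # ambient-air steady state: plain mean of the supplied readings
  mvars <- intersect(c("A", "I", "Fs", "Fm_prime"), names(meas))
  m <- lapply(meas[mvars], mean)
  rl <- light_respiration(rd, rl_factor)
  pp <- stage("fluorometry", phi_psii(m$Fs, m$Fm_prime))
  fe <- stage("phi_e", phi_e(pp, fit))
  jt <- stage("total_electron_flow", total_electron_flow(m$I, fe, consts))
  part <- stage("partition", partition_flows(jt, m$A, rl))
  result <- dplyr::bind_cols(
    tibble::tibble(leaf_id = leaf_id, k = fit$k, b = fit$b,
                   r_squared = fit$r_squared, phi_psii = pp, phi_e = fe,
                   a = m$A, rl = rl),
    part
  )
  structure(list(calibration = fit, result = result), class = "leaf_partition")
}

#' @export
print.leaf_partition <- function(x, ...) {
  print(x$calibration)
  cat("\nPartition:\n")
  print(x$result)
  invisible(x)
}

#' Partition every leaf in a measurement set
#'
#' Splits calibration and ambient-air measurement tables by `plant_id`, runs
#' [run_leaf()] on each leaf, and binds the per-leaf results into one tibble.
#' Dark respiration is taken from `rd` (a named vector or a tibble with
#' columns `plant_id`, `rd`), or, when `rd` is `NULL`, derived per leaf from
#' dark readings (I ~ 0) present in `meas` via [dark_respiration()].
#'
#' @param calib Calibration (2% O2) records for all leaves, with `plant_id`.
#' @param meas Ambient-air (21% O2) records for all leaves, with `plant_id`.
#' @param rd Dark respiration per leaf; named numeric vector, tibble, or
#'   `NULL` to derive from dark readings in `meas`.
#' @inheritParams run_leaf
#' @return A tibble with one row per leaf: `leaf_id`, `genotype` (when
#'   present in `meas`), calibration `k`, `b`, `r_squared`, and the
#'   partition columns of [partition_flows()]. Leaves whose chain fails are
#'   reported with `NA` values and the error message in `flags`.
#' @export
partition_leaves <- function(calib, meas, rd = NULL,
                             consts = fluoro_constants(),
                             mode = c("gross", "as_printed"),
                             rl_factor = 0.5, average_per_light = TRUE) {
  mode <- match.arg(mode)
  if (!"plant_id" %in% names(meas) || !"plant_id" %in% names(calib)) {
    abort("Both tables need a `plant_id` column.", class = "leafflow_config_error")
  }
  ids <- unique(as.character(meas$plant_id))
  rd_tbl <- NULL
  if (!is.null(rd)) {
    rd_tbl <- if (is.data.frame(rd)) setNames(rd$rd, rd$plant_id) else rd
  }
  rows <- lapply(ids, function(id) {
    m_all <- meas[meas$plant_id == id, , drop = FALSE]
    is_dark <- !is.na(m_all$I) & m_all$I <= 5
    m <- m_all[!is_dark, , drop = FALSE]
    cl <- calib[calib$plant_id == id, , drop = FALSE]
    geno <- if ("genotype" %in% names(m_all)) as.character(m_all$genotype[1]) else NA_character_
    res <- tryCatch({
      rd_i <- if (!is.null(rd_tbl)) {
        if (id %in% names(rd_tbl)) unname(rd_tbl[[id]]) else NA_real_
      } else {
        dark_respiration(m_all)
      }
      if (is.null(rd_i) || is.na(rd_i)) {
        abort(paste0("No dark respiration available for leaf ", id, "."),
              class = "leafflow_insufficient_data")
      }
      run_leaf(cl, m, rd_i, consts, mode, rl_factor, average_per_light)$result
    }, error = function(e) {
      tibble::tibble(leaf_id = id, k = NA_real_, b = NA_real_,
                     r_squared = NA_real_, phi_psii = NA_real_,
                     phi_e = NA_real_, a = NA_real_, rl = NA_real_,
                     jt = NA_real_, jc = NA_real_, jo = NA_real_,
                     pr = NA_real_, a_gross = NA_real_,
                     pr_over_agross = NA_real_, jc_over_jo = NA_real_,
                     flags = paste0("error: ", conditionMessage(e)))
    })
    res$genotype <- geno
    res
  })
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "leaf_id", "genotype")
}
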