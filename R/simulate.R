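#' Configuration for the synthetic-leaf simulator
#'
#' Defines the ground-truth physiology of a simulated C3 leaf. Potential
#' linear electron flow at incident light I follows a non-rectangular
#' hyperbola, the smaller root of
#' \deqn{\theta J^2 - (\phi_{e,0} I + J_{max}) J + \phi_{e,0} I J_{max} = 0,}
#' with initial slope `quantum_yield_e` (electrons per incident photon),
#' asymptote `jmax` and curvature `theta`. At a given O2 level the
#' oxygenation-to-carboxylation ratio is `phi_ox` (ambient, 21% O2) or
#' `phi_ox_low_o2` (2% O2); electron flow is split as
#' \eqn{V_c = J / (4(1+\phi))}, \eqn{V_o = \phi V_c}, and net assimilation is
#' \eqn{A = V_c - 0.5 V_o - R_d/2}. Fluorescence is emulated through the
#' linear calibration relation itself, \eqn{\Phi_{PSII} =
#' b_{true} + (k_{true}/4)\,\Phi_{e^-}} with \eqn{\Phi_{e^-} =
#' J/(I \alpha_{leaf})}, so that calibration recovery is exactly testable;
#' Fm' is fixed at 1000 instrument units and Fs = Fm' (1 - Phi_PSII).
#'
#' Defaults emulate the measurement protocol of a light-response calibration
#' under 2% O2 followed by an ambient steady state: light steps 1000, 750,
#' 500, 300, 200, 100, 50 umol m-2 s-1, three readings per step, Gaussian
#' observation noise with sd 0.01 on Phi_PSII and 0.3 umol m-2 s-1 on A.
#' `phi_ox_low_o2` defaults to 0.01 (small residual oxygenation at 2% O2);
#' set it to 0 for exact round-trip tests.
#'
#' @param jmax Maximal potential electron transport, umol e- m-2 s-1.
#' @param quantum_yield_e Initial slope of J(I), e- per incident photon.
#' @param theta Curvature of the non-rectangular hyperbola, in (0, 1].
#' @param phi_ox Vo/Vc at ambient (21%) O2.
#' @param phi_ox_low_o2 Vo/Vc at 2% O2 (must be < `phi_ox`).
#' @param rd_true Dark respiration magnitude, umol CO2 m-2 s-1.
#' @param k_true,b_true True slope and intercept of the
#'   \eqn{\Phi_{PSII}}-\eqn{\Phi_{CO2}} calibration line.
#' @param noise_phi_psii,noise_a Gaussian observation noise sd on Phi_PSII
#'   (dimensionless) and A (umol m-2 s-1).
#' @param light_steps Light sequence for a light-response run.
#' @param readings_per_step Readings logged per light step.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param consts [fluoro_constants()] used by the emulator.
#' @return A validated list of class `leaf_sim_config`.
#' @export
leaf_sim_config <- function(jmax = 120, quantum_yield_e = 0.3, theta = 0.7,
                            phi_ox = 0.25, phi_ox_low_o2 = 0.01,
                            rd_true = 1.0, k_true = 9, b_true = 0.05,
                            noise_phi_psii = 0.01, noise_a = 0.3,
                            light_steps = c(1000, 750, 500, 300, 200, 100, 50),
                            readings_per_step = 3L, seed = NULL,
                            consts = fluoro_constants()) {
  cfg <- list(jmax = jmax, quantum_yield_e = quantum_yield_e, theta = theta,
              phi_ox = phi_ox, phi_ox_low_o2 = phi_ox_low_o2,
              rd_true = rd_true, k_true = k_true, b_true = b_true,
              noise_phi_psii = noise_phi_psii, noise_a = noise_a,
              light_steps = light_steps,
              readings_per_step = as.integer(readings_per_step),
              seed = seed, consts = as_fluoro_constants(consts))
  with(cfg, {
    if (jmax < 0 || quantum_yield_e < 0 || rd_true < 0 || phi_ox < 0 ||
        phi_ox_low_o2 < 0 || noise_phi_psii < 0 || noise_a < 0) {
      abort("All rates and noise sds must be >= 0.", class = "leafflow_config_error")
    }
    if (theta <= 0 || theta > 1) {
      abort("`theta` must be in (0, 1].", class = "leafflow_config_error")
    }
    if (phi_ox_low_o2 >= phi_ox && phi_ox > 0) {
      abort("`phi_ox_low_o2` must be < `phi_ox`.", class = "leafflow_config_error")
    }
    if (readings_per_step < 1L) {
      abort("`readings_per_step` must be >= 1.", class = "leafflow_config_error")
    }
  })
  structure(cfg, class = "leaf_sim_config")
}

# smaller root of theta J^2 - (aI + jmax) J + aI jmax = 0
nrh_electron_flow <- function(i, jmax, quantum_yield_e, theta) {
  ai <- quantum_yield_e * i
  disc <- (ai + jmax)^2 - 4 * theta * ai * jmax
  if (any(disc < 0)) {
    abort("Negative discriminant in the light-response hyperbola.",
          class = "leafflow_internal_error")
  }
  ((ai + jmax) - sqrt(disc)) / (2 * theta)
}

sim_phi_ox <- function(config, o2_fraction) {
  if (o2_fraction <= 0.05) config$phi_ox_low_o2 else config$phi_ox
}

#' Noise-free ground truth of the simulated leaf
#'
#' Returns the exact quantities underlying [simulate_leaf()] at each light
#' level, for assertion in tests: carboxylation Vc, oxygenation Vo, net
#' assimilation A, photorespiration Pr = Vo/2, the electron flows
#' J_T = 4Vc + 4Vo, J_C = 4Vc, J_O = 4Vo, gross assimilation and the ratios
#' Pr/A_gross and J_C/J_O (= 1/phi).
#'
#' @param config A [leaf_sim_config()].
#' @param o2_fraction O2 mole fraction (0.21 ambient, 0.02 calibration).
#' @param light Light levels; defaults to `config$light_steps`.
#' @return A tibble with one row per light level.
#' @export
ground_truth <- function(config, o2_fraction = 0.21,
                         light = config$light_steps) {
  stopifnot(inherits(config, "leaf_sim_config"))
  phi <- sim_phi_ox(config, o2_fraction)
  j <- nrh_electron_flow(light, config$jmax, config$quantum_yield_e, config$theta)
  vc <- j / (4 * (1 + phi))
  vo <- phi * vc
  rl <- config$rd_true / 2
  a <- vc - 0.5 * vo - rl
  pr <- vo / 2
  a_gross <- a + rl + pr     # = vc
  phi_e_true <- j / (light * config$consts$alpha_leaf)
  tibble::tibble(
    I = light, o2_fraction = o2_fraction, phi = phi,
    j = j, vc = vc, vo = vo, a = a, rd = config$rd_true, rl = rl,
    pr = pr, a_gross = a_gross,
    jt = 4 * vc + 4 * vo, jc = 4 * vc, jo = 4 * vo,
    pr_over_agross = pr / a_gross,
    jc_over_jo = ifelse(vo == 0, Inf, vc / vo),
    phi_e_true = phi_e_true,
    phi_psii_true = config$b_true + config$k_true / 4 * phi_e_true
  )
}

#' Simulate instrument readings for one leaf
#'
#' Emits Li-cor-style gas-exchange + fluorescence records for a light
#' sequence at the given O2 level, from the ground-truth physiology of
#' `config` plus seeded Gaussian observation noise on A and Phi_PSII
#' (independent across readings; Phi_PSII observations are truncated to
#' \[0, 0.999\]). Cuvette conditions (CO2 400 ppm, leaf 21.4 degC, VPD 0.84
#' kPa) and nominal gs, Ci, E are filled with constant typical values.
#'
#' @param config A [leaf_sim_config()].
#' @param o2_fraction O2 mole fraction of the run.
#' @param light Light sequence; defaults to `config$light_steps`.
#' @param plant_id,genotype Identifiers stamped on the records.
#' @return A tibble of gas-exchange records in instrument (canonical column)
#'   form, ordered by light step then reading.
#' @export
simulate_leaf <- function(config, o2_fraction = 0.21,
                          light = config$light_steps,
                          plant_id = "leaf1", genotype = "WT") {
  stopifnot(inherits(config, "leaf_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  gt <- ground_truth(config, o2_fraction, light)
  nrep <- config$readings_per_step
  idx <- rep(seq_len(nrow(gt)), each = nrep)
  n <- length(idx)
  a_obs <- gt$a[idx] + rnorm(n, 0, config$noise_a)
  pp_obs <- gt$phi_psii_true[idx] + rnorm(n, 0, config$noise_phi_psii)
  pp_obs <- pmin(pmax(pp_obs, 0), 0.999)
  fm <- 1000
  tibble::tibble(
    plant_id = plant_id, genotype = genotype, obs = seq_len(n),
    A = a_obs, gs = 0.2, Ci = 280, E = 2.0,
    I = gt$I[idx], Fs = fm * (1 - pp_obs), Fm_prime = fm,
    o2_fraction = o2_fraction, co2_ref = 400, leaf_temp = 21.4, vpd = 0.84
  )
}

#' Simulate the paired calibration + ambient measurement for one leaf
#'
#' Runs [simulate_leaf()] twice with a shared seed stream: the full light
#' sequence at 2% O2 (calibration phase), then the ambient (21% O2) steady
#' state at `meas_light` with `readings_per_step` readings.
#'
#' @param config A [leaf_sim_config()].
#' @param meas_light Light level of the ambient steady state (default 1000).
#' @inheritParams simulate_leaf
#' @return A list with tibbles `calibration`, `measurement` and `dark`
#'   (post-darkening respiration readings, A negative as instruments log
#'   it, fluorescence absent), plus `rd_true`.
#' @export
simulate_leaf_experiment <- function(config, meas_light = 1000,
                                     plant_id = "leaf1", genotype = "WT") {
  stopifnot(inherits(config, "leaf_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_inner <- config
  cfg_inner$seed <- NULL    # one seeding for the whole experiment
  calib <- simulate_leaf(cfg_inner, o2_fraction = 0.02,
                         plant_id = plant_id, genotype = genotype)
  meas <- simulate_leaf(cfg_inner, o2_fraction = 0.21, light = meas_light,
                        plant_id = plant_id, genotype = genotype)
  nrep <- config$readings_per_step
  dark <- tibble::tibble(
    plant_id = plant_id, genotype = genotype,
    obs = max(meas$obs) + seq_len(nrep),
    A = -config$rd_true + rnorm(nrep, 0, config$noise_a),
    gs = 0.05, Ci = 400, E = 0.5, I = 0,
    Fs = NA_real_, Fm_prime = NA_real_,
    o2_fraction = 0.21, co2_ref = 400, leaf_temp = 21.4, vpd = 0.84
  )
  list(calibration = calib, measurement = meas, dark = dark,
       rd_true = config$rd_true)
}

#' Configuration for the synthetic trait study
#'
#' Defines a genotype x replicate trait study: each trait value is drawn as
#' baseline x effect x (1 + Normal(0, cv)). The default design mirrors a
#' four-genotype comparison (a wild type and three transgenic lines) with
#' six biological replicates and a 5% coefficient of variation.
#'
#' @param genotypes Named list: per genotype, a named numeric vector of
#'   multiplicative effect sizes vs the baseline (unlisted traits default to
#'   1). The reference genotype must have effect 1 for all traits (use
#'   `list(WT = c())`).
#' @param n_replicates Biological replicates per genotype (>= 2).
#' @param baselines Named numeric vector of baseline (reference) trait means.
#' @param trait_cv Coefficient of variation; a single number or a named
#'   vector per trait (>= 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `study_sim_config`.
#' @export
study_sim_config <- function(genotypes = list(WT = c(), GD = c(A = 1.16, gs = 1.24),
                                              HD = c(A = 1.11, gs = 1.23),
                                              OX = c(A = 1.115, gs = 1.21)),
                             n_replicates = 6L,
                             baselines = default_trait_baselines(),
                             trait_cv = 0.05, seed = NULL) {
  if (is.null(names(genotypes)) || any(names(genotypes) == "")) {
    abort("`genotypes` must be a named list.", class = "leafflow_config_error")
  }
  if (any(trait_cv < 0)) {
    abort("`trait_cv` must be >= 0.", class = "leafflow_config_error")
  }
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) {
    abort("`n_replicates` must be >= 2.", class = "leafflow_config_error")
  }
  for (g in names(genotypes)) {
    eff <- genotypes[[g]]
    if (length(eff) && (is.null(names(eff)) || any(names(eff) == ""))) {
      abort(paste0("Effects for genotype ", g, " must be named by trait."),
            class = "leafflow_config_error")
    }
    if (length(eff) && any(!names(eff) %in% names(baselines))) {
      abort(paste0("Effects for genotype ", g, " name unknown trait(s): ",
                   paste(setdiff(names(eff), names(baselines)), collapse = ", ")),
            class = "leafflow_config_error")
    }
  }
  structure(list(genotypes = genotypes, n_replicates = n_replicates,
                 baselines = baselines, trait_cv = trait_cv, seed = seed),
            class = "study_sim_config")
}

#' @rdname study_sim_config
#' @details `default_trait_baselines()` returns typical values for an
#'   8-week-old Arabidopsis rosette measured at 1000 umol m-2 s-1 and 400
#'   ppm CO2: A 14 umol m-2 s-1, gs 0.25 mol m-2 s-1, Ci 280 umol mol-1, E
#'   2.5 mmol m-2 s-1, WUE 5.6, Phi_PSII 0.30, Phi_CO2 0.015, ETR 130 umol
#'   e- m-2 s-1, Rd 1.2 umol m-2 s-1, dry weight 0.35 g, seed weight 0.08
#'   g, silique length 12 mm, soluble sugars 20 and starch 8 mg g-1,
#'   germination index 100.
#' @export
default_trait_baselines <- function() {
  c(A = 14, gs = 0.25, Ci = 280, E = 2.5, WUE = 5.6,
    phi_psii = 0.30, phi_co2 = 0.015, etr = 130, rd = 1.2,
    dry_weight = 0.35, seed_weight = 0.08, silique_length = 12,
    soluble_sugars = 20, starch = 8, germination_index = 100)
}

#' Simulate a genotype x replicate trait study
#'
#' Draws every (genotype, replicate, trait) value as baseline x effect x
#' (1 + Normal(0, cv)), seeded, and returns it as a long trait table in the
#' format of [read_trait_table()].
#'
#' @param config A [study_sim_config()].
#' @return A trait table tibble (`genotype`, `replicate`, `trait`, `value`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  traits <- names(config$baselines)
  cv_of <- function(tr) {
    if (length(config$trait_cv) == 1L && is.null(names(config$trait_cv))) {
      config$trait_cv
    } else {
      unname(config$trait_cv[tr])
    }
  }
  rows <- lapply(names(config$genotypes), function(g) {
    eff <- config$genotypes[[g]]
    lapply(seq_len(config$n_replicates), function(r) {
      vals <- vapply(traits, function(tr) {
        e <- if (tr %in% names(eff)) eff[[tr]] else 1
        config$baselines[[tr]] * e * (1 + rnorm(1, 0, cv_of(tr)))
      }, numeric(1))
      tibble::tibble(genotype = g, replicate = as.integer(r),
                     trait = traits, value = unname(vals))
    })
  })
  validate_trait_table(dplyr::bind_rows(unlist(rows, recursive = FALSE)))
}
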