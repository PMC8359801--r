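#' Light-adapted PSII quantum efficiency
#'
#' Computes the light-adapted operating efficiency of photosystem II from
#' steady-state fluorescence `Fs` and the maximal fluorescence `Fm'` reached
#' during a saturating pulse:
#' \deqn{\Phi_{PSII} = (F_m' - F_s) / F_m'}
#'
#' `Fs > Fm'` is physically impossible for a true saturating pulse but occurs
#' in noisy traces; the negative value is returned with a warning rather than
#' rejected, so that callers can flag and filter.
#'
#' @param fs Steady-state fluorescence (instrument units). Vectorized.
#' @param fm_prime Maximal fluorescence during the pulse; must be > 0.
#' @return Dimensionless quantum efficiency, same length as the inputs.
#' @examples
#' phi_psii(400, 1000)   # 0.6
#' @export
phi_psii <- function(fs, fm_prime) {
  if (any(!is.na(fm_prime) & fm_prime <= 0)) {
    abort("`fm_prime` must be > 0.", class = "leafflow_domain_error")
  }
  out <- (fm_prime - fs) / fm_prime
  if (any(!is.na(out) & out < 0)) {
    warn("Fs > Fm' for some readings: negative Phi_PSII returned.")
  }
  out
}

#' Fluorescence-based electron transport rate
#'
#' Linear electron transport rate through PSII:
#' \deqn{ETR = \Phi_{PSII} \cdot f \cdot I \cdot \alpha_{leaf}}
#' where `f` is the fraction of absorbed photons used by PSII and
#' `alpha_leaf` the leaf absorptance (see [fluoro_constants()]).
#'
#' @param phi_psii PSII operating efficiency (dimensionless).
#' @param i Incident photon flux density, umol photons m-2 s-1; must be >= 0.
#' @param consts A [fluoro_constants()] object.
#' @return ETR in umol electrons m-2 s-1.
#' @examples
#' etr(0.5, 1000)   # 220 with the default constants
#' @export
etr <- function(phi_psii, i, consts = fluoro_constants()) {
  consts <- as_fluoro_constants(consts)
  if (any(!is.na(i) & i < 0)) {
    abort("Photon flux `i` must be >= 0.", class = "leafflow_domain_error")
  }
  phi_psii * consts$f * i * consts$alpha_leaf
}

#' Respiration in the light
#'
#' Day respiration is partially suppressed relative to darkness; the standard
#' working assumption is \eqn{R_l = R_d / 2}. The factor is configurable for
#' sensitivity analyses.
#'
#' @param rd Dark respiration magnitude, umol CO2 m-2 s-1 (>= 0).
#' @param factor Suppression factor, default 0.5.
#' @return R_l in umol CO2 m-2 s-1.
#' @export
light_respiration <- function(rd, factor = 0.5) {
  if (any(!is.na(rd) & rd < 0)) {
    abort("`rd` must be a non-negative magnitude (sign is handled at ingest).",
          class = "leafflow_domain_error")
  }
  if (!is.numeric(factor) || factor < 0) {
    abort("`factor` must be >= 0.", class = "leafflow_domain_error")
  }
  rd * factor
}

#' Quantum efficiency of CO2 assimilation
#'
#' Converts net assimilation into CO2 fixed per incident absorbed photon.
#' Two conventions are provided:
#' \describe{
#'   \item{`"as_printed"` (default)}{\eqn{\Phi_{CO2} = (A - R_l)/(I\,\alpha_{leaf})}}
#'   \item{`"gross"`}{\eqn{\Phi_{CO2} = (A + R_l)/(I\,\alpha_{leaf})}}
#' }
#' The two differ in whether day respiration is treated as a debit against
#' the quantum yield or added back to recover gross carboxylation-driven
#' fixation. The gross form is the one consistent with the electron-flow
#' budget used in [partition_flows()], where respiration is added to A; see
#' the package vignette for the full argument.
#'
#' @param a Net CO2 assimilation, umol m-2 s-1.
#' @param rl Respiration in the light, umol m-2 s-1.
#' @param i Incident photon flux density; must be > 0.
#' @param consts A [fluoro_constants()] object.
#' @param mode `"as_printed"` or `"gross"`.
#' @return Dimensionless quantum efficiency.
#' @examples
#' phi_co2(10, 0.5, 1000)                  # (10 - 0.5)/880
#' phi_co2(10, 0.5, 1000, mode = "gross")  # (10 + 0.5)/880
#' @export
phi_co2 <- function(a, rl, i, consts = fluoro_constants(),
                    mode = c("as_printed", "gross")) {
  consts <- as_fluoro_constants(consts)
  mode <- match.arg(mode)
  if (any(!is.na(i) & i <= 0)) {
    abort("Photon flux `i` must be > 0 for a quantum efficiency.",
          class = "leafflow_domain_error")
  }
  num <- if (mode == "gross") a + rl else a - rl
  num / (i * consts$alpha_leaf)
}

#' Derive fluorescence quantities for a measurement table
#'
#' Appends `phi_psii`, `etr`, `rl` and `phi_co2` columns to a tibble of
#' gas-exchange records, composing [phi_psii()], [etr()],
#' [light_respiration()] and [phi_co2()] row-wise.
#'
#' @param df Tibble with columns `Fs`, `Fm_prime`, `A`, `I`.
#' @param rd Dark respiration magnitude for this leaf (single number).
#' @param consts A [fluoro_constants()] object.
#' @param mode Quantum-efficiency convention passed to [phi_co2()].
#' @param rl_factor Light-suppression factor passed to [light_respiration()].
#' @return The input tibble with the four derived columns appended.
#' @export
derive_fluorometry <- function(df, rd, consts = fluoro_constants(),
                               mode = c("as_printed", "gross"),
                               rl_factor = 0.5) {
  mode <- match.arg(mode)
  consts <- as_fluoro_constants(consts)
  rl <- light_respiration(rd, rl_factor)
  df |>
    dplyr::mutate(
      phi_psii = phi_psii(.data$Fs, .data$Fm_prime),
      etr = etr(.data$phi_psii, .data$I, consts),
      rl = rl,
      phi_co2 = phi_co2(.data$A, rl, .data$I, consts, mode = mode)
    )
}
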