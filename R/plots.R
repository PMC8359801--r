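#' Plot a light-response measurement set
#'
#' Net assimilation and PSII operating efficiency against incident light,
#' one panel each, colored by leaf. A quick visual check that the
#' light-response curves saturate sensibly and the fluorescence trace is
#' clean.
#'
#' @param df A tibble of gas-exchange records (columns `I`, `A`, `Fs`,
#'   `Fm_prime`, optionally `plant_id`).
#' @return A ggplot object.
#' @export
plot_light_response <- function(df) {
  df <- df |>
    dplyr::mutate(phi_psii = phi_psii(.data$Fs, .data$Fm_prime),
                  leaf = if ("plant_id" %in% names(df)) as.character(.data$plant_id) else "leaf")
  long <- tidyr::pivot_longer(df[c("leaf", "I", "A", "phi_psii")],
                              cols = c("A", "phi_psii"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$I, y = .data$value,
                                     colour = .data$leaf)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          A = "A (umol CO2 m-2 s-1)",
                          phi_psii = "Phi_PSII (-)"))) +
    ggplot2::labs(x = "Incident photon flux (umol m-2 s-1)", y = NULL,
                  colour = "Leaf") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_phi_relation Scatter of the calibration points with the
#'   fitted line.
#' @param object A `phi_calibration` object.
#' @export
autoplot.phi_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$phi_co2, y = .data$phi_psii)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$k, intercept = object$b,
                         colour = "steelblue") +
    ggplot2::labs(
      title = if (!is.na(object$leaf_id)) paste("Leaf", object$leaf_id) else NULL,
      subtitle = sprintf("k = %.3f, b = %.4f, R2 = %.4f",
                         object$k, object$b, object$r_squared),
      x = expression(Phi[CO2]), y = expression(Phi[PSII])) +
    ggplot2::theme_minimal()
}

#' @describeIn pca_traits Loadings of the first two components, with the
#'   share of variance each explains.
#' @param object A `trait_pca` object.
#' @export
autoplot.trait_pca <- function(object, ...) {
  ld <- tibble::as_tibble(object$loadings[, 1:2, drop = FALSE], rownames = "trait")
  names(ld)[2:3] <- c("PC1", "PC2")
  ve <- 100 * object$variance_explained
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   label = .data$trait)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$PC1, yend = .data$PC2),
                          x = 0, y = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", if (length(ve) > 1) ve[2] else 0)) +
    ggplot2::theme_minimal()
}

#' Plot per-leaf partition results
#'
#' Bar chart of Pr/A_gross and J_C/J_O per leaf (grouped by genotype when
#' available) from a [partition_leaves()] table.
#'
#' @param df A partition tibble from [partition_leaves()] or
#'   [pipeline_partition()].
#' @return A ggplot object.
#' @export
plot_partition <- function(df) {
  long <- tidyr::pivot_longer(
    df[c("leaf_id", intersect("genotype", names(df)), "pr_over_agross", "jc_over_jo")],
    cols = c("pr_over_agross", "jc_over_jo"),
    names_to = "ratio", values_to = "value")
  fill_var <- if ("genotype" %in% names(long)) "genotype" else "leaf_id"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$leaf_id, y = .data$value,
                                     fill = .data[[fill_var]])) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$ratio), scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          pr_over_agross = "Pr / A_gross",
                          jc_over_jo = "J_C / J_O"))) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
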