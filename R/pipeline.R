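#' End-to-end pipeline: simulate a study to disk
#'
#' Writes a complete synthetic dataset for one leaf per genotype (2%-O2
#' calibration light curve + ambient steady state) plus a genotype x
#' replicate trait table, with a ground-truth sidecar, into `out_dir`. The
#' seed is mandatory so runs are reproducible byte-for-byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (required).
#' @param leaf_config A [leaf_sim_config()]; its `seed` is overridden.
#' @param study_config A [study_sim_config()]; its `seed` is overridden.
#' @param genotypes Genotypes to simulate one leaf each for.
#' @return Invisibly, a named list of the file paths written:
#'   `calibration`, `measurement`, `traits`, `ground_truth`.
#' @export
pipeline_simulate <- function(out_dir, seed,
                              leaf_config = leaf_sim_config(),
                              study_config = study_sim_config(),
                              genotypes = names(study_config$genotypes)) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    abort("A `seed` is required for simulation runs.",
          class = "leafflow_config_error")
  }
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calib_all <- list(); meas_all <- list(); gt_all <- list()
  for (i in seq_along(genotypes)) {
    g <- genotypes[i]
    cfg <- leaf_config
    cfg$seed <- seed + i
    ex <- simulate_leaf_experiment(cfg, plant_id = paste0(g, "_leaf1"),
                                   genotype = g)
    calib_all[[g]] <- ex$calibration
    meas_all[[g]] <- dplyr::bind_rows(ex$measurement, ex$dark)
    gt <- ground_truth(cfg, o2_fraction = 0.21, light = 1000)
    gt$plant_id <- paste0(g, "_leaf1"); gt$genotype <- g
    gt_all[[g]] <- gt
  }
  st_cfg <- study_config
  st_cfg$seed <- seed
  traits <- simulate_study(st_cfg)
  paths <- list(
    calibration = file.path(out_dir, "calibration_2pct_o2.csv"),
    measurement = file.path(out_dir, "measurement_21pct_o2.csv"),
    traits = file.path(out_dir, "traits.csv"),
    ground_truth = file.path(out_dir, "ground_truth.csv")
  )
  write_gasx(dplyr::bind_rows(calib_all), paths$calibration,
             comments = paste0("seed: ", seed))
  write_gasx(dplyr::bind_rows(meas_all), paths$measurement,
             comments = paste0("seed: ", seed))
  write_trait_table(traits, paths$traits, comments = paste0("seed: ", seed))
  write_commented_csv(dplyr::bind_rows(gt_all), paths$ground_truth,
                      c(provenance_lines("ground truth sidecar"),
                        paste0("seed: ", seed)))
  invisible(paths)
}

#' End-to-end pipeline: per-leaf electron-flow partition
#'
#' Reads calibration (2% O2 light curve) and ambient-air measurement files,
#' runs the full chain ([partition_leaves()]) for every leaf, and optionally
#' writes the per-leaf partition table with a provenance comment header.
#' Inputs may also be passed as tibbles directly.
#'
#' @param calib Path to the calibration file, or a tibble.
#' @param meas Path to the ambient measurement file, or a tibble.
#' @param out Optional output path for the partition table (CSV).
#' @param dialect A [gasx_dialect()] used for file inputs; the canonical
#'   (identity) mapping by default since [write_gasx()] emits canonical
#'   columns.
#' @param rd Dark respiration per leaf (named vector or tibble), or `NULL`
#'   to derive from dark readings present in `meas`, or a single number
#'   applied to every leaf.
#' @inheritParams partition_leaves
#' @return The per-leaf partition tibble.
#' @export
pipeline_partition <- function(calib, meas, out = NULL,
                               dialect = gasx_dialect(), rd = NULL,
                               consts = fluoro_constants(),
                               mode = c("gross", "as_printed"),
                               rl_factor = 0.5, average_per_light = TRUE) {
  mode <- match.arg(mode)
  calib_df <- if (is.character(calib)) read_gasx(calib, dialect) else tibble::as_tibble(calib)
  meas_df <- if (is.character(meas)) read_gasx(meas, dialect) else tibble::as_tibble(meas)
  if (!nrow(meas_df)) {
    abort("No records in the measurement input.", class = "leafflow_data_error")
  }
  if (is.numeric(rd) && length(rd) == 1L && is.null(names(rd))) {
    ids <- unique(as.character(meas_df$plant_id))
    rd <- setNames(rep(rd, length(ids)), ids)
  }
  res <- partition_leaves(calib_df, meas_df, rd = rd, consts = consts,
                          mode = mode, rl_factor = rl_factor,
                          average_per_light = average_per_light)
  if (!is.null(out)) {
    write_commented_csv(res, out, c(
      provenance_lines("per-leaf electron-flow partition"),
      paste0("phi_co2 mode: ", mode, "; rl_factor: ", rl_factor,
             "; f: ", consts$f, "; alpha_leaf: ", consts$alpha_leaf)))
  }
  res
}

#' End-to-end pipeline: study report from a trait table
#'
#' Reads a trait table (path or tibble), runs [study_report()], and
#' optionally writes the report bundle with [write_study_report()].
#'
#' @param traits Path to a trait table file, or a trait table tibble.
#' @param out_dir Optional directory for the report bundle.
#' @param select_traits Optional character vector restricting the report to a
#'   subset of traits (default: all traits in the table).
#' @inheritParams study_report
#' @return The `study_report` object.
#' @export
pipeline_report <- function(traits, out_dir = NULL, reference = "WT",
                            select_traits = NULL,
                            t_variant = c("pooled", "welch"),
                            pca_unit = c("replicate", "genotype_mean"), ...) {
  t_variant <- match.arg(t_variant)
  pca_unit <- match.arg(pca_unit)
  tbl <- if (is.character(traits)) read_trait_table(traits) else validate_trait_table(traits)
  rep <- study_report(tbl, reference = reference, traits = select_traits,
                      t_variant = t_variant, pca_unit = pca_unit, ...)
  if (!is.null(out_dir)) write_study_report(rep, out_dir)
  rep
}
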