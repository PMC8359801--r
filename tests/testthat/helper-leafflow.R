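# Shared fixture builders. Everything is generated in code at test time.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# A tiny Li-cor-style export written to a temp file.
write_licor_fixture <- function(path = tempfile(fileext = ".csv"),
                                rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      Obs = 1:3, Photo = c(12.1, 12.0, 12.2), Cond = c(0.21, 0.20, 0.21),
      Ci = c(281, 280, 279), Trmmol = c(2.1, 2.0, 2.0), PARi = c(1000, 1000, 1000),
      Fs = c(640, 642, 641), `Fm.` = c(1480, 1478, 1482),
      Tleaf = 21.4, VpdL = 0.84, CO2R = 400, check.names = FALSE
    )
    names(rows)[names(rows) == "Fm."] <- "Fm'"
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal gas-exchange tibble in canonical columns.
canon_records <- function(a, gs = 0.2, fs = 450, fm = 1000, i = 1000) {
  n <- max(length(a), length(gs), length(fs), length(fm), length(i))
  tibble::tibble(plant_id = "L1", genotype = "WT", obs = seq_len(n),
                 A = rep_len(a, n), gs = rep_len(gs, n), Ci = 280, E = 2,
                 I = rep_len(i, n), Fs = rep_len(fs, n),
                 Fm_prime = rep_len(fm, n), o2_fraction = 0.21,
                 co2_ref = 400, leaf_temp = 21.4, vpd = 0.84)
}

# Noise-free simulator config used by the exact round-trip tests.
exact_config <- function(phi_ox = 0.25, seed = 1, ...) {
  leaf_sim_config(noise_phi_psii = 0, noise_a = 0, phi_ox = phi_ox,
                  phi_ox_low_o2 = 0, seed = seed, ...)
}

small_trait_table <- function() {
  set.seed(42)
  simulate_study(study_sim_config(
    genotypes = list(WT = c(), GD = c(A = 1.16)),
    baselines = c(A = 14, gs = 0.25, dry_weight = 0.35),
    n_replicates = 6L, trait_cv = 0.05, seed = 42))
}
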