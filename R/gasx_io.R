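#' Column-mapping dialects for instrument exports
#'
#' A dialect maps canonical field names used throughout the package onto the
#' column headers found in a particular instrument export. `licor6400_dialect()`
#' covers the column names written by Li-cor 6400 text exports
#' ("Photo", "Cond", "PARi", ...); `gasx_dialect()` builds a custom mapping,
#' and `read_dialect()` loads one from a YAML (or JSON-compatible YAML) file
#' whose keys are canonical names and whose values are the file's headers.
#'
#' Canonical fields: `plant_id`, `genotype`, `obs` (reading index), `A`
#' (net assimilation, umol CO2 m-2 s-1), `gs` (stomatal conductance,
#' mol H2O m-2 s-1), `Ci` (intercellular CO2, umol mol-1), `E`
#' (transpiration, mmol H2O m-2 s-1), `I` (incident photon flux,
#' umol m-2 s-1), `Fs`, `Fm_prime` (fluorescence, instrument units),
#' `o2_fraction` (mole fraction, 0-1), `co2_ref` (ppm), `leaf_temp` (degC),
#' `vpd` (kPa).
#'
#' @param ... Named character scalars, canonical name = file column name.
#'   Unspecified fields fall back to the identity mapping.
#' @return A named character vector of class `gasx_dialect`.
#' @examples
#' licor6400_dialect()
#' gasx_dialect(A = "Photo", I = "PARi")
#' @export
gasx_dialect <- function(...) {
  user <- c(...)
  base <- canonical_gasx_fields()
  identity <- setNames(base, base)
  if (length(user)) {
    if (is.null(names(user)) || any(names(user) == "")) {
      abort("All dialect entries must be named (canonical = file column).",
            class = "leafflow_config_error")
    }
    unknown <- setdiff(names(user), base)
    if (length(unknown)) {
      abort(paste0("Unknown canonical field(s) in dialect: ",
                   paste(unknown, collapse = ", ")),
            class = "leafflow_config_error")
    }
    identity[names(user)] <- user
  }
  structure(identity, class = "gasx_dialect")
}

#' @rdname gasx_dialect
#' @export
licor6400_dialect <- function() {
  gasx_dialect(
    A = "Photo", gs = "Cond", Ci = "Ci", E = "Trmmol", I = "PARi",
    Fs = "Fs", Fm_prime = "Fm'", obs = "Obs", co2_ref = "CO2R",
    leaf_temp = "Tleaf", vpd = "VpdL"
  )
}

#' @rdname gasx_dialect
#' @param path Path to a YAML file of canonical-name: column-name pairs.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Dialect file not found: ", path),
          class = "leafflow_config_error")
  }
  entries <- yaml::read_yaml(path)
  do.call(gasx_dialect, lapply(entries, as.character))
}

canonical_gasx_fields <- function() {
  c("plant_id", "genotype", "obs", "A", "gs", "Ci", "E", "I",
    "Fs", "Fm_prime", "o2_fraction", "co2_ref", "leaf_temp", "vpd")
}

required_gasx_fields <- function() c("A", "gs", "I")

numeric_gasx_fields <- function() {
  setdiff(canonical_gasx_fields(), c("plant_id", "genotype"))
}

#' Read a gas-exchange measurement table
#'
#' Reads a delimited (comma or tab) text file of per-reading leaf
#' measurements, renames instrument columns to canonical names via a
#' [gasx_dialect()], coerces measurement columns to numeric, and attaches a
#' `qc_flags` column recording physically suspect readings. Lines starting
#' with `#` are treated as metadata comments and skipped. Columns not named
#' in the dialect are preserved unchanged after the canonical ones.
#'
#' Quality flags raised per row (readings are flagged, never dropped):
#' `fs_gt_fm` when Fs > Fm'; `fm_nonpos` when Fm' <= 0; `neg_gs`, `neg_E`,
#' `neg_I` for negative conductance, transpiration or light; `bad_o2` when
#' the O2 mole fraction is outside \[0, 1\].
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect A [gasx_dialect()]; defaults to the Li-cor 6400 mapping.
#' @return A tibble with canonical columns first (missing optional fields are
#'   filled with `NA`), any extra columns, and `qc_flags` (comma-separated,
#'   `""` when clean).
#' @seealso [write_gasx()], [steady_state_average()]
#' @export
read_gasx <- function(path, dialect = licor6400_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("Measurement file not found: ", path),
          class = "leafflow_io_error")
  }
  dialect <- if (inherits(dialect, "gasx_dialect")) dialect else do.call(gasx_dialect, as.list(dialect))
  delim <- guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing_req <- required_gasx_fields()[!dialect[required_gasx_fields()] %in% names(raw)]
  if (length(missing_req)) {
    abort(paste0("Required column(s) missing from ", path, ": ",
                 paste(missing_req, collapse = ", "),
                 " (file column(s) ", paste(dialect[missing_req], collapse = ", "), ")"),
          class = "leafflow_config_error")
  }
  present <- dialect[dialect %in% names(raw)]
  out <- raw
  names(out)[match(present, names(out))] <- names(present)
  for (fld in setdiff(canonical_gasx_fields(), names(out))) out[[fld]] <- NA
  for (fld in numeric_gasx_fields()) {
    vals <- out[[fld]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & !vals %in% c("", "NA", "NaN") & is.na(num))
    if (length(bad)) {
      abort(paste0("Unparseable numeric value in column `", fld, "`, data row ",
                   bad[1], " of ", path, ": \"", vals[bad[1]], "\""),
            class = "leafflow_data_error")
    }
    out[[fld]] <- num
  }
  extra <- setdiff(names(out), canonical_gasx_fields())
  out <- tibble::as_tibble(out[c(canonical_gasx_fields(), extra)])
  out$qc_flags <- gasx_qc_flags(out)
  if (any(out$qc_flags != "")) {
    n_flag <- sum(out$qc_flags != "")
    warn(paste0(n_flag, " reading(s) in ", basename(path),
                " raised quality flags (see `qc_flags`)."))
  }
  out
}

gasx_qc_flags <- function(df) {
  n <- nrow(df)
  flags <- vector("list", n)
  add <- function(idx, flag) {
    for (i in which(idx)) flags[[i]] <<- c(flags[[i]], flag)
  }
  isnum <- function(x) !is.na(x)
  add(isnum(df$Fm_prime) & df$Fm_prime <= 0, "fm_nonpos")
  add(isnum(df$Fs) & isnum(df$Fm_prime) & df$Fm_prime > 0 & df$Fs > df$Fm_prime, "fs_gt_fm")
  add(isnum(df$gs) & df$gs < 0, "neg_gs")
  add(isnum(df$E) & df$E < 0, "neg_E")
  add(isnum(df$I) & df$I < 0, "neg_I")
  add(isnum(df$o2_fraction) & (df$o2_fraction < 0 | df$o2_fraction > 1), "bad_o2")
  vapply(flags, function(f) paste(f, collapse = ","), character(1))
}

guess_delim <- function(path) {
  first <- readLines(path, n = 20L, warn = FALSE)
  first <- first[!startsWith(first, "#")]
  if (!length(first)) return(",")
  if (sum(grepl("\t", first)) >= sum(grepl(",", first))) "\t" else ","
}

#' Write a gas-exchange measurement table
#'
#' Writes records in the canonical CSV layout that [read_gasx()] reads back
#' with the default (canonical) dialect, preceded by `#`-prefixed metadata
#' comment lines.
#'
#' @param df A tibble of gas-exchange records.
#' @param path Output file path.
#' @param comments Character vector of metadata lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_gasx <- function(df, path, comments = character()) {
  df <- df[setdiff(names(df), "qc_flags")]
  write_commented_csv(df, path, c(provenance_lines("gas-exchange records"), comments))
}

#' Detect and average a steady-state reading window
#'
#' Scans consecutive windows of `window` readings and returns the mean of the
#' first window in which every stability variable varies by less than
#' `rel_tol` relative to the window mean (max |x - mean| / |mean|). This
#' operationalizes the instrument practice of logging several consecutive
#' stable readings at full photosynthetic induction and averaging them.
#'
#' Averaged fields: `A`, `gs`, `Ci`, `E`, `Fs`, `Fm_prime` (and `I`,
#' `o2_fraction`, `co2_ref`, `leaf_temp`, `vpd` when present). Identifier
#' fields are taken from the first record of the accepted window.
#'
#' @param df Ordered tibble of gas-exchange records for one leaf.
#' @param window Number of consecutive readings required (default 3).
#' @param rel_tol Maximum relative spread tolerated within the window
#'   (default 0.02).
#' @param stability_vars Columns that must be stable; default `A` and `gs`.
#' @return A one-row tibble (the averaged record) with attribute
#'   `window_start` giving the index of the first averaged reading.
#' @examples
#' recs <- tibble::tibble(A = c(10, 10, 10, 20), gs = 0.2, Ci = 280,
#'                        E = 2, Fs = 450, Fm_prime = 1000, I = 1000)
#' steady_state_average(recs)
#' @export
steady_state_average <- function(df, window = 3L, rel_tol = 0.02,
                                 stability_vars = c("A", "gs")) {
  if (!is.numeric(rel_tol) || rel_tol <= 0) {
    abort("`rel_tol` must be > 0.", class = "leafflow_domain_error")
  }
  window <- as.integer(window)
  if (nrow(df) < window) {
    abort(paste0("Need at least ", window, " records, got ", nrow(df), "."),
          class = "leafflow_insufficient_data")
  }
  stability_vars <- intersect(stability_vars, names(df))
  if (!length(stability_vars)) {
    abort("No stability variables present in the data.",
          class = "leafflow_config_error")
  }
  spread_of <- function(i) {
    max(vapply(stability_vars, function(v) {
      x <- df[[v]][i:(i + window - 1L)]
      if (anyNA(x)) return(Inf)
      m <- mean(x)
      if (m == 0) return(if (all(x == 0)) 0 else Inf)
      max(abs(x - m)) / abs(m)
    }, numeric(1)))
  }
  starts <- seq_len(nrow(df) - window + 1L)
  spreads <- vapply(starts, spread_of, numeric(1))
  hit <- which(spreads < rel_tol)
  if (!length(hit)) {
    best <- which.min(spreads)
    abort(paste0("No steady-state window found (best window starts at reading ",
                 best, ", max relative spread ", signif(spreads[best], 3), ")."),
          class = "leafflow_no_steady_state", best_window = best,
          best_spread = spreads[best])
  }
  i <- hit[1]
  rows <- df[i:(i + window - 1L), , drop = FALSE]
  avg_fields <- intersect(c("A", "gs", "Ci", "E", "Fs", "Fm_prime", "I",
                            "o2_fraction", "co2_ref", "leaf_temp", "vpd"),
                          names(df))
  out <- rows[1, , drop = FALSE]
  for (v in avg_fields) out[[v]] <- mean(rows[[v]])
  attr(out, "window_start") <- i
  out
}

#' Dark respiration from dark readings
#'
#' Averages net assimilation over readings taken in darkness (I below
#' `dark_light_max`) and returns dark respiration R_d as a positive
#' magnitude: instruments report dark CO2 efflux as negative A, so the mean
#' is negated on ingest.
#'
#' @param df Tibble of gas-exchange records including dark readings.
#' @param dark_light_max Maximum photon flux counted as darkness (default 5).
#' @return R_d, a single non-negative number (umol CO2 m-2 s-1).
#' @export
dark_respiration <- function(df, dark_light_max = 5) {
  dark <- df[!is.na(df$I) & df$I <= dark_light_max & !is.na(df$A), , drop = FALSE]
  if (!nrow(dark)) {
    abort("No dark readings (I <= dark_light_max) found.",
          class = "leafflow_insufficient_data")
  }
  rd <- -mean(dark$A)
  if (rd < 0) {
    warn("Mean dark assimilation was positive; returning |mean| as R_d.")
    rd <- abs(rd)
  }
  rd
}

#' Read and write trait tables
#'
#' A trait table is a long tibble with one row per (genotype, replicate,
#' trait) carrying a single numeric `value`. The on-disk format is CSV with
#' `#` metadata comment lines; round-trips are lossless to full double
#' precision.
#'
#' @param path File path.
#' @return `read_trait_table()` returns a tibble with columns `genotype`
#'   (character), `replicate` (integer), `trait` (character), `value`
#'   (double). `write_trait_table()` returns `path` invisibly.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Trait table not found: ", path), class = "leafflow_io_error")
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          genotype = readr::col_character(),
                          replicate = readr::col_integer(),
                          trait = readr::col_character(),
                          value = readr::col_double()
                        ))
  validate_trait_table(df)
}

#' @rdname read_trait_table
#' @param table A trait table tibble.
#' @param comments Extra `#` metadata lines to write.
#' @export
write_trait_table <- function(table, path, comments = character()) {
  table <- validate_trait_table(table)
  write_commented_csv(table, path, c(provenance_lines("trait table"), comments))
}

validate_trait_table <- function(df) {
  need <- c("genotype", "replicate", "trait", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Trait table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "leafflow_data_error")
  }
  df <- tibble::as_tibble(df[need])
  df$genotype <- as.character(df$genotype)
  df$replicate <- as.integer(df$replicate)
  df$trait <- as.character(df$trait)
  df$value <- as.double(df$value)
  key <- paste(df$genotype, df$replicate, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    abort(paste0("Duplicate trait-table key: genotype=", d$genotype,
                 ", replicate=", d$replicate, ", trait=", d$trait),
          class = "leafflow_data_error")
  }
  df
}

write_commented_csv <- function(df, path, comments) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  body <- readr::format_csv(df)
  writeLines(sub("\n$", "", body), con)
  invisible(path)
}

# No timestamp: output files must be byte-identical across reruns of the
# same inputs and seed.
provenance_lines <- function(what) {
  paste0("leafflow ", as.character(utils::packageVersion("leafflow")),
         " -- ", what)
}
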