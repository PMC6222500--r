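# Delimited energy/dihedral tables and the packaged study fixtures.
#
# Fixture cells mirror the printed tables verbatim: thousands separators,
# U+2212 minus signs and "ND" (not determined) markers are kept in the
# files and normalized here. "ND" and empty cells become NA, never 0.

#' Parse printed numeric cells
#'
#' Strips thousands separators, normalizes the typographic minus (U+2212)
#' to ASCII and maps empty cells and `"ND"` markers to `NA`.
#'
#' @param x character vector of cells.
#' @return numeric vector.
#' @export
parse_energy_cell <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)
  x <- gsub(",", "", x, fixed = TRUE)
  out <- rep(NA_real_, length(x))
  keep <- !(is.na(x) | x == "" | toupper(x) == "ND")
  val <- suppressWarnings(as.numeric(x[keep]))
  if (anyNA(val)) {
    bad <- x[keep][is.na(val)][1]
    stop(sprintf("cannot parse numeric cell '%s'", bad), call. = FALSE)
  }
  out[keep] <- val
  out
}

# column expectations per fixture family
table_schemas <- list(
  compounds = list(
    required = c("compound", "r1", "r2", "r3"),
    numeric  = character(0)),
  trans_dihedrals = list(
    required = c("compound", "psi_n_gas", "omega_gas", "phi_c_gas", "psi_c_gas",
                 "psi_n_water", "omega_water", "phi_c_water", "psi_c_water"),
    numeric  = c("psi_n_gas", "omega_gas", "phi_c_gas", "psi_c_gas",
                 "psi_n_water", "omega_water", "phi_c_water", "psi_c_water")),
  increments = list(
    required = c("compound", "opt_e", "attachment", "e_tb"),
    numeric  = c("opt_e", "e_tb")),
  steric = list(
    required = c("compound", "opt_e", "n_tbu_n", "n_tbu_c", "add_e", "st_e"),
    numeric  = c("solvation_e", "opt_e", "n_tbu_n", "n_tbu_c", "add_e", "st_e")),
  cis_gas = list(
    required = c("compound", "psi_n", "omega", "phi_c", "psi_c", "d_e", "d_g"),
    numeric  = c("psi_n", "omega", "phi_c", "psi_c", "d_e", "d_g")),
  cis_water = list(
    required = c("compound", "solvation_e", "psi_n", "omega", "phi_c", "psi_c",
                 "d_e", "d_g"),
    numeric  = c("solvation_e", "psi_n", "omega", "phi_c", "psi_c", "d_e", "d_g")),
  barriers = list(
    required = c("compound",
                 "anti_plus_de", "anti_plus_dg", "anti_minus_de", "anti_minus_dg",
                 "syn_plus_de", "syn_plus_dg", "syn_minus_de", "syn_minus_dg",
                 "dg_eff"),
    numeric  = c("anti_plus_de", "anti_plus_dg", "anti_minus_de", "anti_minus_dg",
                 "syn_plus_de", "syn_plus_dg", "syn_minus_de", "syn_minus_dg",
                 "dg_eff"))
)

#' Load a delimited energy table
#'
#' Reads a tab-separated table with a header row, validates it against a
#' named column schema and types the numeric columns. Header names are
#' preserved verbatim. Empty cells and `"ND"` markers become `NA`.
#'
#' @param path file path to a TSV file.
#' @param schema one of `"compounds"`, `"trans_dihedrals"`, `"increments"`,
#'   `"steric"`, `"cis_gas"`, `"cis_water"`, `"barriers"`.
#' @return a `data.frame`, one row per table row.
#' @seealso [amide_table()] for the packaged study tables.
#' @export
load_energy_table <- function(path, schema) {
  schema <- match.arg(schema, names(table_schemas))
  sch <- table_schemas[[schema]]
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8", blank.lines.skip = TRUE,
                          na.strings = NULL)
  if (nrow(df) == 0L) stop(sprintf("'%s': table has no data rows", path), call. = FALSE)
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s': missing required column(s) for schema '%s': %s",
                 path, schema, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  for (col in intersect(sch$numeric, names(df))) {
    df[[col]] <- parse_energy_cell(df[[col]])
  }
  # normalize typographic primes in compound labels
  if ("compound" %in% names(df)) df$compound <- gsub("’", "'", df$compound)
  df
}

# table number -> (file, schema)
fixture_registry <- list(
  `1`  = c("table01_compounds.tsv",        "compounds"),
  `2`  = c("table02_trans_dihedrals.tsv",  "trans_dihedrals"),
  `3`  = c("table03_increments_gas.tsv",   "increments"),
  `4`  = c("table04_increments_water.tsv", "increments"),
  `5`  = c("table05_steric_trans_gas.tsv", "steric"),
  `6`  = c("table06_steric_trans_water.tsv", "steric"),
  `7`  = c("table07_cis_gas.tsv",          "cis_gas"),
  `8`  = c("table08_cis_water.tsv",        "cis_water"),
  `9`  = c("table09_steric_cis_gas.tsv",   "steric"),
  `10` = c("table10_steric_cis_water.tsv", "steric"),
  `11` = c("table11_barriers_gas.tsv",     "barriers"),
  `12` = c("table12_barriers_water.tsv",   "barriers")
)

#' Load a packaged study table
#'
#' The study's printed data tables ship with the package as plain-text
#' fixtures: compound definitions (1), trans dihedrals (2), tert-butyl
#' increment calculations for gas/water (3/4), trans steric-energy tables
#' (5 gas, 6 water), cis dihedrals and relative energies (7 gas, 8 water),
#' cis steric-energy tables (9 gas, 10 water) and directional barrier
#' tables (11 gas, 12 water).
#'
#' @param n table number, 1 to 12.
#' @return a typed `data.frame` (see [load_energy_table()]).
#' @examples
#' amide_table(5)
#' @export
amide_table <- function(n) {
  key <- as.character(as.integer(n))
  if (!key %in% names(fixture_registry)) {
    stop("`n` must be a table number between 1 and 12", call. = FALSE)
  }
  entry <- fixture_registry[[key]]
  path <- system.file("extdata", entry[1], package = "amidescan", mustWork = TRUE)
  load_energy_table(path, entry[2])
}
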