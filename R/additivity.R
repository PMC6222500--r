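# Group-additivity steric-energy model.
#
# The additive reference energy of a substituted compound is the optimized
# energy of the unsubstituted scaffold (the base, per isomer and phase)
# plus one transferable tert-butyl increment per substitution: E_tb^N for
# attachment at the sp3 amino nitrogen (ammonia vs tert-butylamine) and
# E_tb^C for attachment at an sp3 alpha carbon (methane vs neopentane).
# The steric energy is the excess of the optimized energy over this
# additive estimate.

#' Derive a group increment from a parent/substituted energy pair
#'
#' The additive energy value of a substitution is the optimized-energy
#' difference between the substituted small molecule and its parent (e.g.
#' tert-butylamine minus ammonia for attachment at sp3 nitrogen).
#'
#' @param parent_e,substituted_e optimized energies, kcal/mol.
#' @return increment in kcal/mol (`substituted_e - parent_e`).
#' @examples
#' derive_increment(-35508.975, -134218.106) # gas-phase sp3-N increment
#' @export
derive_increment <- function(parent_e, substituted_e) {
  if (!all(is.finite(parent_e)) || !all(is.finite(substituted_e))) {
    stop("energies must be finite", call. = FALSE)
  }
  substituted_e - parent_e
}

#' Derive both tert-butyl increments from an increment table
#'
#' Consumes a two-pair increment table (parent/substituted rows for sp3
#' nitrogen and sp3 carbon, as loaded by `amide_table(3)` or
#' `amide_table(4)`) and returns the increments via [derive_increment()].
#'
#' @param table data.frame with columns `compound`, `opt_e`, `attachment`
#'   (non-empty on each parent row).
#' @return named numeric vector `c("sp3-N" = ..., "sp3-C" = ...)`, kcal/mol.
#' @export
derive_increments <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("compound", "opt_e", "attachment") %in% names(table)))
  att <- trimws(table$attachment)
  starts <- which(nzchar(att) & !is.na(att))
  if (length(starts) != 2L || any(starts + 1L > nrow(table))) {
    stop("increment table must contain two parent/substituted row pairs",
         call. = FALSE)
  }
  vals <- vapply(starts, function(i) {
    derive_increment(table$opt_e[i], table$opt_e[i + 1L])
  }, numeric(1))
  names(vals) <- ifelse(grepl("nitrogen", att[starts], ignore.case = TRUE),
                        "sp3-N", "sp3-C")
  if (!setequal(names(vals), c("sp3-N", "sp3-C"))) {
    stop("increment table must cover both sp3 nitrogen and sp3 carbon",
         call. = FALSE)
  }
  vals[c("sp3-N", "sp3-C")]
}

#' Construct an additivity model
#'
#' Holds, per (isomer, phase) block, the base energy of the unsubstituted
#' scaffold and, per phase, the two tert-butyl increments. Blocks on
#' different absolute energy scales are never mixed: each additive energy
#' uses the base of its own (isomer, phase).
#'
#' @param base data.frame with columns `isomer` (`"trans"`/`"cis"`),
#'   `phase` (`"gas"`/`"water"`) and `energy` (kcal/mol) — one row per
#'   block the model will serve.
#' @param increments data.frame with columns `attachment` (`"sp3-N"`/
#'   `"sp3-C"`), `phase` and `value` (kcal/mol) — exactly one value per
#'   (attachment, phase).
#' @return object of class `"additivity_model"`.
#' @export
additivity_model <- function(base, increments) {
  stopifnot(is.data.frame(base),
            all(c("isomer", "phase", "energy") %in% names(base)),
            is.data.frame(increments),
            all(c("attachment", "phase", "value") %in% names(increments)))
  if (anyDuplicated(base[c("isomer", "phase")])) {
    stop("duplicate base energy for an (isomer, phase) block", call. = FALSE)
  }
  if (anyDuplicated(increments[c("attachment", "phase")])) {
    stop("duplicate increment for an (attachment, phase)", call. = FALSE)
  }
  if (!all(is.finite(base$energy)) || !all(is.finite(increments$value))) {
    stop("model energies must be finite", call. = FALSE)
  }
  out <- list(base = base, increments = increments)
  class(out) <- "additivity_model"
  out
}

model_base <- function(model, isomer, phase) {
  hit <- model$base$isomer == isomer & model$base$phase == phase
  if (sum(hit) != 1L) {
    stop(sprintf("no base energy for isomer '%s', phase '%s'", isomer, phase),
         call. = FALSE)
  }
  model$base$energy[hit]
}

model_increment <- function(model, attachment, phase) {
  hit <- model$increments$attachment == attachment &
    model$increments$phase == phase
  if (sum(hit) != 1L) {
    stop(sprintf("no increment for attachment '%s', phase '%s'", attachment, phase),
         call. = FALSE)
  }
  model$increments$value[hit]
}

#' Additive reference energy of a compound
#'
#' `base(isomer, phase) + n_N * E_tb^N(phase) + n_C * E_tb^C(phase)`, with
#' substitution counts from [substitution_counts()].
#'
#' @param model an `"additivity_model"`.
#' @param compound an `"amide_compound"` or N-code string.
#' @param isomer `"trans"` or `"cis"`.
#' @param phase `"gas"` or `"water"`.
#' @return additive energy, kcal/mol.
#' @examples
#' \dontrun{
#' additive_energy(model, "N0010", "trans", "gas")
#' }
#' @export
additive_energy <- function(model, compound, isomer, phase) {
  stopifnot(inherits(model, "additivity_model"))
  isomer <- match.arg(isomer, c("trans", "cis"))
  phase <- match.arg(phase, c("gas", "water"))
  counts <- substitution_counts(compound)
  model_base(model, isomer, phase) +
    counts[["n_n"]] * model_increment(model, "sp3-N", phase) +
    counts[["n_c"]] * model_increment(model, "sp3-C", phase)
}

#' Steric energy
#'
#' Excess of the optimized minimum-energy value over the additive
#' reference: `st_e = opt_e - add_e`. Positive values indicate steric
#' strain not captured by transferable increments.
#'
#' @param opt_e optimized energy, kcal/mol.
#' @param add_e additive reference energy, kcal/mol.
#' @return steric energy, kcal/mol.
#' @export
steric_energy <- function(opt_e, add_e) {
  if (!all(is.finite(opt_e)) || !all(is.finite(add_e))) {
    stop("energies must be finite", call. = FALSE)
  }
  opt_e - add_e
}

#' Steric-energy table for a set of conformer records
#'
#' Applies the additivity model to each record and tabulates substitution
#' counts, additive energies and steric energies. Values are unrounded;
#' the printed tables round to 3 decimals for display.
#'
#' @param records data.frame with columns `compound` (N-code), `isomer`,
#'   `phase` and `opt_e` (kcal/mol); extra columns are carried through.
#' @param model an `"additivity_model"` covering every (isomer, phase)
#'   block present in `records`.
#' @return `records` with added columns `n_tbu_n`, `n_tbu_c`, `add_e`,
#'   `st_e`.
#' @export
steric_table <- function(records, model) {
  stopifnot(is.data.frame(records),
            all(c("compound", "isomer", "phase", "opt_e") %in% names(records)),
            inherits(model, "additivity_model"))
  if (!all(is.finite(records$opt_e))) {
    stop("all record energies must be finite", call. = FALSE)
  }
  n <- nrow(records)
  counts <- t(vapply(records$compound, substitution_counts, integer(2)))
  add_e <- numeric(n)
  for (i in seq_len(n)) {
    add_e[i] <- additive_energy(model, records$compound[i],
                                records$isomer[i], records$phase[i])
  }
  out <- records
  out$n_tbu_n <- counts[, "n_n"]
  out$n_tbu_c <- counts[, "n_c"]
  out$add_e <- add_e
  out$st_e <- steric_energy(records$opt_e, add_e)
  out
}

#' Build the study's additivity model from the packaged tables
#'
#' Derives the gas and water tert-butyl increments from the packaged
#' small-molecule tables and takes the unsubstituted scaffold's optimized
#' energy in each (isomer, phase) block as that block's base.
#'
#' @return an `"additivity_model"` covering all four blocks.
#' @export
study_additivity_model <- function() {
  inc_gas <- derive_increments(amide_table(3))
  inc_water <- derive_increments(amide_table(4))
  increments <- data.frame(
    attachment = rep(c("sp3-N", "sp3-C"), 2),
    phase = rep(c("gas", "water"), each = 2),
    value = c(inc_gas, inc_water)
  )
  base_of <- function(tab, isomer) {
    lab <- split_isomer_label(tab$compound)
    tab$opt_e[lab$code == "N0000" & lab$isomer == isomer]
  }
  base <- data.frame(
    isomer = c("trans", "cis", "trans", "cis"),
    phase = c("gas", "gas", "water", "water"),
    energy = c(base_of(amide_table(5), "trans"),
               base_of(amide_table(9), "cis"),
               base_of(amide_table(6), "trans"),
               base_of(amide_table(10), "cis"))
  )
  additivity_model(base, increments)
}

#' Conformer records from a packaged steric table
#'
#' Reshapes a steric-table fixture (tables 5, 6, 9 or 10) into the record
#' layout consumed by [steric_table()].
#'
#' @param n fixture table number (5, 6, 9 or 10).
#' @param isomer,phase the block the table describes.
#' @return data.frame with columns `compound`, `isomer`, `phase`, `opt_e`
#'   and, where present, `solvation_e`.
#' @export
conformer_records <- function(n, isomer, phase) {
  stopifnot(n %in% c(5, 6, 9, 10))
  tab <- amide_table(n)
  lab <- split_isomer_label(tab$compound)
  if (!all(lab$isomer == isomer)) {
    stop(sprintf("table %d rows are not all '%s' records", n, isomer), call. = FALSE)
  }
  out <- data.frame(compound = lab$code, isomer = isomer, phase = phase,
                    opt_e = tab$opt_e, stringsAsFactors = FALSE)
  if ("solvation_e" %in% names(tab)) out$solvation_e <- tab$solvation_e
  if (phase == "gas" && any(is.finite(out$solvation_e))) {
    stop("solvation energies are water-phase only", call. = FALSE)
  }
  out
}
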