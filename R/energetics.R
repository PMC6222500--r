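# Cis-vs-trans energetics: relative (free) energies, solvation shifts,
# effective rotation barriers and equilibrium fractions.

#' Pair the cis and trans records of one compound/phase
#'
#' The trans minimum is the reference: relative quantities are
#' cis minus trans.
#'
#' @param compound N-code string.
#' @param phase `"gas"` or `"water"`.
#' @param trans,cis named lists (or named numeric vectors) of per-isomer
#'   quantities; conventional names are `E` (electronic energy, kcal/mol),
#'   `G` (Gibbs free energy, kcal/mol) and `solvation` (kcal/mol).
#' @return object of class `"isomer_pair"`.
#' @export
isomer_pair <- function(compound, phase, trans, cis) {
  phase <- match.arg(phase, c("gas", "water"))
  out <- list(compound = compound, phase = phase,
              trans = as.list(trans), cis = as.list(cis))
  class(out) <- "isomer_pair"
  out
}

#' Cis energy relative to the trans minimum
#'
#' @param pair an `"isomer_pair"`.
#' @param field `"E"` or `"G"`.
#' @return cis value minus trans value, kcal/mol.
#' @export
relative_energy <- function(pair, field = c("E", "G")) {
  stopifnot(inherits(pair, "isomer_pair"))
  field <- match.arg(field)
  tv <- pair$trans[[field]]
  cv <- pair$cis[[field]]
  if (is.null(tv) || is.null(cv) || !is.finite(tv) || !is.finite(cv)) {
    stop(sprintf("field '%s' missing on one isomer of %s (%s)",
                 field, pair$compound, pair$phase), call. = FALSE)
  }
  cv - tv
}

#' Solvation-energy shift of the cis isomer
#'
#' Difference of continuum solvation energies, cis minus trans; negative
#' values mean the cis isomer is better solvated. Defined for the water
#' phase only.
#'
#' @param cis_solv,trans_solv solvation energies, kcal/mol.
#' @param phase must be `"water"`; passing `"gas"` is an error.
#' @return shift in kcal/mol.
#' @export
solvation_shift <- function(cis_solv, trans_solv, phase = "water") {
  if (!identical(phase, "water")) {
    stop("solvation shift is defined for water-phase records only", call. = FALSE)
  }
  if (!all(is.finite(cis_solv)) || !all(is.finite(trans_solv))) {
    stop("solvation energies must be finite", call. = FALSE)
  }
  cis_solv - trans_solv
}

barrier_key_order <- c("anti+", "anti-", "syn+", "syn-")

#' Effective barrier over directional syn/anti entries
#'
#' Takes up to four directional barrier entries (syn/anti, rotation in the
#' + or - sense) and selects the minimum free-energy barrier as the
#' effective one — the assumption being that isomerization proceeds over
#' the lowest available path. Absent entries (symmetric compounds scanned
#' in one direction only) are skipped. Ties report the lexicographically
#' first key (anti before syn, + before -).
#'
#' @param entries data.frame with columns `type` (`"syn"`/`"anti"`),
#'   `direction` (`"+"`/`"-"`), `dg` (kcal/mol, `NA` when absent) and
#'   optionally `de`.
#' @param compound,phase optional labels carried into the summary.
#' @return object of class `"barrier_summary"`: list with `entries`,
#'   `dg_eff`, `argmin` (e.g. `"anti+"`), `compound`, `phase`.
#' @export
effective_barrier <- function(entries, compound = NA_character_,
                              phase = NA_character_) {
  stopifnot(is.data.frame(entries),
            all(c("type", "direction", "dg") %in% names(entries)))
  if (!all(entries$type %in% c("syn", "anti")) ||
      !all(entries$direction %in% c("+", "-"))) {
    stop("entries must be keyed by type in {syn, anti} and direction in {+, -}",
         call. = FALSE)
  }
  key <- paste0(entries$type, entries$direction)
  if (anyDuplicated(key)) stop("duplicate barrier entry keys", call. = FALSE)
  present <- is.finite(entries$dg)
  if (!any(present)) {
    stop(sprintf("no barrier entries present%s",
                 if (is.na(compound)) "" else paste0(" for ", compound)),
         call. = FALSE)
  }
  dg_eff <- min(entries$dg[present])
  hits <- key[present][entries$dg[present] == dg_eff]
  argmin <- barrier_key_order[min(match(hits, barrier_key_order))]
  out <- list(entries = entries, dg_eff = dg_eff, argmin = argmin,
              compound = compound, phase = phase)
  class(out) <- "barrier_summary"
  out
}

#' @export
print.barrier_summary <- function(x, ...) {
  cat(sprintf("<barrier_summary>%s%s dG_eff = %.2f kcal/mol via %s\n",
              if (is.na(x$compound)) "" else paste0(" ", x$compound),
              if (is.na(x$phase)) "" else paste0(" (", x$phase, ")"),
              x$dg_eff, x$argmin))
  invisible(x)
}

#' Barrier summaries from a packaged barrier table
#'
#' Reshapes a directional barrier fixture (table 11 gas, table 12 water)
#' into one [effective_barrier()] summary per compound.
#'
#' @param n fixture table number (11 or 12).
#' @return named list of `"barrier_summary"` objects, keyed by N-code.
#' @export
barrier_summaries <- function(n) {
  stopifnot(n %in% c(11, 12))
  phase <- if (n == 11) "gas" else "water"
  tab <- amide_table(n)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    entries <- data.frame(
      type = c("anti", "anti", "syn", "syn"),
      direction = c("+", "-", "+", "-"),
      de = c(tab$anti_plus_de[i], tab$anti_minus_de[i],
             tab$syn_plus_de[i], tab$syn_minus_de[i]),
      dg = c(tab$anti_plus_dg[i], tab$anti_minus_dg[i],
             tab$syn_plus_dg[i], tab$syn_minus_dg[i])
    )
    effective_barrier(entries, compound = tab$compound[i], phase = phase)
  })
  names(out) <- tab$compound
  out
}

#' Equilibrium cis fraction from the cis/trans free-energy gap
#'
#' Two-state Boltzmann population of the cis isomer,
#' `exp(-dG/RT) / (1 + exp(-dG/RT))`, with `dG` the cis minus trans free
#' energy.
#'
#' @param dg free-energy gap, kcal/mol.
#' @param temperature absolute temperature, K (default 298.15).
#' @return fraction in (0, 1); 0.5 at `dg = 0`.
#' @export
equilibrium_cis_fraction <- function(dg, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive", call. = FALSE)
  z <- exp(-dg / (gas_constant_kcal * temperature))
  z / (1 + z)
}
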