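# Model compounds: tert-butyl-substituted glycylglycine methyl ester (GGMe).
#
# Compounds are named by an N-code "N<d1><d2><d3>['] 0" where the three
# digits flag tert-butyl substitution at the N-terminal amino nitrogen (R1),
# the N-terminal alpha carbon (R2) and the C-terminal alpha carbon (R3).
# Alpha-carbon substituents default to the S configuration; a prime after
# the third digit marks the unnatural R configuration at R3. The fourth
# digit (always 0) denotes the methyl ester.

#' Parse a model-compound N-code
#'
#' Decodes codes such as `"N0000"`, `"N1010"` or `"N011'0"` into the
#' substituent assignment at the three variable sites of the
#' glycylglycine-methyl-ester scaffold. Both the ASCII apostrophe `'` and
#' the typographic prime `’` are accepted; the canonical code uses
#' ASCII.
#'
#' @param code character scalar, e.g. `"N011'0"`.
#' @return An object of class `"amide_compound"`: a list with elements
#'   `code` (canonicalized), `r1` (`"H"` or `"tBu"`), `r2` (`"H"` or
#'   `"tBu-S"`), `r3` (`"H"`, `"tBu-S"` or `"tBu-R"`) and `ester`
#'   (`"methyl"`).
#' @examples
#' parse_compound_code("N0000")
#' parse_compound_code("N011'0")
#' @export
parse_compound_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop("`code` must be a single character string", call. = FALSE)
  }
  canonical <- gsub("’", "'", code)
  m <- regmatches(canonical,
                  regexec("^N([01])([01])([01])(')?([0-9])$", canonical))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed compound code '%s' (offending character '%s')",
                 code, first_bad_code_char(canonical)), call. = FALSE)
  }
  d1 <- m[2]; d2 <- m[3]; d3 <- m[4]; prime <- m[5]; d4 <- m[6]
  if (d4 != "0") {
    stop(sprintf("malformed compound code '%s' (offending character '%s'): fourth digit must be 0",
                 code, d4), call. = FALSE)
  }
  if (prime == "'" && d3 == "0") {
    stop(sprintf("malformed compound code '%s': prime requires a substituent at the third site",
                 code), call. = FALSE)
  }
  out <- list(
    code = canonical,
    r1 = if (d1 == "1") "tBu" else "H",
    r2 = if (d2 == "1") "tBu-S" else "H",
    r3 = if (d3 == "0") "H" else if (prime == "'") "tBu-R" else "tBu-S",
    ester = "methyl"
  )
  class(out) <- "amide_compound"
  out
}

# first character at which a candidate code deviates from N[01][01][01]'?0
first_bad_code_char <- function(canonical) {
  chars <- strsplit(canonical, "")[[1]]
  if (length(chars) == 0L) return("<empty>")
  if (chars[1] != "N") return(chars[1])
  for (i in 2:4) {
    if (length(chars) < i) return("<truncated>")
    if (!chars[i] %in% c("0", "1")) return(chars[i])
  }
  rest <- chars[-(1:4)]
  if (length(rest) == 0L) return("<truncated>")
  if (!rest[1] %in% c("'", "0", "1")) return(rest[1])
  if (rest[1] == "'" && length(rest) == 1L) return("<truncated>")
  # wrong digit count or trailing junk
  rest[length(rest)]
}

#' @export
print.amide_compound <- function(x, ...) {
  cat(sprintf("<amide_compound> %s: R1=%s R2=%s R3=%s ester=%s\n",
              x$code, x$r1, x$r2, x$r3, x$ester))
  invisible(x)
}

#' Format a compound back to its canonical N-code
#'
#' Inverse of [parse_compound_code()]; uses the ASCII apostrophe.
#'
#' @param compound an `"amide_compound"` object.
#' @return character scalar.
#' @export
compound_code <- function(compound) {
  stopifnot(inherits(compound, "amide_compound"))
  paste0("N",
         if (compound$r1 == "tBu") "1" else "0",
         if (compound$r2 == "tBu-S") "1" else "0",
         switch(compound$r3, H = "0", `tBu-S` = "1", `tBu-R` = "1'"),
         "0")
}

#' Count tert-butyl substitutions by attachment-atom class
#'
#' Returns the number of tert-butyl groups attached to the sp3 amino
#' nitrogen and to sp3 alpha carbons, the multiplicities used by the
#' additivity model.
#'
#' @param compound an `"amide_compound"` object or an N-code string.
#' @return named integer vector `c(n_n = ..., n_c = ...)`.
#' @examples
#' substitution_counts("N1110") # 1 on nitrogen, 2 on carbon
#' @export
substitution_counts <- function(compound) {
  if (is.character(compound)) compound <- parse_compound_code(compound)
  stopifnot(inherits(compound, "amide_compound"))
  c(n_n = as.integer(compound$r1 == "tBu"),
    n_c = as.integer(compound$r2 != "H") + as.integer(compound$r3 != "H"))
}

#' The ten model-compound codes of the study
#'
#' All substitution patterns of the scaffold considered: tert-butyl at the
#' amino nitrogen and/or either alpha carbon, with both R3 configurations
#' when both alpha carbons are substituted.
#'
#' @return character vector of 10 canonical codes.
#' @export
model_compound_codes <- function() {
  c("N0000", "N0010", "N0100", "N0110", "N011'0",
    "N1000", "N1010", "N1100", "N1110", "N111'0")
}

#' Strip a trailing isomer tag from a table compound label
#'
#' Fixture rows label compounds as e.g. `"N0110t"` (trans) or `"N0110c"`
#' (cis); this splits the label into code and isomer.
#'
#' @param label character vector of labels.
#' @return data.frame with columns `code` (canonical ASCII) and `isomer`
#'   (`"trans"`, `"cis"` or `NA` when untagged).
#' @export
split_isomer_label <- function(label) {
  label <- gsub("’", "'", label)
  isomer <- rep(NA_character_, length(label))
  isomer[grepl("t$", label)] <- "trans"
  isomer[grepl("c$", label)] <- "cis"
  code <- sub("[tc]$", "", label)
  data.frame(code = code, isomer = isomer, stringsAsFactors = FALSE)
}
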