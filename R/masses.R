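# Monoisotopic mass bookkeeping for peptides and their modified forms.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic residue (i.e. water-free) masses in Daltons
#' for the 20 standard amino acids.
#'
#' @format Named numeric vector, one entry per one-letter residue code.
#' @export
AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Mass constants
#'
#' Monoisotopic masses (Da) of water and the proton, used throughout the
#' fragment and precursor arithmetic.
#' @export
MASS_WATER <- 18.0105646863
#' @rdname MASS_WATER
#' @export
MASS_PROTON <- 1.0072764666

#' Average residue masses (fallback for unknown residues)
#' @noRd
AA_AVG_UNKNOWN <- 110.0  # generic average used only when `allow_unknown = TRUE`

#' Post-translational modification catalogue
#'
#' The fixed and variable modifications considered during matching of
#' degraded (ancient) proteomes: carbamidomethylation of cysteine (fixed,
#' from alkylation during extraction), and as variable modifications
#' protein N-terminal acetylation, deamidation of Asn/Gln (the diagenetic
#' hallmark of ancient proteins), N-terminal Gln-to-pyroglutamate
#' cyclisation, methionine oxidation and proline hydroxylation.
#'
#' @return A data frame with columns `name`, `targets` (residue letters, or
#'   `"nterm"`/`"nterm_Q"` for terminus-specific entries), `delta_mass` (Da,
#'   monoisotopic) and `mode` (`"fixed"` or `"variable"`).
#' @export
#' @examples
#' modification_catalogue()
modification_catalogue <- function() {
  data.frame(
    name = c("carbamidomethyl", "acetyl_nterm", "deamidated",
             "pyroglutamate", "oxidation", "hydroxyproline"),
    targets = c("C", "nterm", "NQ", "nterm_Q", "M", "P"),
    delta_mass = c(57.02146, 42.01057, 0.98402, -17.02655, 15.99491, 15.99491),
    mode = c("fixed", "variable", "variable", "variable", "variable", "variable"),
    stringsAsFactors = FALSE
  )
}

.mod_delta <- function(names) {
  cat <- modification_catalogue()
  idx <- match(names, cat$name)
  if (anyNA(idx)) stop("unknown modification: ", paste(names[is.na(idx)], collapse = ", "))
  cat$delta_mass[idx]
}

#' Parse a modification string
#'
#' Modifications on a peptide are encoded compactly as
#' `"<pos>:<name>;<pos>:<name>"` with 1-based positions within the peptide
#' (terminus mods sit at position 1). The empty string means unmodified.
#'
#' @param mods Encoded modification string.
#' @return Data frame with columns `pos` (integer) and `name`.
#' @export
parse_mods <- function(mods) {
  if (is.null(mods) || is.na(mods) || !nzchar(mods)) {
    return(data.frame(pos = integer(), name = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed modification token in '", mods, "'")
  data.frame(
    pos = as.integer(vapply(parts, `[`, "", 1L)),
    name = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

#' Encode a modification table back to a string
#' @param tab Data frame with `pos` and `name` columns.
#' @return Single character string (empty when no modifications).
#' @export
encode_mods <- function(tab) {
  if (nrow(tab) == 0L) return("")
  tab <- tab[order(tab$pos, tab$name), , drop = FALSE]
  paste(sprintf("%d:%s", tab$pos, tab$name), collapse = ";")
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of monoisotopic residue masses plus one water, plus the mass deltas
#' of any modifications. Deterministic; `"X"` and other unknown residues are
#' an error unless `allow_unknown = TRUE`, in which case a documented
#' generic average residue mass (110 Da) is substituted.
#'
#' @param sequence Upper-case amino-acid string.
#' @param mods Modification string (see [parse_mods()]) or a data frame with
#'   `pos` and `name` columns. Positions must lie within the peptide.
#' @param allow_unknown Substitute 110 Da for residues absent from the mass
#'   table instead of erroring.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("G")              # 75.03203, glycine as free amino acid
#' peptide_mass("NQ", "1:deamidated")
peptide_mass <- function(sequence, mods = "", allow_unknown = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- AA_MONO[res]
  if (anyNA(m)) {
    if (!allow_unknown) {
      stop("unknown residue(s) in '", sequence, "': ",
           paste(unique(res[is.na(m)]), collapse = ","))
    }
    m[is.na(m)] <- AA_AVG_UNKNOWN
  }
  tab <- if (is.data.frame(mods)) mods else parse_mods(mods)
  if (nrow(tab) > 0L) {
    if (any(tab$pos < 1L | tab$pos > length(res))) {
      stop("modification position outside peptide '", sequence, "'")
    }
    delta <- sum(.mod_delta(tab$name))
  } else delta <- 0
  sum(m) + MASS_WATER + delta
}
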