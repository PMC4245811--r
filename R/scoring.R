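# Peptide-spectrum matching: fragment generation, candidate lookup,
# binomial ion score, and target-decoy FDR filtering.

#' Theoretical b/y fragment ions of a modified peptide
#'
#' Generates all singly charged b1..b(n-1) and y1..y(n-1) ions (and doubly
#' charged variants when `max_frag_charge >= 2`). Modification mass deltas
#' are applied at their residue positions; terminus modifications
#' (acetylation, pyroglutamate) ride on residue 1 and therefore on every b
#' ion and only the full-length y ions, as they should.
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param mods Modification string (see [parse_mods()]).
#' @param max_frag_charge Highest fragment charge generated (default 1).
#' @return Data frame with columns `ion` (label such as `"b3"` or `"y5^2"`)
#'   and `mz`.
#' @export
#' @examples
#' theoretical_fragments("AGK")  # b2 at 129.06585, y1 at 147.11280
theoretical_fragments <- function(sequence, mods = "", max_frag_charge = 1L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  stopifnot(n >= 2L)
  m <- unname(AA_MONO[res])
  if (anyNA(m)) stop("unknown residue in '", sequence, "'")
  tab <- parse_mods(mods)
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) m[tab$pos[i]] <- m[tab$pos[i]] + .mod_delta(tab$name[i])
  }
  b_neutral <- cumsum(m)[-n]            # residue-sum of prefix
  y_neutral <- rev(cumsum(rev(m)))[-1L] # residue-sum of suffix (y1..y(n-1))
  y_neutral <- rev(y_neutral)
  ions <- data.frame(
    ion = c(paste0("b", seq_len(n - 1L)), paste0("y", seq_len(n - 1L))),
    mz = c(b_neutral + MASS_PROTON, y_neutral + MASS_WATER + MASS_PROTON),
    stringsAsFactors = FALSE)
  if (max_frag_charge >= 2L) {
    neutral <- c(b_neutral, y_neutral + MASS_WATER)
    ions <- rbind(ions, data.frame(
      ion = paste0(c(paste0("b", seq_len(n - 1L)), paste0("y", seq_len(n - 1L))), "^2"),
      mz = (neutral + 2 * MASS_PROTON) / 2,
      stringsAsFactors = FALSE))
  }
  ions
}

#' Candidate peptides for a precursor
#'
#' All modified forms in the panel whose theoretical m/z at the given
#' charge lies within a symmetric relative (ppm) window of the observed
#' precursor m/z.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param charge Precursor charge.
#' @param forms Modified-form table (`panel$forms`), sorted by `mono_mass`.
#' @param tol_ppm Precursor tolerance in parts per million (default 10).
#' @return Subset of `forms` (possibly empty).
#' @export
candidate_peptides <- function(precursor_mz, charge, forms, tol_ppm = 10) {
  # |mz_obs - mz_theo| <= tol * 1e-6 * mz_theo
  mz_lo <- precursor_mz / (1 + tol_ppm * 1e-6)
  mz_hi <- precursor_mz / (1 - tol_ppm * 1e-6)
  mass_lo <- mz_lo * charge - charge * MASS_PROTON
  mass_hi <- mz_hi * charge - charge * MASS_PROTON
  lo <- findInterval(mass_lo, forms$mono_mass, left.open = TRUE) + 1L
  hi <- findInterval(mass_hi, forms$mono_mass)
  if (hi < lo) return(forms[0, , drop = FALSE])
  forms[lo:hi, , drop = FALSE]
}

#' Binomial-tail ion score
#'
#' The chance probability of observing at least `k` fragment matches in
#' `n` trials with per-fragment hit probability `p_hit` is the exact
#' binomial tail; the ion score is `-10 log10` of it, floored at 0
#' (`k = 0` scores 0 by convention).
#'
#' @param k Matched fragments.
#' @param n Considered fragments.
#' @param p_hit Per-fragment chance hit probability in (0, 1].
#' @return List with `p_value` and `score`.
#' @export
#' @examples
#' binomial_ion_score(10, 10, 0.01)$score  # 200
binomial_ion_score <- function(k, n, p_hit) {
  stopifnot(k >= 0L, k <= n, p_hit > 0, p_hit <= 1)
  if (k == 0L) return(list(p_value = 1, score = 0))
  log_p <- stats::pbinom(k - 1L, n, p_hit, lower.tail = FALSE, log.p = TRUE)
  list(p_value = exp(log_p), score = max(0, -10 * log_p / log(10)))
}

#' Score one peptide against one spectrum
#'
#' Theoretical b/y fragments are matched greedily one-to-one to observed
#' peaks within `frag_tol_da` (each peak usable once, nearest peak wins;
#' intensity is ignored). The chance probability of `k` matches among `n`
#' considered fragments is the binomial tail
#' `P = Pr(X >= k | n, p_hit)` with per-fragment hit probability
#' `p_hit = n_peaks * 2 * frag_tol / span` of the observed m/z range, and
#' the ion score is `-10 log10(P)`, floored at 0. Degenerate spectra
#' (fewer than two peaks or zero span) score 0.
#'
#' @param spectrum A spectrum (see [read_mgf()]).
#' @param sequence,mods Candidate peptide and its modification string.
#' @param frag_tol_da Fragment tolerance in Da (default 0.07).
#' @param max_frag_charge Fragment charges generated (default 1).
#' @return List with `matched`, `considered`, `p_value`, `score`.
#' @export
score_psm <- function(spectrum, sequence, mods = "", frag_tol_da = 0.07,
                      max_frag_charge = 1L) {
  frag <- theoretical_fragments(sequence, mods, max_frag_charge)
  n <- nrow(frag)
  mz <- spectrum$mz
  span <- if (length(mz) >= 2L) max(mz) - min(mz) else 0
  if (span <= 0) {
    return(list(matched = 0L, considered = n, p_value = 1, score = 0))
  }
  used <- logical(length(mz))
  k <- 0L
  for (f in sort(frag$mz)) {
    d <- abs(mz - f)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= frag_tol_da) {
      used[j] <- TRUE
      k <- k + 1L
    }
  }
  p_hit <- min(1, length(mz) * 2 * frag_tol_da / span)
  b <- binomial_ion_score(k, n, p_hit)
  list(matched = k, considered = n, p_value = b$p_value, score = b$score)
}

#' Search spectra against a reference panel
#'
#' For each spectrum, candidate modified forms are selected by precursor
#' mass (stated charge when present and within the searched charge range;
#' spectra without a stated charge are tried at the default charges), each
#' candidate is scored, and the best peptide-spectrum match is kept (ties:
#' more matched fragments, then lexicographically smallest peptide).
#'
#' @param spectra List of spectra.
#' @param panel A `blg_panel`.
#' @param tol_ppm Precursor tolerance (ppm, default 10).
#' @param frag_tol_da Fragment tolerance (Da, default 0.07).
#' @param charges Precursor charge states searched (default 2:5).
#' @param default_charges Charges tried when a spectrum states none
#'   (default c(2, 3)).
#' @param background Optional background database from
#'   [build_background_db()]; its forms are searched alongside the panel,
#'   so spectra of non-BLG origin can be claimed by their own best match
#'   (as in a full-proteome search) instead of surfacing as chance BLG
#'   candidates. Background PSMs carry `species = NA`.
#' @return Data frame of best PSMs, one row per spectrum with any
#'   candidate: `spectrum_id`, `sample_id`, `sequence`, `mods`, `species`,
#'   `accession`, `start`, `end`, `is_decoy`, `matched`, `considered`,
#'   `p_value`, `score`.
#' @export
search_spectra <- function(spectra, panel, tol_ppm = 10, frag_tol_da = 0.07,
                           charges = 2:5, default_charges = c(2L, 3L),
                           background = NULL) {
  forms <- panel$forms
  if (!is.null(background)) {
    forms <- rbind(forms, background$forms[, names(forms), drop = FALSE])
    forms <- forms[order(forms$mono_mass), , drop = FALSE]
  }
  rows <- lapply(spectra, function(s) {
    ch <- if (is.na(s$charge)) default_charges else s$charge
    ch <- ch[ch %in% charges]
    if (!length(ch)) return(NULL)
    cand <- do.call(rbind, lapply(ch, function(z)
      candidate_peptides(s$precursor_mz, z, forms, tol_ppm)))
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    cand <- cand[!duplicated(cand[c("sequence", "mods", "accession")]), , drop = FALSE]
    sc <- lapply(seq_len(nrow(cand)), function(i)
      score_psm(s, cand$sequence[i], cand$mods[i], frag_tol_da))
    score <- vapply(sc, `[[`, 0, "score")
    matched <- vapply(sc, `[[`, 0L, "matched")
    ord <- order(-score, -matched, cand$sequence)
    i <- ord[1]
    data.frame(spectrum_id = s$spectrum_id, sample_id = s$sample_id,
               sequence = cand$sequence[i], mods = cand$mods[i],
               species = cand$species[i], accession = cand$accession[i],
               start = cand$start[i], end = cand$end[i],
               is_decoy = cand$is_decoy[i],
               matched = matched[i], considered = sc[[i]]$considered,
               p_value = sc[[i]]$p_value, score = score[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(spectrum_id = character(), sample_id = character(),
                      sequence = character(), mods = character(),
                      species = character(), accession = character(),
                      start = integer(), end = integer(),
                      is_decoy = logical(), matched = integer(),
                      considered = integer(), p_value = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Target-decoy FDR filtering of best-per-spectrum PSMs
#'
#' Accepts target PSMs with ion score at or above the cutoff and chance
#' probability below `alpha` (the two criteria are applied conjunctively),
#' and estimates the false discovery rate as the number of decoy PSMs
#' passing the same filter divided by the number of accepted targets.
#'
#' @param psms PSM data frame from [search_spectra()].
#' @param score_cutoff Ion score threshold (default 25).
#' @param alpha Significance threshold on the chance probability
#'   (default 0.05).
#' @return Object of class `fdr_result`: list with `threshold`, `alpha`,
#'   `accepted` (target rows passing), `n_decoys_passing`,
#'   `estimated_fdr`.
#' @export
fdr_filter <- function(psms, score_cutoff = 25, alpha = 0.05) {
  pass <- psms$score >= score_cutoff & psms$p_value < alpha
  acc <- psms[pass & !psms$is_decoy, , drop = FALSE]
  nd <- sum(pass & psms$is_decoy)
  structure(list(threshold = score_cutoff, alpha = alpha,
                 accepted = acc, n_decoys_passing = nd,
                 estimated_fdr = nd / max(1L, nrow(acc))),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("Target-decoy FDR filter (score >= ", x$threshold,
      ", p < ", x$alpha, ")\n", sep = "")
  cat("  accepted targets:", nrow(x$accepted), "\n")
  cat("  decoys passing:  ", x$n_decoys_passing, "\n")
  cat("  estimated FDR:   ", signif(x$estimated_fdr, 3), "\n")
  invisible(x)
}
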