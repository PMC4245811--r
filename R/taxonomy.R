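# Per-sample taxonomic consensus and BLG protein coverage.

#' Consensus dairy-taxon call for one sample
#'
#' The sample consensus is the deepest taxonomy node that is an
#' ancestor-or-equal of every peptide-level assignment (lowest common
#' ancestor semantics); species-level assignments are additionally
#' reported individually, and a sample is BLG-positive with at least one
#' accepted spectrum.
#'
#' @param assignments Data frame with columns `peptide_seq`,
#'   `diagnostic_taxon` (taxon name or `NA`), `spectra_count`.
#' @param lineages Named list of root-to-species lineage paths (see
#'   [build_panel()]; `panel$lineages`).
#' @param sample_id Sample label.
#' @param pooled Is this a pooled extract of several individuals?
#' @return Object of class `sample_result`: list with `sample_id`,
#'   `accepted_peptides` (the input), `consensus_taxon`, `species_hits`,
#'   `multi_species`, `total_blg_spectra`, `positive`, `pooled` and
#'   `coverage_pct` (filled by [sample_coverage()], initially `NA`).
#' @export
sample_consensus <- function(assignments, lineages, sample_id = NA_character_,
                             pooled = FALSE) {
  stopifnot(all(c("peptide_seq", "diagnostic_taxon", "spectra_count") %in%
                  names(assignments)))
  taxa <- assignments$diagnostic_taxon
  taxa <- taxa[!is.na(taxa)]
  consensus <- if (length(taxa)) taxon_lca(unique(taxa), lineages) else NA_character_
  species <- intersect(unique(taxa), names(lineages))
  total <- sum(assignments$spectra_count)
  structure(list(sample_id = sample_id,
                 accepted_peptides = assignments,
                 consensus_taxon = consensus,
                 species_hits = species,
                 multi_species = length(species) >= 2L,
                 total_blg_spectra = as.integer(total),
                 positive = total >= 1L,
                 pooled = pooled,
                 coverage_pct = NA_real_),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat("Sample", x$sample_id, if (x$pooled) "(pooled)" else "", "\n")
  cat("  BLG", if (x$positive) "POSITIVE" else "negative",
      "-", x$total_blg_spectra, "spectra,",
      nrow(x$accepted_peptides), "peptides\n")
  cat("  consensus taxon:", ifelse(is.na(x$consensus_taxon), "none",
                                   x$consensus_taxon), "\n")
  if (length(x$species_hits)) {
    cat("  species-specific hits:", paste(x$species_hits, collapse = ", "),
        if (x$multi_species) "(multiple species)", "\n")
  }
  if (!is.na(x$coverage_pct)) cat("  consensus coverage:",
                                  sprintf("%.1f%%", x$coverage_pct), "\n")
  invisible(x)
}

#' Map a peptide onto the panel consensus
#'
#' Leftmost exact match of the peptide in the consensus under the matching
#' equivalence rules (always I=L; N/D and Q/E when deamidation-aware).
#'
#' @param peptide_seq Peptide sequence.
#' @param consensus Consensus amino-acid string.
#' @param deamidation_aware Collapse N/D and Q/E as well (default `TRUE`).
#' @return Integer vector `c(start, end)` (0-based half-open) or `NULL`
#'   when the peptide does not occur.
#' @export
map_peptide_to_consensus <- function(peptide_seq, consensus,
                                     deamidation_aware = TRUE) {
  hay <- collapse_seq(consensus, deamidation_aware)
  needle <- collapse_seq(peptide_seq, deamidation_aware)
  at <- regexpr(needle, hay, fixed = TRUE)
  if (at < 0) return(NULL)
  c(start = at - 1L, end = at - 1L + nchar(needle))
}

#' Protein coverage from peptide intervals
#'
#' Percentage of consensus residues covered by the union of the 0-based
#' half-open peptide intervals.
#'
#' @param intervals Data frame (or matrix) with columns `start` and `end`,
#'   or `NULL`/empty for no peptides.
#' @param consensus_length Length of the consensus in residues.
#' @return Coverage percentage in `[0, 100]` (full precision; round only
#'   for reporting).
#' @export
#' @examples
#' interval_coverage(data.frame(start = c(0, 5), end = c(10, 20)), 40)  # 50
interval_coverage <- function(intervals, consensus_length) {
  stopifnot(consensus_length >= 1L)
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  st <- as.integer(intervals[, "start"]); en <- as.integer(intervals[, "end"])
  if (any(st < 0L) || any(en > consensus_length) || any(en <= st)) {
    stop("peptide interval outside [0, ", consensus_length, ")")
  }
  o <- order(st, en)
  st <- st[o]; en <- en[o]
  covered <- 0L; cur_s <- st[1]; cur_e <- en[1]
  for (i in seq_along(st)[-1]) {
    if (st[i] <= cur_e) cur_e <- max(cur_e, en[i])
    else { covered <- covered + (cur_e - cur_s); cur_s <- st[i]; cur_e <- en[i] }
  }
  covered <- covered + (cur_e - cur_s)
  100 * covered / consensus_length
}

#' Coverage of the consensus by a set of identified peptides
#'
#' Maps each peptide to the consensus ([map_peptide_to_consensus()]);
#' unmappable peptides are excluded with a warning.
#'
#' @param peptide_seqs Character vector of peptide sequences.
#' @param consensus Consensus string.
#' @param deamidation_aware Equivalence flag.
#' @return List with `coverage_pct` and `intervals` (data frame of mapped
#'   `peptide_seq`, `start`, `end`).
#' @export
consensus_coverage <- function(peptide_seqs, consensus,
                               deamidation_aware = TRUE) {
  peptide_seqs <- unique(peptide_seqs)
  hits <- lapply(peptide_seqs, map_peptide_to_consensus, consensus = consensus,
                 deamidation_aware = deamidation_aware)
  miss <- vapply(hits, is.null, TRUE)
  if (any(miss)) {
    warning(sum(miss), " peptide(s) not mappable to the consensus; excluded")
  }
  if (all(miss)) {
    return(list(coverage_pct = 0,
                intervals = data.frame(peptide_seq = character(),
                                       start = integer(), end = integer())))
  }
  iv <- data.frame(peptide_seq = peptide_seqs[!miss],
                   start = vapply(hits[!miss], `[[`, 0L, "start"),
                   end = vapply(hits[!miss], `[[`, 0L, "end"))
  list(coverage_pct = interval_coverage(iv, nchar(consensus)), intervals = iv)
}

#' Per-sample taxonomic assignment from accepted peptides
#'
#' Groups an accepted-peptide table by sample, attaches each peptide's
#' diagnostic taxon from the panel, and produces one [sample_consensus()]
#' result per sample, including per-sample consensus coverage.
#'
#' @param peptides Data frame with columns `sample_id`, `peptide_seq` and
#'   `spectra_count` (one row per distinct peptide per sample). An
#'   accepted-PSM table from [fdr_filter()] can be converted with
#'   [psms_to_peptides()].
#' @param panel A `blg_panel`.
#' @param pooled_samples Character vector of sample ids that are pooled
#'   extracts.
#' @return Named list of `sample_result` objects.
#' @export
assign_samples <- function(peptides, panel, pooled_samples = character()) {
  stopifnot(all(c("sample_id", "peptide_seq", "spectra_count") %in% names(peptides)))
  split_rows <- split(peptides, peptides$sample_id)
  out <- lapply(names(split_rows), function(sid) {
    tab <- split_rows[[sid]]
    tab$diagnostic_taxon <- vapply(tab$peptide_seq, diagnostic_taxon,
                                   "", panel = panel, USE.NAMES = FALSE)
    res <- sample_consensus(
      data.frame(peptide_seq = tab$peptide_seq,
                 diagnostic_taxon = tab$diagnostic_taxon,
                 spectra_count = tab$spectra_count,
                 stringsAsFactors = FALSE),
      panel$lineages, sample_id = sid, pooled = sid %in% pooled_samples)
    cov <- suppressWarnings(
      consensus_coverage(tab$peptide_seq, panel$consensus,
                         panel$params$deamidation_aware))
    res$coverage_pct <- cov$coverage_pct
    res$intervals <- cov$intervals
    res
  })
  stats::setNames(out, names(split_rows))
}

#' Collapse accepted PSMs to per-sample peptide counts
#'
#' @param accepted Accepted-PSM data frame (`fdr_filter()$accepted`).
#' @param blg_only Keep only PSMs assigned to panel (BLG) sequences,
#'   dropping background-database matches (`species` is `NA`). Default
#'   `TRUE`.
#' @return Data frame with `sample_id`, `peptide_seq`, `spectra_count`.
#' @export
psms_to_peptides <- function(accepted, blg_only = TRUE) {
  if (blg_only && nrow(accepted) > 0L) {
    accepted <- accepted[!is.na(accepted$species), , drop = FALSE]
  }
  if (nrow(accepted) == 0L) {
    return(data.frame(sample_id = character(), peptide_seq = character(),
                      spectra_count = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(spectra_count = accepted$spectrum_id),
                          by = list(sample_id = accepted$sample_id,
                                    peptide_seq = accepted$sequence),
                          FUN = length)
  agg[order(agg$sample_id, agg$peptide_seq), , drop = FALSE]
}
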