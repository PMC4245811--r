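# In-silico trypsin digestion (fully- and semi-tryptic).

#' In-silico tryptic digestion of a protein sequence
#'
#' Trypsin cleaves C-terminal to K or R except when the next residue is
#' proline (Keil rule). Fully-tryptic peptides have both termini at cleavage
#' sites or protein ends; in semi-tryptic mode, peptides with exactly one
#' non-tryptic terminus are added, modelling the nonspecific truncation
#' typical of degraded ancient proteins. Missed cleavages are internal
#' uncut K/R sites.
#'
#' @param sequence Upper-case amino-acid string (20-letter alphabet).
#' @param max_missed Maximum internal missed cleavage sites (default 2).
#' @param min_len,max_len Peptide length bounds in residues (defaults 7 and
#'   30, a typical detectable range).
#' @param semi Also emit semi-tryptic peptides (default `TRUE`).
#' @return Data frame with one row per unique peptide interval: `sequence`,
#'   `start`, `end` (0-based half-open on the parent), `missed_cleavages`,
#'   `termini` (`"full"` or `"semi"`).
#' @export
#' @examples
#' digest_sequence("AKCR", max_missed = 1, min_len = 1, semi = FALSE)
digest_sequence <- function(sequence, max_missed = 2L, min_len = 7L,
                            max_len = 30L, semi = TRUE) {
  stopifnot(max_missed >= 0L, min_len >= 1L, min_len <= max_len)
  empty <- data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      termini = character(), stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(res %in% names(AA_MONO))) {
    stop("non-amino-acid character in sequence: ",
         paste(unique(res[!res %in% names(AA_MONO)]), collapse = ","))
  }
  n <- length(res)
  # cut position c (1..n-1) means a bond break between residues c and c+1,
  # i.e. a 0-based boundary at c
  cuts <- which(res[-n] %in% c("K", "R") & res[-1L] != "P")
  bounds <- c(0L, cuts, n)

  starts <- integer(); ends <- integer(); term <- character()
  add <- function(st, en, tm) {
    len <- en - st
    keep <- len >= min_len & len <= max_len
    starts <<- c(starts, st[keep]); ends <<- c(ends, en[keep])
    term <<- c(term, rep(tm, sum(keep)))
  }
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    add(rep(bounds[i], jmax - i), bounds[(i + 1L):jmax], "full")
  }
  if (semi) {
    n_internal <- function(st, en) {
      vapply(seq_along(st), function(k) sum(cuts > st[k] & cuts < en[k]), 0L)
    }
    for (b in bounds) {
      # N-terminus anchored at boundary b, free C-terminus
      if (b + min_len <= n) {
        en <- seq.int(b + min_len, min(n, b + max_len))
        ok <- !(en %in% bounds) & n_internal(rep(b, length(en)), en) <= max_missed
        add(rep(b, sum(ok)), en[ok], "semi")
      }
      # C-terminus anchored at boundary b, free N-terminus
      if (b - min_len >= 0L) {
        st <- seq.int(max(0L, b - max_len), b - min_len)
        ok <- !(st %in% bounds) & n_internal(st, rep(b, length(st))) <= max_missed
        add(st[ok], rep(b, sum(ok)), "semi")
      }
    }
  }
  if (!length(starts)) return(empty)
  out <- data.frame(start = starts, end = ends, termini = term,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out$sequence <- substring(sequence, out$start + 1L, out$end)
  out$missed_cleavages <- vapply(
    seq_len(nrow(out)),
    function(k) sum(cuts > out$start[k] & cuts < out$end[k]), 0L)
  out <- out[out$missed_cleavages <= max_missed, , drop = FALSE]
  out <- out[order(out$start, out$end), c("sequence", "start", "end",
                                          "missed_cleavages", "termini")]
  rownames(out) <- NULL
  out
}
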