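# Mascot generic format (MGF) peak-list I/O.

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE` and
#' `TITLE` headers. Mirroring the conversion used for searching, peaks are
#' truncated to the `max_peaks` most intense and re-sorted by m/z. Blocks
#' without a `PEPMASS` are skipped with a warning. Spectra with no stated
#' charge get `charge = NA` and are searched at the documented default
#' charge states.
#'
#' @param path MGF file.
#' @param max_peaks Retain at most this many most-intense peaks (default
#'   200).
#' @return List of spectra; each is a list with `spectrum_id`, `sample_id`
#'   (taken from a `SAMPLE=` header or the part of the title before the
#'   first dot, else `NA`), `precursor_mz`, `charge` (integer or `NA`),
#'   `mz` and `intensity` (numeric vectors sorted by m/z).
#' @export
read_mgf <- function(path, max_peaks = 200L) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    stop("unparsable MGF (unbalanced BEGIN IONS/END IONS): ", path)
  }
  out <- vector("list", length(begin))
  kept <- logical(length(begin))
  for (b in seq_along(begin)) {
    block <- lines[(begin[b] + 1L):(end[b] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    keyval <- strsplit(hdr, "=", fixed = TRUE)
    keys <- vapply(keyval, `[`, "", 1L)
    vals <- vapply(keyval, function(x) paste(x[-1L], collapse = "="), "")
    if (!"PEPMASS" %in% keys) {
      warning("MGF block ", b, " has no PEPMASS; skipped")
      next
    }
    title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else paste0("scan_", b)
    sample <- if ("SAMPLE" %in% keys) vals[keys == "SAMPLE"][1] else {
      if (grepl(".", title, fixed = TRUE)) sub("\\..*$", "", title) else NA_character_
    }
    charge <- if ("CHARGE" %in% keys) {
      ch <- vals[keys == "CHARGE"][1]
      as.integer(sub("^([0-9]+)[+-]?$", "\\1", ch))
    } else NA_integer_
    pm <- as.numeric(strsplit(trimws(vals[keys == "PEPMASS"][1]), "[ \t]+")[[1]][1])
    pk <- block[!is_hdr & nzchar(trimws(block))]
    if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), function(x)
        as.numeric(x[1:2])))
      if (anyNA(m)) stop("unparsable peak line in MGF block ", b, " of ", path)
      if (nrow(m) > max_peaks) {
        keep <- order(m[, 2], decreasing = TRUE)[seq_len(max_peaks)]
        m <- m[keep, , drop = FALSE]
      }
      o <- order(m[, 1])
      mz <- m[o, 1]; inten <- m[o, 2]
    } else {
      mz <- numeric(); inten <- numeric()
    }
    out[[b]] <- list(spectrum_id = title, sample_id = sample,
                     precursor_mz = pm, charge = charge,
                     mz = mz, intensity = inten)
    kept[b] <- TRUE
  }
  out[kept]
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] up to the peak cap: numbers are printed with
#' fixed precision (m/z to 5 decimals, intensity to 2) so identical inputs
#' give byte-identical files.
#'
#' @param spectra List of spectra as returned by [read_mgf()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    if (!is.null(s$sample_id) && !is.na(s$sample_id)) {
      writeLines(paste0("SAMPLE=", s$sample_id), con)
    }
    writeLines(sprintf("PEPMASS=%.5f", s$precursor_mz), con)
    if (!is.na(s$charge)) writeLines(sprintf("CHARGE=%d+", s$charge), con)
    if (length(s$mz)) {
      writeLines(sprintf("%.5f %.2f", s$mz, s$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
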