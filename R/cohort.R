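# Regional cohort aggregation of per-sample BLG results.

#' Summarize samples into a regional cohort table
#'
#' Aggregates per-sample BLG results (positivity and spectral counts) by
#' region, one row per region, in the shape of a published survey summary:
#' sample count, BLG-positive count (a pooled extract of several
#' individuals counts as one sample and is flagged), and total BLG
#' spectra.
#'
#' @param samples Data frame with columns `sample_id`, `region`,
#'   `positive` (logical), `spectra` (integer), and optionally `pooled`
#'   (logical) and `date_range`; or a list of `sample_result` objects plus
#'   a `regions` named vector.
#' @param regions Optional named character vector mapping sample ids to
#'   regions (required when `samples` is a list of `sample_result`s).
#' @return Data frame with one row per region: `region`, `date_range`,
#'   `n_samples`, `n_positive`, `total_spectra`, `pooled_note`.
#' @export
summarize_cohort <- function(samples, regions = NULL) {
  if (!is.data.frame(samples)) {
    stopifnot(!is.null(regions))
    samples <- do.call(rbind, lapply(samples, function(s) {
      data.frame(sample_id = s$sample_id,
                 region = unname(regions[s$sample_id]),
                 positive = s$positive,
                 spectra = s$total_blg_spectra,
                 pooled = s$pooled,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(samples) || nrow(samples) == 0L) {
    return(data.frame(region = character(), date_range = character(),
                      n_samples = integer(), n_positive = integer(),
                      total_spectra = integer(), pooled_note = logical(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(samples$pooled)) samples$pooled <- FALSE
  if (is.null(samples$date_range)) samples$date_range <- NA_character_
  rows <- lapply(split(samples, samples$region), function(g) {
    data.frame(region = g$region[1],
               date_range = g$date_range[1],
               n_samples = nrow(g),
               n_positive = sum(g$positive),
               total_spectra = sum(g$spectra),
               pooled_note = any(g$pooled & g$positive),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of BLG-positive samples across cohort rows
#'
#' `100 * sum(n_positive) / sum(n_samples)` over the selected rows,
#' reported to one decimal place.
#'
#' @param rows Cohort table from [summarize_cohort()] (or any data frame
#'   with `region`, `n_samples`, `n_positive`).
#' @param region_filter Optional character vector of regions to include
#'   (default: all rows).
#' @return Percentage, rounded to 1 decimal.
#' @export
positive_fraction <- function(rows, region_filter = NULL) {
  if (!is.null(region_filter)) rows <- rows[rows$region %in% region_filter, , drop = FALSE]
  if (nrow(rows) == 0L || sum(rows$n_samples) == 0L) {
    stop("no samples selected")
  }
  round(100 * sum(rows$n_positive) / sum(rows$n_samples), 1)
}

#' Bundled regional survey cohort table
#'
#' A transcription of the regional summary table of the archaeological
#' dental-calculus milk-protein survey this package reanalyses: per-region
#' sample counts, BLG-positive individual counts and total BLG spectra for
#' Northern Europe, Central Europe, northern Southwest Asia, Central West
#' Africa and Norse Greenland. The Norway row is a pooled five-individual
#' extract counted as one positive sample.
#'
#' @return Data frame in the [summarize_cohort()] row shape, with columns
#'   `group` (macro-region) and `eurasian` (logical) added.
#' @export
survey_cohort <- function() {
  path <- system.file("extdata", "survey_cohort.tsv", package = "paleomilk",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
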