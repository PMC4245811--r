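# End-to-end orchestration: panel build -> search -> FDR -> taxonomy ->
# cohort -> report bundle.

#' Default pipeline configuration
#'
#' Search defaults are the standard degraded-proteome settings: 10 ppm
#' precursor tolerance, 0.07 Da fragment tolerance, semi-tryptic digestion
#' with up to two missed cleavages, ion-score cutoff 25 with significance
#' threshold 0.05, deamidation-aware matching on.
#'
#' @param panel_fasta Panel FASTA path (default: bundled synthetic panel).
#' @param mgf Character vector of MGF paths (search mode), or `NULL`.
#' @param peptide_table Identified-peptide TSV (`sample_id`, `peptide_seq`,
#'   `spectra_count`) for table mode, or `NULL`.
#' @param sample_table Optional TSV with `sample_id`, `region`,
#'   `is_control`, `pooled` columns (the roster; samples absent from the
#'   results are reported negative).
#' @param out_dir Output directory.
#' @param ... Overrides for `tol_ppm`, `frag_tol_da`, `score_cutoff`,
#'   `alpha`, `max_missed`, `min_len`, `max_len`, `semi`, `max_variable`,
#'   `deamidation_aware`, `seed`, and `background_seed` (when set, a
#'   shuffled-sequence background database with that seed joins the search
#'   space — required when searching simulated cohorts, whose background
#'   spectra were drawn from the same database).
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(panel_fasta = synthetic_panel_fasta(), mgf = NULL,
                            peptide_table = NULL, sample_table = NULL,
                            out_dir = "paleomilk_out", ...) {
  cfg <- list(panel_fasta = panel_fasta, mgf = mgf,
              peptide_table = peptide_table, sample_table = sample_table,
              out_dir = out_dir,
              tol_ppm = 10, frag_tol_da = 0.07, score_cutoff = 25,
              alpha = 0.05, max_missed = 2L, min_len = 7L, max_len = 30L,
              semi = TRUE, max_variable = 2L, deamidation_aware = TRUE,
              seed = 1L, background_seed = NULL)
  utils::modifyList(cfg, list(...))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full BLG identification pipeline
#'
#' Two entry modes: raw MGF peak lists (panel build, spectral search,
#' target-decoy FDR, taxonomy, cohort) or a pre-identified peptide table
#' (taxonomy and cohort only), so published supplementary peptide tables
#' can be reanalysed without spectra. Writes per-sample, cohort, coverage
#' and FDR TSVs plus a plain-text run log recording the configuration
#' hash. Idempotent for identical inputs and configuration.
#'
#' @param cfg Configuration from [pipeline_config()].
#' @return Invisibly, a list with `panel`, `psms`, `fdr`, `samples`
#'   (list of `sample_result`), `cohort` (data frame), `files` (output
#'   paths).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logfile,
                               append = TRUE)
  cfg_json <- file.path(cfg$out_dir, "config.json")
  ser <- cfg[setdiff(names(cfg), c("out_dir"))]
  jsonlite::write_json(ser, cfg_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  cat("", file = logfile)
  logline("paleomilk pipeline start; config hash ",
          unname(tools::md5sum(cfg_json)), "; R ", as.character(getRversion()))

  panel <- .stage("panel", build_panel(
    cfg$panel_fasta, max_missed = cfg$max_missed, min_len = cfg$min_len,
    max_len = cfg$max_len, semi = cfg$semi, max_variable = cfg$max_variable,
    deamidation_aware = cfg$deamidation_aware))
  logline("panel: ", length(panel$records), " species, ",
          nrow(panel$forms), " searchable forms")

  roster <- NULL
  if (!is.null(cfg$sample_table)) {
    roster <- .stage("roster", utils::read.delim(cfg$sample_table,
                                                 stringsAsFactors = FALSE))
  }

  psms <- NULL; fdr <- NULL
  if (!is.null(cfg$mgf)) {
    spectra <- .stage("read_mgf", {
      sp <- unlist(lapply(cfg$mgf, read_mgf), recursive = FALSE)
      if (!length(sp)) stop("no spectra in input MGF files")
      sp
    })
    logline("search: ", length(spectra), " spectra")
    background <- if (!is.null(cfg$background_seed)) {
      .stage("background", build_background_db(panel, cfg$background_seed))
    } else NULL
    psms <- .stage("search", search_spectra(
      spectra, panel, tol_ppm = cfg$tol_ppm, frag_tol_da = cfg$frag_tol_da,
      background = background))
    fdr <- .stage("fdr", fdr_filter(psms, cfg$score_cutoff, cfg$alpha))
    logline("fdr: ", nrow(fdr$accepted), " accepted targets, estimated FDR ",
            signif(fdr$estimated_fdr, 3))
    peptides <- psms_to_peptides(fdr$accepted)
  } else if (!is.null(cfg$peptide_table)) {
    peptides <- .stage("peptide_table", {
      tab <- utils::read.delim(cfg$peptide_table, stringsAsFactors = FALSE)
      need <- c("sample_id", "peptide_seq", "spectra_count")
      if (!all(need %in% names(tab))) {
        stop("peptide table must have columns ", paste(need, collapse = ", "))
      }
      tab
    })
  } else {
    stop("pipeline stage 'input' failed: provide either mgf or peptide_table",
         call. = FALSE)
  }

  pooled <- if (!is.null(roster) && !is.null(roster$pooled)) {
    roster$sample_id[as.logical(roster$pooled)]
  } else character()
  samples <- .stage("assign", assign_samples(peptides, panel, pooled))

  # fill roster samples with no accepted peptides as negatives
  if (!is.null(roster)) {
    missing <- setdiff(roster$sample_id, names(samples))
    for (sid in missing) {
      samples[[sid]] <- sample_consensus(
        data.frame(peptide_seq = character(), diagnostic_taxon = character(),
                   spectra_count = integer(), stringsAsFactors = FALSE),
        panel$lineages, sample_id = sid, pooled = sid %in% pooled)
      samples[[sid]]$coverage_pct <- 0
    }
    regions <- stats::setNames(roster$region, roster$sample_id)
  } else {
    regions <- stats::setNames(rep(NA_character_, length(samples)),
                               names(samples))
  }
  cohort <- .stage("cohort", summarize_cohort(samples, regions))

  files <- list(
    psms = file.path(cfg$out_dir, "psms.tsv"),
    samples = file.path(cfg$out_dir, "samples.tsv"),
    cohort = file.path(cfg$out_dir, "cohort.tsv"),
    coverage = file.path(cfg$out_dir, "coverage.tsv"),
    fdr = file.path(cfg$out_dir, "fdr.tsv"),
    log = logfile, config = cfg_json)
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", row.names = FALSE,
                                          quote = FALSE)
  if (!is.null(psms)) {
    psms$accepted <- psms$score >= cfg$score_cutoff &
      psms$p_value < cfg$alpha & !psms$is_decoy
    wt(psms, files$psms)
    wt(data.frame(score_cutoff = fdr$threshold, alpha = fdr$alpha,
                  accepted_targets = nrow(fdr$accepted),
                  decoys_passing = fdr$n_decoys_passing,
                  estimated_fdr = fdr$estimated_fdr), files$fdr)
  }
  sample_df <- do.call(rbind, lapply(samples, function(s) data.frame(
    sample_id = s$sample_id, region = unname(regions[s$sample_id]),
    positive = s$positive, spectra = s$total_blg_spectra,
    n_peptides = nrow(s$accepted_peptides),
    consensus_taxon = s$consensus_taxon,
    species_hits = paste(s$species_hits, collapse = ","),
    multi_species = s$multi_species, pooled = s$pooled,
    coverage_pct = round(s$coverage_pct, 1), stringsAsFactors = FALSE)))
  sample_df <- sample_df[order(sample_df$sample_id), , drop = FALSE]
  wt(sample_df, files$samples)
  wt(cohort, files$cohort)
  cov_iv <- do.call(rbind, lapply(samples, function(s) {
    if (is.null(s$intervals) || nrow(s$intervals) == 0L) return(NULL)
    cbind(sample_id = s$sample_id, s$intervals)
  }))
  if (is.null(cov_iv)) {
    cov_iv <- data.frame(sample_id = character(), peptide_seq = character(),
                         start = integer(), end = integer())
  }
  wt(cov_iv, files$coverage)
  logline("done: ", length(samples), " samples, ",
          sum(sample_df$positive), " BLG-positive")
  invisible(list(panel = panel, psms = psms, fdr = fdr, samples = samples,
                 sample_table = sample_df, cohort = cohort, files = files))
}
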