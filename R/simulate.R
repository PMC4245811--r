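# Ground-truthed synthetic cohorts: MGF spectra with known generating
# peptides, background peptidomes, controls, and LP allele-frequency points.

#' Default instrument simulation parameters
#'
#' Gaussian mass errors with SD equal to one third of the corresponding
#' search tolerance (so ~99.7% of true peaks fall inside the matching
#' windows), mild peak dropout, uniform noise peaks, and log-normal
#' intensities (the scorer ignores intensity; only the most-intense-peak
#' cap makes it matter).
#'
#' @return Named list: `mass_error_sd_ppm`, `fragment_error_sd_da`,
#'   `peak_dropout`, `noise_peaks`, `deamidation_rate`.
#' @export
default_instrument <- function() {
  list(mass_error_sd_ppm = 10 / 3,
       fragment_error_sd_da = 0.07 / 3,
       peak_dropout = 0.1,
       noise_peaks = 30L,
       deamidation_rate = 0.3)
}


# one synthetic MS/MS spectrum from a peptide + modification string
simulate_spectrum <- function(sequence, mods, spectrum_id, sample_id, inst) {
  frag <- theoretical_fragments(sequence, mods, max_frag_charge = 1L)
  mz <- frag$mz + stats::rnorm(nrow(frag), 0, inst$fragment_error_sd_da)
  keep <- stats::runif(length(mz)) >= inst$peak_dropout
  if (!any(keep)) keep[sample.int(length(mz), 1L)] <- TRUE
  mz <- mz[keep]
  inten <- stats::rlnorm(length(mz), meanlog = 10, sdlog = 1)
  if (inst$noise_peaks > 0L) {
    lo <- max(100, min(mz) - 50); hi <- max(mz) + 50
    nmz <- stats::runif(inst$noise_peaks, lo, hi)
    ninten <- stats::rlnorm(inst$noise_peaks, meanlog = 8, sdlog = 1)
    mz <- c(mz, nmz); inten <- c(inten, ninten)
  }
  o <- order(mz)
  z <- sample(2:3, 1L)
  mono <- peptide_mass(sequence, mods)
  pmz <- (mono + z * MASS_PROTON) / z
  pmz <- pmz * (1 + stats::rnorm(1, 0, inst$mass_error_sd_ppm) * 1e-6)
  list(spectrum_id = spectrum_id, sample_id = sample_id,
       precursor_mz = pmz, charge = z, mz = mz[o], intensity = inten[o])
}

# draw a deamidation pattern for a peptide (at most max_variable sites so
# the generated form stays inside the searched modification space)
draw_mods <- function(sequence, rate, max_variable = 2L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  fixed <- data.frame(pos = which(res == "C"),
                      name = rep("carbamidomethyl", sum(res == "C")),
                      stringsAsFactors = FALSE)
  sites <- which(res %in% c("N", "Q"))
  hit <- sites[stats::runif(length(sites)) < rate]
  if (length(hit) > max_variable) hit <- sort(sample(hit, max_variable))
  var <- data.frame(pos = hit, name = rep("deamidated", length(hit)),
                    stringsAsFactors = FALSE)
  encode_mods(rbind(fixed, var))
}

#' Simulate one sample's spectra
#'
#' True spectra are drawn from the digestion peptidome of the sample's
#' species mix (mass-eligible target peptides only), perturbed by Gaussian
#' mass errors, peak dropout and uniform noise peaks, with diagenetic
#' deamidation applied per N/Q site at `deamidation_rate`. Background
#' spectra come from a shuffled-sequence peptidome. Control samples
#' (`is_control` of `"blank"` or `"fetuin"`) contain background only.
#'
#' @param entry List describing the sample: `sample_id`, `region`,
#'   `species_mix` (named proportions summing to 1), `n_true`,
#'   `n_background`, `is_control` (`"none"`, `"blank"` or `"fetuin"`),
#'   `pooled`.
#' @param panel A `blg_panel`.
#' @param inst Instrument parameters ([default_instrument()]).
#' @param bg Background database from [build_background_db()]; background
#'   spectra are drawn from its (non-decoy, unmodified) peptides so that a
#'   search against panel plus background can explain them.
#' @return List with `spectra` (list) and `truth` (data frame:
#'   `sample_id`, `spectrum_id`, `is_blg`, `sequence`, `mods`, `species`).
#' @export
simulate_sample <- function(entry, panel, inst = default_instrument(),
                            bg = build_background_db(panel)) {
  is_control <- !is.null(entry$is_control) && entry$is_control != "none"
  n_true <- if (is_control) 0L else entry$n_true
  if (is_control && entry$n_true > 0L) {
    stop("control samples must have zero true BLG spectra")
  }
  mix <- entry$species_mix
  if (n_true > 0L) {
    if (is.null(mix) || abs(sum(mix) - 1) > 1e-8) {
      stop("species_mix proportions must sum to 1 for sample ", entry$sample_id)
    }
    if (!all(names(mix) %in% names(panel$lineages))) {
      stop("species absent from panel: ",
           paste(setdiff(names(mix), names(panel$lineages)), collapse = ", "))
    }
  }
  # unmodified (fixed-mods-only) mass-eligible target peptides per species
  plain <- panel$forms[!panel$forms$is_decoy &
                         !grepl("deamidated|oxidation|hydroxyproline|pyroglutamate|acetyl",
                                panel$forms$mods), , drop = FALSE]
  spectra <- list(); truth <- list()
  sid <- entry$sample_id
  count <- 0L
  for (i in seq_len(n_true)) {
    sp <- if (length(mix) == 1L) names(mix) else
      sample(names(mix), 1L, prob = mix)
    pool <- plain[plain$species == sp, , drop = FALSE]
    j <- sample.int(nrow(pool), 1L)
    seqs <- pool$sequence[j]
    mods <- draw_mods(seqs, inst$deamidation_rate,
                      panel$params$max_variable)
    count <- count + 1L
    scan <- sprintf("%s.%05d", sid, count)
    spectra[[length(spectra) + 1L]] <- simulate_spectrum(seqs, mods, scan, sid, inst)
    truth[[length(truth) + 1L]] <- data.frame(
      sample_id = sid, spectrum_id = scan, is_blg = TRUE,
      sequence = seqs, mods = mods, species = sp, stringsAsFactors = FALSE)
  }
  bg_plain <- bg$forms[!bg$forms$is_decoy &
                         !grepl("deamidated|oxidation|hydroxyproline|pyroglutamate|acetyl",
                                bg$forms$mods), , drop = FALSE]
  n_bg <- entry$n_background
  for (i in seq_len(n_bg)) {
    j <- sample.int(nrow(bg_plain), 1L)
    seqs <- bg_plain$sequence[j]
    mods <- draw_mods(seqs, inst$deamidation_rate, 2L)
    count <- count + 1L
    scan <- sprintf("%s.%05d", sid, count)
    spectra[[length(spectra) + 1L]] <- simulate_spectrum(seqs, mods, scan, sid, inst)
    truth[[length(truth) + 1L]] <- data.frame(
      sample_id = sid, spectrum_id = scan, is_blg = FALSE,
      sequence = seqs, mods = mods, species = NA_character_,
      stringsAsFactors = FALSE)
  }
  list(spectra = spectra,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(sample_id = character(), spectrum_id = character(),
                    is_blg = logical(), sequence = character(),
                    mods = character(), species = character(),
                    stringsAsFactors = FALSE))
}

#' Simulate a full cohort to disk
#'
#' Deterministic given `config$seed`: writes one MGF per sample, a truth
#' TSV, a sample-metadata TSV (region, control status, pooled flag) and a
#' JSON echo of the configuration.
#'
#' @param config List with `seed`, `samples` (list of entries as in
#'   [simulate_sample()], each also carrying `region` and optionally
#'   `pooled`), and optionally `instrument` overriding
#'   [default_instrument()] entries.
#' @param panel A `blg_panel`.
#' @param dir Output directory (created if needed).
#' @param bg Background database; defaults to
#'   `build_background_db(panel, config$seed)`. Pass a prebuilt one to
#'   share it across cohorts (the matching database must then be given to
#'   the search).
#' @return Invisibly, a list with `mgf` (named paths), `truth_tsv`,
#'   `samples_tsv`, `config_json`, and in-memory `spectra` and `truth`.
#' @export
simulate_cohort <- function(config, panel, dir, bg = NULL) {
  stopifnot(!is.null(config$seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inst <- utils::modifyList(default_instrument(), config$instrument %||% list())
  if (is.null(bg)) bg <- build_background_db(panel, seed = config$seed)
  set.seed(config$seed)
  all_spectra <- list(); truths <- list(); paths <- character()
  meta <- list()
  for (entry in config$samples) {
    sim <- simulate_sample(entry, panel, inst, bg)
    p <- file.path(dir, paste0(entry$sample_id, ".mgf"))
    write_mgf(sim$spectra, p)
    paths[entry$sample_id] <- p
    all_spectra <- c(all_spectra, sim$spectra)
    truths[[length(truths) + 1L]] <- sim$truth
    meta[[length(meta) + 1L]] <- data.frame(
      sample_id = entry$sample_id, region = entry$region %||% NA_character_,
      is_control = entry$is_control %||% "none",
      pooled = isTRUE(entry$pooled),
      n_true = if ((entry$is_control %||% "none") != "none") 0L else entry$n_true,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truths)) do.call(rbind, truths) else NULL
  truth_tsv <- file.path(dir, "truth.tsv")
  samples_tsv <- file.path(dir, "samples.tsv")
  config_json <- file.path(dir, "config.json")
  if (!is.null(truth)) {
    utils::write.table(truth, truth_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.table(data.frame(), truth_tsv, sep = "\t", row.names = FALSE)
  }
  meta_df <- if (length(meta)) do.call(rbind, meta) else data.frame()
  utils::write.table(meta_df, samples_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, instrument = inst,
         n_samples = length(config$samples)),
    config_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(mgf = paths, truth_tsv = truth_tsv, samples_tsv = samples_tsv,
                 config_json = config_json, spectra = all_spectra,
                 truth = truth, samples = meta_df,
                 background_seed = config$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study-shaped cohort template
#'
#' Builds a simulation configuration whose regional structure mirrors the
#' Eurasian survey this package reanalyses: the bundled per-region sample
#' and positive counts, total BLG spectra distributed over each region's
#' positives, the published species structure of the positives (cattle-,
#' sheep- and goat-specific consumers, multi-species consumers, and
#' bovid-level-only samples) and a pooled Norway extract. `scale` shrinks
#' the per-sample spectral load for quick test runs without changing the
#' cohort shape.
#'
#' @param seed Simulation seed.
#' @param scale Multiplier on per-sample true/background spectral counts
#'   (default 1; counts are floored at 1 for positives).
#' @param n_background Background spectra per sample before scaling
#'   (default 10).
#' @return Config list for [simulate_cohort()].
#' @export
cohort_template <- function(seed = 1L, scale = 1, n_background = 10L) {
  tab <- survey_cohort()
  tab <- tab[tab$eurasian, , drop = FALSE]
  # species structure of the positives: 4 cattle, 3 sheep, 2 goat,
  # 3 multi-species consumers; the remaining positives are simulated as
  # cattle-milk consumers (some bovid had to produce their BLG; whether
  # species-diagnostic peptides are *detected* in a sample is an outcome
  # of the search, not an input)
  mixes <- c(rep(list(c(Bos = 1)), 4),
             rep(list(c(Ovis = 1)), 3),
             rep(list(c(Capra = 1)), 2),
             rep(list(c(Bos = 0.5, Ovis = 0.5)), 2),
             rep(list(c(Ovis = 0.5, Capra = 0.5)), 1),
             rep(list(c(Bos = 1)), 10))  # filled up to the positive count
  samples <- list(); mi <- 0L
  nbg <- max(1L, round(n_background * scale))
  for (r in seq_len(nrow(tab))) {
    npos <- tab$n_positive[r]; n <- tab$n_samples[r]
    spectra_each <- if (npos > 0) {
      base <- tab$total_spectra[r] %/% npos
      extra <- tab$total_spectra[r] %% npos
      pmax(1L, round((base + c(rep(1L, extra), rep(0L, npos - extra))) * scale))
    } else integer()
    for (k in seq_len(n)) {
      pos <- k <= npos
      if (pos) mi <- mi + 1L
      samples[[length(samples) + 1L]] <- list(
        sample_id = sprintf("%s_%02d", gsub("[^A-Za-z]", "", tab$region[r]), k),
        region = tab$region[r],
        species_mix = if (pos) mixes[[min(mi, length(mixes))]] else NULL,
        n_true = if (pos) spectra_each[k] else 0L,
        n_background = nbg,
        is_control = "none",
        pooled = pos && isTRUE(tab$pooled_note[r]))
    }
  }
  list(seed = seed, samples = samples)
}

#' Simulate LP allele-frequency observations
#'
#' Points are placed uniformly in the given window; each point's combined
#' causal-allele frequency is drawn binomially around a smooth latent field
#' (sampling `2 * sample_size` chromosomes), so dispersion shrinks with
#' sample size.
#'
#' @param n Number of points.
#' @param field Function `f(lon, lat)` giving the latent allele frequency.
#' @param lon_range,lat_range Sampling window (degrees).
#' @param sample_sizes Pool of sample sizes drawn from (default 20-200).
#' @param seed Optional seed.
#' @return Data frame with `lon`, `lat`, `allele_freq`, `sample_size`,
#'   `latent_p`.
#' @export
simulate_lp_points <- function(n, field = function(lon, lat) 0.4,
                               lon_range = c(-10, 40), lat_range = c(35, 70),
                               sample_sizes = 20:200, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lon <- stats::runif(n, lon_range[1], lon_range[2])
  lat <- stats::runif(n, lat_range[1], lat_range[2])
  p <- pmin(1, pmax(0, field(lon, lat)))
  ss <- sample(sample_sizes, n, replace = TRUE)
  af <- stats::rbinom(n, 2L * ss, p) / (2 * ss)
  data.frame(lon = lon, lat = lat, allele_freq = af, sample_size = ss,
             latent_p = p)
}
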