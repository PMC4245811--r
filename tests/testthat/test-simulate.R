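small_cfg <- function(seed = 42L, ...) {
  utils::modifyList(list(seed = seed, samples = list(
    list(sample_id = "S1", region = "A", species_mix = c(Bos = 1),
         n_true = 6L, n_background = 4L, is_control = "none"),
    list(sample_id = "B1", region = "A", species_mix = NULL,
         n_true = 0L, n_background = 6L, is_control = "blank"))),
    list(...))
}

test_that("cohort simulation is byte-identical given the seed", {
  pan <- full_panel()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(small_cfg(), pan, d1)
  simulate_cohort(small_cfg(), pan, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  d3 <- withr::local_tempdir()
  simulate_cohort(small_cfg(seed = 43L), pan, d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "S1.mgf"))),
                         unname(tools::md5sum(file.path(d3, "S1.mgf")))))
})

test_that("noiseless spectra are recovered as their generating peptides", {
  pan <- full_panel()
  cfg <- list(seed = 7L,
              instrument = list(peak_dropout = 0, noise_peaks = 0L,
                                deamidation_rate = 0,
                                mass_error_sd_ppm = 0, fragment_error_sd_da = 0),
              samples = list(list(sample_id = "N1", region = "A",
                                  species_mix = c(Bos = 1), n_true = 20L,
                                  n_background = 0L, is_control = "none")))
  d <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, pan, d)
  sp <- read_mgf(sim$mgf[["N1"]])
  psms <- search_spectra(sp, pan,
                         background = build_background_db(pan, cfg$seed))
  joined <- merge(sim$truth, psms, by = "spectrum_id")
  expect_identical(nrow(joined), 20L)
  expect_identical(joined$sequence.x, joined$sequence.y)
  expect_identical(joined$mods.x, joined$mods.y)
  expect_true(all(joined$score > 25))
})

test_that("full deamidation marks every N/Q and still matches", {
  pan <- full_panel()
  cfg <- list(seed = 11L, instrument = list(deamidation_rate = 1),
              samples = list(list(sample_id = "D1", region = "A",
                                  species_mix = c(Ovis = 1), n_true = 15L,
                                  n_background = 0L, is_control = "none")))
  d <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, pan, d)
  has_nq <- grepl("[NQ]", sim$truth$sequence)
  expect_true(all(grepl("deamidated", sim$truth$mods[has_nq])))
  sp <- read_mgf(sim$mgf[["D1"]])
  psms <- search_spectra(sp, pan, background = build_background_db(pan, 11L))
  acc <- fdr_filter(psms)$accepted
  expect_gte(nrow(acc), 14L)  # deamidated forms are in the search space
})

test_that("control samples refuse true spectra and zero-sample configs work", {
  pan <- full_panel()
  bad <- list(sample_id = "C1", region = "A", species_mix = c(Bos = 1),
              n_true = 3L, n_background = 2L, is_control = "blank")
  expect_error(simulate_sample(bad, pan), "control samples")
  expect_error(
    simulate_sample(list(sample_id = "Z", region = "A",
                         species_mix = c(Mammoth = 1), n_true = 2L,
                         n_background = 0L, is_control = "none"), pan),
    "proportions|absent")
  d <- withr::local_tempdir()
  out <- simulate_cohort(list(seed = 1L, samples = list()), pan, d)
  expect_length(out$spectra, 0)
})

test_that("generated spectra are finite, positive, and MGF round-trip", {
  pan <- full_panel()
  d <- withr::local_tempdir()
  sim <- simulate_cohort(small_cfg(seed = 5L), pan, d)
  for (s in sim$spectra) {
    expect_true(all(is.finite(s$mz)) && all(s$mz > 0))
    expect_true(all(is.finite(s$intensity)) && all(s$intensity > 0))
    expect_false(is.unsorted(s$mz))
  }
  back <- read_mgf(sim$mgf[["S1"]])
  expect_length(back, sum(sim$truth$sample_id == "S1"))
  expect_equal(back[[1]]$mz, sim$spectra[[1]]$mz, tolerance = 1e-4)
})

test_that("LP point simulation recovers the latent field within binomial error", {
  pts <- simulate_lp_points(150, field = function(lon, lat) 0.4, seed = 19L)
  expect_true(all(pts$allele_freq >= 0 & pts$allele_freq <= 1))
  g <- lp_grid(c(-10, 40), c(35, 70), nx = 8, ny = 8)
  s <- smooth_lp_surface(pts, sigma = 20, grid = g)
  expect_true(all(abs(s$values - phenotype_freq(0.4)) < 0.05, na.rm = TRUE))
  # dispersion shrinks with sample size
  set.seed(19)
  small_n <- simulate_lp_points(200, sample_sizes = 10L)
  big_n <- simulate_lp_points(200, sample_sizes = 500L)
  expect_gt(stats::sd(small_n$allele_freq), stats::sd(big_n$allele_freq))
  expect_identical(nrow(simulate_lp_points(1)), 1L)
})
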