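test_that("theoretical fragments match hand-computed b/y ladders", {
  fr <- theoretical_fragments("AGK")
  expect_identical(nrow(fr), 4L)  # 2(n-1) singly charged ions
  expect_equal(fr$mz[fr$ion == "b2"], 129.06585, tolerance = 1e-5)
  expect_equal(fr$mz[fr$ion == "y1"], 147.11280, tolerance = 1e-5)
  # doubly charged variants double the count
  expect_identical(nrow(theoretical_fragments("AGK", max_frag_charge = 2)), 8L)
  # a modification shifts exactly the ions containing its residue
  plain <- theoretical_fragments("NGQK")
  mod <- theoretical_fragments("NGQK", "3:deamidated")
  expect_equal(mod$mz[mod$ion == "b3"] - plain$mz[plain$ion == "b3"],
               0.98402, tolerance = 1e-5)
  expect_equal(mod$mz[mod$ion == "y2"] - plain$mz[plain$ion == "y2"],
               0.98402, tolerance = 1e-5)
  expect_equal(mod$mz[mod$ion == "b2"], plain$mz[plain$ion == "b2"])
  expect_equal(mod$mz[mod$ion == "y1"], plain$mz[plain$ion == "y1"])
})

test_that("binomial ion score equals exact tail summation", {
  exact_tail <- function(k, n, p) sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
  expect_equal(binomial_ion_score(10, 10, 0.01)$score, 200, tolerance = 1e-6)
  for (case in list(c(5, 10, 0.05), c(3, 18, 0.007), c(1, 4, 0.5))) {
    b <- binomial_ion_score(case[1], case[2], case[3])
    expect_equal(b$p_value, exact_tail(case[1], case[2], case[3]),
                 tolerance = 1e-10)
    expect_equal(b$score, -10 * log10(exact_tail(case[1], case[2], case[3])),
                 tolerance = 1e-6)
  }
  expect_identical(binomial_ion_score(0, 10, 0.1)$score, 0)
})

test_that("candidate sets respect the ppm window and are tolerance-monotone", {
  set.seed(21)
  masses <- sort(runif(500, 600, 3500))
  forms <- data.frame(sequence = sprintf("P%03d", seq_along(masses)),
                      mono_mass = masses)
  theo_mz <- (masses[250] + 2 * MASS_PROTON) / 2
  hit <- candidate_peptides(theo_mz, 2, forms, tol_ppm = 10)
  expect_true("P250" %in% hit$sequence)
  expect_true("P250" %in% candidate_peptides(theo_mz * (1 + 9.9e-6), 2, forms, 10)$sequence)
  expect_false("P250" %in% candidate_peptides(theo_mz * (1 + 10.1e-6), 2, forms, 10)$sequence)
  # monotonicity vs a brute-force scan, many random precursors
  for (i in 1:40) {
    mz <- runif(1, 300, 1800); z <- sample(2:4, 1)
    c5 <- candidate_peptides(mz, z, forms, 5)$sequence
    c10 <- candidate_peptides(mz, z, forms, 10)$sequence
    expect_true(all(c5 %in% c10))
    brute <- forms$sequence[abs((forms$mono_mass + z * MASS_PROTON) / z - mz) /
                              ((forms$mono_mass + z * MASS_PROTON) / z) * 1e6 <= 10]
    expect_setequal(c10, brute)
  }
})

test_that("the ion score ignores peak order and intensity scale", {
  pep <- "LIVTQTMK"
  fr <- theoretical_fragments(pep)
  set.seed(9)
  mz <- c(fr$mz, runif(20, 150, 900))
  inten <- runif(length(mz), 1, 100)
  sp <- list(spectrum_id = "x", sample_id = "x",
             precursor_mz = 0, charge = 2L, mz = mz, intensity = inten)
  base <- score_psm(sp, pep)
  perm <- sample(seq_along(mz))
  sp2 <- sp; sp2$mz <- mz[perm]; sp2$intensity <- inten[perm] * 1000
  again <- score_psm(sp2, pep)
  expect_equal(base$score, again$score)
  expect_identical(base$matched, again$matched)
  expect_identical(base$matched, nrow(fr))
  # degenerate spectra score zero
  empty <- list(spectrum_id = "e", mz = numeric(), intensity = numeric())
  expect_identical(score_psm(empty, pep)$score, 0)
  one <- list(spectrum_id = "o", mz = 500, intensity = 1)
  expect_identical(score_psm(one, pep)$score, 0)
})

test_that("greedy matching uses each peak at most once", {
  pep <- "GGK"  # b1 57+p, b2 114+p, y1, y2
  fr <- theoretical_fragments(pep)
  # a single peak near two fragments can only be matched once
  sp <- list(mz = c(fr$mz[1], fr$mz[1] + 0.01, 800), intensity = c(1, 1, 1))
  got <- score_psm(sp, pep)
  expect_lte(got$matched, 2L)
})

test_that("FDR filtering is monotone and handles the edge cases", {
  psms <- data.frame(
    spectrum_id = sprintf("s%d", 1:8),
    score = c(90, 80, 60, 40, 30, 28, 10, 5),
    p_value = 10^(-c(9, 8, 6, 4, 3, 2.8, 1, 0.5)),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  r <- fdr_filter(psms, score_cutoff = 25, alpha = 0.05)
  expect_identical(nrow(r$accepted), 5L)
  expect_equal(r$estimated_fdr, 1 / 5)
  # all targets above cutoff, zero decoys
  clean <- psms[!psms$is_decoy & psms$score >= 25, ]
  expect_equal(fdr_filter(clean, 25, 0.05)$estimated_fdr, 0)
  # equal targets and decoys above the cutoff
  even <- data.frame(spectrum_id = c("a", "b"), score = c(50, 50),
                     p_value = c(1e-5, 1e-5), is_decoy = c(FALSE, TRUE))
  expect_equal(fdr_filter(even, 25, 0.05)$estimated_fdr, 1.0)
  # monotonicity: raising the cutoff never adds accepted PSMs
  cuts <- c(0, 10, 25, 50, 80, 100)
  sizes <- vapply(cuts, function(ct) nrow(fdr_filter(psms, ct, 0.05)$accepted), 0L)
  expect_true(all(diff(sizes) <= 0))
})
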