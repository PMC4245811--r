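test_that("panel FASTA parsing follows the header convention", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">X1|SpA|lineage:Root>SpA", "acdef",
               ">X2|SpB|lineage:Root>SpB", "GHIKL"), f)
  recs <- read_panel_fasta(f)
  expect_length(recs, 2)
  expect_identical(vapply(recs, `[[`, "", "species"), c("SpA", "SpB"))
  expect_identical(recs[[1]]$sequence, "ACDEF")  # uppercased

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_identical(read_panel_fasta(empty), list())

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">X1|SpA", "ACDEF"), bad)
  expect_error(read_panel_fasta(bad), "malformed panel FASTA header")

  badlin <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">X1|SpA|lineage:Root>Other", "ACDEF"), badlin)
  expect_error(read_panel_fasta(badlin), "must end at its species")
})

test_that("decoys are reversed, flagged, and composition-preserving", {
  pan <- toy_panel()
  expect_length(pan$decoy_records, length(pan$records))
  for (i in seq_along(pan$records)) {
    t <- pan$records[[i]]$sequence
    d <- pan$decoy_records[[i]]$sequence
    expect_identical(d, paste(rev(strsplit(t, "")[[1]]), collapse = ""))
    expect_identical(sort(strsplit(t, "")[[1]]), sort(strsplit(d, "")[[1]]))
    expect_true(startsWith(pan$decoy_records[[i]]$accession, "DECOY_"))
  }
  expect_identical(sum(pan$forms$is_decoy) > 0, TRUE)
  # palindromic sequence: decoy equals target but stays flagged
  rec <- list(list(accession = "P", species = "P",
                   lineage = c("Root", "P"), sequence = "GAKAG"))
  pp <- build_panel(rec, min_len = 1L, max_len = 10L, semi = FALSE,
                    mass_range = c(1, 5000))
  expect_identical(pp$decoy_records[[1]]$sequence, "GAKAG")
  expect_true(all(pp$forms$is_decoy[startsWith(pp$forms$accession, "DECOY_")]))
})

test_that("decoy digestion uses identical parameters to targets", {
  set.seed(3)
  for (i in 1:8) {
    s <- random_peptide(30, alphabet = names(AA_MONO))
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    # oracle comparison: decoy peptide count equals brute-force on reversal
    got <- digest_sequence(r, 2, 7, 30, semi = TRUE)
    want <- digest_oracle(r, 2, 7, 30, semi = TRUE)
    expect_identical(interval_key(got), interval_key(want))
  }
})

test_that("modified-form enumeration covers the documented combinations", {
  # no eligible sites -> the peptide itself, unmodified
  f0 <- modified_forms("GAVLK")
  expect_identical(nrow(f0), 1L)
  expect_identical(f0$mods, "")

  # two deamidation sites -> 4 forms (0, 1, 1, 2 deamidations)
  f1 <- modified_forms("NQ", max_variable = 2)
  expect_identical(nrow(f1), 4L)
  masses <- sort(round(f1$mono_mass - min(f1$mono_mass), 5))
  expect_equal(masses, c(0, 0.98402, 0.98402, 1.96804), tolerance = 1e-5)

  # cysteine: every form carries the fixed carbamidomethyl
  fc <- modified_forms("ACK")
  expect_true(all(grepl("carbamidomethyl", fc$mods)))
  expect_equal(min(fc$mono_mass), peptide_mass("ACK") + 57.02146,
               tolerance = 1e-5)

  # pyroglutamate only on an N-terminal Q; acetyl only on protein N-term
  expect_true(any(grepl("pyroglutamate", modified_forms("QAK")$mods)))
  expect_false(any(grepl("pyroglutamate", modified_forms("AQK")$mods)))
  expect_false(any(grepl("acetyl", modified_forms("QAK")$mods)))
  expect_true(any(grepl("acetyl", modified_forms("QAK", protein_nterm = TRUE)$mods)))

  # max_variable caps simultaneous variable modifications
  f3 <- modified_forms("NQNQ", max_variable = 1)
  expect_identical(nrow(f3), 5L)  # unmodified + 4 singles
})

test_that("peptide diagnosticity equals brute-force LCA on a toy panel", {
  pan <- toy_panel()
  # brute-force oracle over all unique target peptides
  digests <- lapply(pan$records, function(r)
    collapse_seq(digest_sequence(r$sequence, 2, 5, 10, semi = FALSE)$sequence))
  species <- vapply(pan$records, `[[`, "", "species")
  for (pep in unique(pan$peptidome$sequence)) {
    key <- collapse_seq(pep)
    containing <- species[vapply(digests, function(d) key %in% d, TRUE)]
    want <- if (!length(containing)) NA_character_ else {
      paths <- lapply(containing, function(sp) pan$lineages[[sp]])
      k <- 1
      while (all(vapply(paths, function(p) length(p) >= k && p[k] == paths[[1]][k], TRUE))) k <- k + 1
      paths[[1]][k - 1]
    }
    expect_identical(diagnostic_taxon(pep, pan), want, info = pep)
  }
  # constructed expectations on the toy tree
  expect_identical(diagnostic_taxon("GGGGGGK", pan), "Root")
  expect_identical(diagnostic_taxon("AAAAAAK", pan), "CladeAB")
  expect_identical(diagnostic_taxon("WWWWWWK", pan), "A")
  expect_identical(diagnostic_taxon("MMMMMMK", pan), NA_character_)
})

test_that("lowest common ancestor respects lineage paths", {
  lin <- toy_lineages()
  expect_identical(taxon_lca(c("Ovis", "Capra"), lin), "Caprinae")
  expect_identical(taxon_lca(c("Bos", "Ovis"), lin), "Bovidae")
  expect_identical(taxon_lca(c("Bos", "Pecora"), lin), "Pecora")
  expect_identical(taxon_lca("Bos", lin), "Bos")
  expect_identical(taxon_lca(character(), lin), NA_character_)
})

test_that("consensus of identical sequences is that sequence", {
  recs <- list(
    list(accession = "a", species = "A", lineage = c("R", "A"),
         sequence = "GGKAAKTTK"),
    list(accession = "b", species = "B", lineage = c("R", "B"),
         sequence = "GGKAAKTTK"))
  pan <- build_panel(recs, min_len = 2, max_len = 9, semi = FALSE,
                     mass_range = c(1, 5000))
  expect_identical(pan$consensus, "GGKAAKTTK")
  # single substitution: majority falls back to first-seen residue on ties
  recs[[2]]$sequence <- "GGKSAKTTK"
  pan2 <- build_panel(recs, min_len = 2, max_len = 9, semi = FALSE,
                      mass_range = c(1, 5000))
  expect_identical(nchar(pan2$consensus), 9L)
  expect_identical(substr(pan2$consensus, 4, 4), "A")
})
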