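test_that("sample consensus follows LCA semantics over peptide assignments", {
  lin <- toy_lineages()
  a <- data.frame(
    peptide_seq = c("p1", "p2"),
    diagnostic_taxon = c("Bos", "Pecora"),
    spectra_count = c(2L, 5L))
  r <- sample_consensus(a, lin, "S1")
  expect_identical(r$consensus_taxon, "Pecora")
  expect_identical(r$species_hits, "Bos")
  expect_false(r$multi_species)
  expect_true(r$positive)
  expect_identical(r$total_blg_spectra, 7L)

  b <- data.frame(peptide_seq = c("q1", "q2"),
                  diagnostic_taxon = c("Ovis", "Capra"),
                  spectra_count = c(1L, 1L))
  rb <- sample_consensus(b, lin, "S2")
  expect_setequal(rb$species_hits, c("Ovis", "Capra"))
  expect_true(rb$multi_species)
  expect_identical(rb$consensus_taxon, "Caprinae")

  e <- data.frame(peptide_seq = character(), diagnostic_taxon = character(),
                  spectra_count = integer())
  re <- sample_consensus(e, lin, "S3")
  expect_false(re$positive)
  expect_true(is.na(re$consensus_taxon))
})

test_that("adding peptides moves the consensus only toward the root", {
  lin <- toy_lineages()
  depth <- function(node) if (is.na(node)) Inf else {
    for (l in lin) { i <- match(node, l); if (!is.na(i)) return(i) }
    stop("unknown node")
  }
  set.seed(13)
  nodes <- c("Bos", "Ovis", "Capra", "Caprinae", "Bovidae", "Pecora", "Mammalia")
  for (rep in 1:20) {
    picks <- sample(nodes, 5, replace = TRUE)
    prev_depth <- Inf
    for (k in seq_along(picks)) {
      a <- data.frame(peptide_seq = paste0("p", seq_len(k)),
                      diagnostic_taxon = picks[seq_len(k)],
                      spectra_count = rep(1L, k))
      d <- depth(sample_consensus(a, lin)$consensus_taxon)
      expect_lte(d, prev_depth)
      prev_depth <- d
    }
  }
})

test_that("interval coverage equals the position-marking oracle", {
  expect_identical(interval_coverage(NULL, 100), 0)
  expect_equal(interval_coverage(data.frame(start = 0, end = 40), 40), 100)
  expect_equal(interval_coverage(data.frame(start = c(0, 5), end = c(10, 20)), 40), 50)
  expect_error(interval_coverage(data.frame(start = -1, end = 5), 40), "outside")
  expect_error(interval_coverage(data.frame(start = 0, end = 41), 40), "outside")

  set.seed(31)
  for (rep in 1:30) {
    L <- sample(20:120, 1)
    k <- sample(1:12, 1)
    st <- sample(0:(L - 1), k, replace = TRUE)
    en <- pmin(L, st + sample(1:25, k, replace = TRUE))
    iv <- data.frame(start = st, end = en)
    marks <- logical(L)
    for (i in seq_len(k)) marks[(st[i] + 1):en[i]] <- TRUE
    expect_equal(interval_coverage(iv, L), 100 * sum(marks) / L)
    # order and duplication invariance, monotonicity under addition
    expect_equal(interval_coverage(iv[sample(k), , drop = FALSE], L),
                 interval_coverage(rbind(iv, iv), L))
    expect_gte(interval_coverage(rbind(iv, data.frame(start = 0, end = 5)), L),
               interval_coverage(iv, L))
  }
})

test_that("peptides map to the consensus under matching equivalence", {
  cons <- "GGGGGAAAAATTTTTWWWWW"
  expect_equal(unname(map_peptide_to_consensus("AAAAATT", cons)), c(5, 12))
  # I/L equivalence maps to the same interval
  cons2 <- "GGGGGILLILTTTTT"
  expect_equal(unname(map_peptide_to_consensus("LLLLL", cons2)), c(5, 10))
  # N/D equivalence only when deamidation-aware
  cons3 <- "GGGGGNNNNNTTTTT"
  expect_equal(unname(map_peptide_to_consensus("DNDND", cons3)), c(5, 10))
  expect_null(map_peptide_to_consensus("DNDND", cons3, deamidation_aware = FALSE))
  expect_null(map_peptide_to_consensus("KKKKK", cons))
  # leftmost match wins
  expect_equal(unname(map_peptide_to_consensus("GGG", cons)), c(0, 3))
})

test_that("consensus coverage excludes unmappable peptides with a warning", {
  cons <- "GGGGGAAAAATTTTTWWWWW"
  expect_warning(
    out <- consensus_coverage(c("AAAAA", "KKKKK"), cons),
    "not mappable")
  expect_equal(out$coverage_pct, 25)
  expect_identical(nrow(out$intervals), 1L)
  clean <- consensus_coverage(c("GGGGG", "AAAAA"), cons)
  expect_equal(clean$coverage_pct, 50)
})

test_that("per-sample assignment joins peptides, taxa and coverage", {
  pan <- toy_panel()
  peptides <- data.frame(
    sample_id = c("S1", "S1", "S2"),
    peptide_seq = c("WWWWWWK", "GGGGGGK", "SSSSSSK"),
    spectra_count = c(2L, 3L, 1L))
  res <- assign_samples(peptides, pan, pooled_samples = "S2")
  expect_identical(res$S1$species_hits, "A")
  expect_identical(res$S1$consensus_taxon, "Root")
  expect_identical(res$S1$total_blg_spectra, 5L)
  expect_true(res$S2$pooled)
  expect_identical(res$S2$species_hits, "C")
  expect_gt(res$S1$coverage_pct, 0)
})
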