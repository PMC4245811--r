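# Shared fixtures: toy panels built in code, and a lazily built full panel
# cached across test files.

.cache <- new.env(parent = emptyenv())

# Full bundled panel with default (search) parameters; built once per run.
full_panel <- function() {
  if (is.null(.cache$panel)) .cache$panel <- build_panel(synthetic_panel_fasta())
  .cache$panel
}

# A three-species toy panel over a 3-level tree:
#   Root > CladeAB > A, Root > CladeAB > B, Root > C
# Sequences share a conserved core and carry clade-/species-private
# segments separated by tryptic K residues.
toy_records <- function() {
  list(
    list(accession = "TA", species = "A",
         lineage = c("Root", "CladeAB", "A"),
         sequence = "GGGGGGKAAAAAAKWWWWWWKTTTTTTK"),
    list(accession = "TB", species = "B",
         lineage = c("Root", "CladeAB", "B"),
         sequence = "GGGGGGKAAAAAAKYYYYYYKTTTTTTK"),
    list(accession = "TC", species = "C",
         lineage = c("Root", "C"),
         sequence = "GGGGGGKSSSSSSKFFFFFFKTTTTTTK"))
}

toy_panel <- function(...) {
  build_panel(toy_records(), min_len = 5L, max_len = 10L, semi = FALSE, ...)
}

toy_lineages <- function() {
  list(Bos = c("Mammalia", "Pecora", "Bovidae", "Bovinae", "Bos"),
       Ovis = c("Mammalia", "Pecora", "Bovidae", "Caprinae", "Ovis"),
       Capra = c("Mammalia", "Pecora", "Bovidae", "Caprinae", "Capra"))
}

# random peptide sequence without I (so I/L equivalence tests are explicit)
random_peptide <- function(len, alphabet = setdiff(names(AA_MONO), "I")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force digestion oracle: enumerate every substring and test the
# cleavage-rule predicate directly.
digest_oracle <- function(sequence, max_missed, min_len, max_len, semi) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  is_cut <- function(j) j >= 1 && j <= n - 1 && res[j] %in% c("K", "R") && res[j + 1] != "P"
  rows <- list()
  for (st in 0:(n - 1)) for (en in (st + 1):n) {
    len <- en - st
    if (len < min_len || len > max_len) next
    nt <- st == 0 || is_cut(st)
    ct <- en == n || is_cut(en)
    ntry <- nt + ct
    if (!(ntry == 2 || (semi && ntry == 1))) next
    missed <- if (en - st >= 2) sum(vapply((st + 1):(en - 1), is_cut, TRUE)) else 0L
    if (missed > max_missed) next
    rows[[length(rows) + 1L]] <- c(st, en)
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, rows)
  data.frame(start = m[, 1], end = m[, 2])
}

interval_key <- function(df) sort(paste(df$start, df$end, sep = "-"))
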