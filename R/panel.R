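# Multi-species BLG reference panel: sequences, taxonomy, consensus,
# decoys, and the searchable modified peptidome.

#' Read a BLG ortholog panel from FASTA
#'
#' Headers follow the convention
#' `>accession|species|lineage:Root>...>Species` — the lineage is an
#' ordered root-to-species path of taxon names. Sequences are upper-cased
#' and trailing `*` stop characters stripped.
#'
#' @param path FASTA file.
#' @return A list of protein records, each a list with `accession`,
#'   `species`, `lineage` (character vector, root first) and `sequence`.
#'   An empty file yields an empty list.
#' @export
read_panel_fasta <- function(path) {
  if (!file.exists(path)) stop("panel FASTA not found: ", path)
  if (file.size(path) == 0L) return(list())
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  lapply(seq_along(aa), function(i) {
    h <- headers[i]
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(parts) != 3L || !startsWith(parts[3], "lineage:")) {
      stop("malformed panel FASTA header (entry ", i, "): '", h,
           "' — expected 'accession|species|lineage:Root>...>Species'")
    }
    lineage <- strsplit(sub("^lineage:", "", parts[3]), ">", fixed = TRUE)[[1]]
    lineage <- trimws(lineage)
    species <- trimws(parts[2])
    if (!length(lineage) || lineage[length(lineage)] != species) {
      stop("lineage of entry ", i, " must end at its species ('", species, "')")
    }
    seq <- gsub("\\*", "", toupper(as.character(aa[[i]])))
    if (!nzchar(seq)) stop("empty sequence for entry ", i)
    list(accession = trimws(parts[1]), species = species,
         lineage = lineage, sequence = seq)
  })
}

#' Path to the bundled synthetic BLG ortholog panel
#'
#' A constructed six-species beta-lactoglobulin panel (bovine-like 162-residue
#' backbone with clade- and species-diagnostic substitutions for cattle,
#' water buffalo, sheep, goat, reindeer and horse). It is synthetic: built to
#' exercise genus/species discrimination, not a transcription of real
#' ortholog sequences.
#' @return File path.
#' @export
synthetic_panel_fasta <- function() {
  system.file("extdata", "blg_panel_synthetic.fasta", package = "paleomilk",
              mustWork = TRUE)
}

# ---- taxonomy (lineage-path) helpers ------------------------------------

#' Lowest common ancestor of taxonomy nodes
#'
#' The taxonomy is the rooted tree whose leaves are panel species and whose
#' root-to-leaf paths are the record lineages. `taxon_lca()` returns the
#' deepest node that is an ancestor-or-equal of every input node.
#'
#' @param nodes Character vector of taxon names (leaves or internal nodes).
#' @param lineages Named list (by species) of root-to-species paths.
#' @return A taxon name, or `NA_character_` when `nodes` is empty or a node
#'   is unknown.
#' @export
taxon_lca <- function(nodes, lineages) {
  nodes <- nodes[!is.na(nodes)]
  if (!length(nodes)) return(NA_character_)
  paths <- node_paths(lineages)
  if (!all(nodes %in% names(paths))) return(NA_character_)
  common <- Reduce(function(a, b) {
    k <- min(length(a), length(b))
    same <- which(a[seq_len(k)] == b[seq_len(k)])
    if (!length(same)) character() else a[seq_len(max(same))]
  }, paths[nodes])
  if (!length(common)) NA_character_ else common[length(common)]
}

# map every node (internal + leaf) to its root path
node_paths <- function(lineages) {
  paths <- list()
  for (lin in lineages) {
    for (d in seq_along(lin)) {
      nm <- lin[d]
      if (is.null(paths[[nm]]) || length(paths[[nm]]) < d) paths[[nm]] <- lin[seq_len(d)]
    }
  }
  paths
}

#' Collapse a peptide sequence under matching equivalence rules
#'
#' Leucine and isoleucine are mass-identical and always collapsed. When
#' deamidation-aware matching is on (the default for degraded samples),
#' Asn/Asp and Gln/Glu are additionally collapsed, because diagenetic
#' deamidation erases those distinctions.
#'
#' @param seq Amino-acid string(s).
#' @param deamidation_aware Collapse N/D and Q/E as well.
#' @return Collapsed string(s) usable as comparison keys.
#' @export
collapse_seq <- function(seq, deamidation_aware = TRUE) {
  s <- chartr("I", "L", seq)
  if (deamidation_aware) s <- chartr("DE", "NQ", s)
  s
}

# ---- consensus -----------------------------------------------------------

# Progressive pairwise alignment onto a growing profile: records are folded
# in input order; each is globally aligned (BLOSUM62, gap open 10 / extend
# 0.5) to the current consensus and per-column majority is taken, ties
# resolved in favour of the earlier-seen residue.
build_consensus <- function(records) {
  stopifnot(length(records) > 0L)
  profile <- strsplit(records[[1]]$sequence, "")[[1]]
  counts <- lapply(profile, function(a) stats::setNames(1L, a))
  for (rec in records[-1]) {
    cons <- paste(profile, collapse = "")
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(rec$sequence), Biostrings::AAString(cons),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    new_counts <- vector("list", length(s))
    j <- 0L
    for (k in seq_along(s)) {
      if (s[k] != "-") {
        j <- j + 1L
        new_counts[[k]] <- counts[[j]]
      } else new_counts[[k]] <- stats::setNames(integer(0), character(0))
      if (p[k] != "-") {
        cnt <- new_counts[[k]]
        cnt[p[k]] <- (if (p[k] %in% names(cnt)) cnt[[p[k]]] else 0L) + 1L
        new_counts[[k]] <- cnt
      }
    }
    counts <- new_counts
    profile <- vapply(counts, function(cnt) {
      if (!length(cnt)) return("-")
      names(cnt)[which.max(cnt)]  # ties: earliest-seen residue wins
    }, "")
  }
  paste(profile[profile != "-"], collapse = "")
}

# ---- modified-form enumeration ------------------------------------------

#' Enumerate modified forms of a peptide
#'
#' Applies the fixed carbamidomethyl modification to every cysteine and
#' generates all combinations of variable modifications (deamidation at
#' N/Q, oxidation at M, hydroxylation at P, pyroglutamate at an N-terminal
#' Q, acetylation of the protein N-terminus) with at most `max_variable`
#' variable sites modified and at most one modification per site.
#'
#' @param sequence Peptide sequence.
#' @param protein_nterm Is this the protein N-terminal peptide (enables
#'   acetylation)?
#' @param max_variable Maximum number of simultaneous variable mods.
#' @param catalogue Modification table, see [modification_catalogue()].
#' @return Data frame with columns `mods` (encoded string) and `mono_mass`;
#'   the first row is always the fixed-mods-only form.
#' @export
modified_forms <- function(sequence, protein_nterm = FALSE, max_variable = 2L,
                           catalogue = modification_catalogue()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  fixed <- data.frame(pos = which(res == "C"),
                      name = rep("carbamidomethyl", sum(res == "C")),
                      stringsAsFactors = FALSE)
  # candidate variable sites: (pos, name); at most one mod per site
  sites <- list()
  addsite <- function(pos, name) sites[[length(sites) + 1L]] <<- c(pos, name)
  for (p in which(res %in% c("N", "Q"))) addsite(p, "deamidated")
  for (p in which(res == "M")) addsite(p, "oxidation")
  for (p in which(res == "P")) addsite(p, "hydroxyproline")
  if (res[1] == "Q") addsite(1L, "pyroglutamate")
  if (protein_nterm) addsite(1L, "acetyl_nterm")
  base_mass <- peptide_mass(sequence, fixed)
  out_mods <- encode_mods(fixed); out_mass <- base_mass
  nsite <- length(sites)
  if (nsite > 0L && max_variable > 0L) {
    for (k in seq_len(min(max_variable, nsite))) {
      combos <- utils::combn(nsite, k, simplify = FALSE)
      for (cmb in combos) {
        pos <- as.integer(vapply(sites[cmb], `[`, "", 1L))
        nm <- vapply(sites[cmb], `[`, "", 2L)
        # one modification per residue position; acetyl (terminus) may
        # coexist with a residue mod only if that mod is not at position 1
        respos <- pos[nm != "acetyl_nterm"]
        if (anyDuplicated(respos)) next
        if ("acetyl_nterm" %in% nm &&
            any(respos == 1L & nm[nm != "acetyl_nterm"] == "pyroglutamate")) next
        out_mods <- c(out_mods,
                      encode_mods(rbind(fixed, data.frame(pos = pos, name = nm,
                                                          stringsAsFactors = FALSE))))
        out_mass <- c(out_mass, base_mass + sum(.mod_delta(nm)))
      }
    }
  }
  data.frame(mods = out_mods, mono_mass = out_mass, stringsAsFactors = FALSE)
}

# ---- panel assembly ------------------------------------------------------

#' Build a searchable BLG reference panel
#'
#' Ingests an ortholog FASTA (or a pre-parsed record list), builds the
#' progressive-alignment consensus, digests every target semi-tryptically,
#' enumerates modified forms, appends reversed-sequence decoys digested
#' with identical parameters, and precomputes each target peptide's
#' taxonomic diagnosticity (the lowest common ancestor of all panel species
#' containing it under the matching equivalence rules).
#'
#' @param x FASTA path or record list from [read_panel_fasta()].
#' @param max_missed,min_len,max_len,semi Digestion parameters, see
#'   [digest_sequence()].
#' @param max_variable Maximum simultaneous variable modifications.
#' @param mass_range Retain only forms with monoisotopic mass inside this
#'   window (Da); default 600–3500, a typical detectable range.
#' @param deamidation_aware Use N/D, Q/E-collapsed keys when computing
#'   diagnosticity (I/L are always collapsed).
#' @return An object of class `blg_panel`: list with `records`,
#'   `decoy_records`, `lineages`, `consensus`, `peptidome` (unique target
#'   peptides with diagnostic taxon) and `forms` (all searchable modified
#'   forms, targets and decoys, sorted by mass).
#' @export
build_panel <- function(x, max_missed = 2L, min_len = 7L, max_len = 30L,
                        semi = TRUE, max_variable = 2L,
                        mass_range = c(600, 3500),
                        deamidation_aware = TRUE) {
  records <- if (is.character(x)) read_panel_fasta(x) else x
  if (!length(records)) stop("panel has no records")
  species <- vapply(records, `[[`, "", "species")
  if (anyDuplicated(species)) stop("species must be unique within a panel")
  lineages <- stats::setNames(lapply(records, `[[`, "lineage"), species)

  decoys <- lapply(records, function(r) {
    r$accession <- paste0("DECOY_", r$accession)
    r$sequence <- paste(rev(strsplit(r$sequence, "")[[1]]), collapse = "")
    r
  })

  pep_t <- digest_records(records, FALSE, max_missed, min_len, max_len, semi)
  pep_d <- digest_records(decoys, TRUE, max_missed, min_len, max_len, semi)
  forms <- forms_table(rbind(pep_t, pep_d), max_variable, mass_range)

  # diagnosticity of unique target peptide sequences
  tgt <- pep_t
  key <- collapse_seq(tgt$sequence, deamidation_aware)
  sp_by_key <- split(tgt$species, key)
  uniq <- !duplicated(key)
  peptidome <- tgt[uniq, , drop = FALSE]
  peptidome$key <- key[uniq]
  peptidome$diagnostic_taxon <- vapply(peptidome$key, function(k) {
    taxon_lca(unique(sp_by_key[[k]]), lineages)
  }, "")
  rownames(peptidome) <- NULL

  structure(list(records = records, decoy_records = decoys,
                 lineages = lineages,
                 consensus = build_consensus(records),
                 peptidome = peptidome, forms = forms,
                 params = list(max_missed = max_missed, min_len = min_len,
                               max_len = max_len, semi = semi,
                               max_variable = max_variable,
                               mass_range = mass_range,
                               deamidation_aware = deamidation_aware)),
            class = "blg_panel")
}

# digest a record list into a peptide table
digest_records <- function(records, is_decoy, max_missed, min_len, max_len,
                           semi) {
  do.call(rbind, lapply(records, function(rec) {
    d <- digest_sequence(rec$sequence, max_missed, min_len, max_len, semi)
    if (nrow(d) == 0L) return(NULL)
    d$accession <- rec$accession
    d$species <- rec$species
    d$is_decoy <- is_decoy
    d
  }))
}

# expand a peptide table into mass-sorted, mass-filtered modified forms
forms_table <- function(peps, max_variable, mass_range) {
  forms <- do.call(rbind, lapply(seq_len(nrow(peps)), function(i) {
    f <- modified_forms(peps$sequence[i], protein_nterm = peps$start[i] == 0L,
                        max_variable = max_variable)
    cbind(peps[rep(i, nrow(f)), , drop = FALSE], f, row.names = NULL)
  }))
  forms <- forms[forms$mono_mass >= mass_range[1] &
                 forms$mono_mass <= mass_range[2], , drop = FALSE]
  forms <- forms[order(forms$mono_mass), , drop = FALSE]
  rownames(forms) <- NULL
  forms
}

#' Shuffled-sequence background database
#'
#' The oral-cavity background (host and bacterial proteins) against which
#' real spectra were searched is emulated by a decoy-like peptidome:
#' each panel sequence is shuffled (deterministically, given `seed`),
#' digested fully-tryptically with the panel's parameters, expanded to
#' modified forms and given its own reversed decoys. Including this
#' database in the search space lets non-BLG spectra be explained by their
#' own best match instead of surfacing as chance BLG candidates, which is
#' how a full-proteome search behaves.
#'
#' @param panel A `blg_panel`.
#' @param seed Integer seed for the shuffles.
#' @param n_per_record Shuffled copies per panel record (default 2).
#' @return List with `records` and `forms` (same columns as `panel$forms`,
#'   `species = NA`, accessions prefixed `BG_`).
#' @export
build_background_db <- function(panel, seed = 1L, n_per_record = 2L) {
  pr <- panel$params
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  records <- list()
  for (rec in panel$records) {
    for (k in seq_len(n_per_record)) {
      records[[length(records) + 1L]] <- list(
        accession = sprintf("BG_%s_%d", rec$accession, k),
        species = NA_character_,
        lineage = character(),
        sequence = paste(sample(strsplit(rec$sequence, "")[[1]]), collapse = ""))
    }
  }
  decoys <- lapply(records, function(r) {
    r$accession <- paste0("DECOY_", r$accession)
    r$sequence <- paste(rev(strsplit(r$sequence, "")[[1]]), collapse = "")
    r
  })
  pep <- rbind(
    digest_records(records, FALSE, pr$max_missed, pr$min_len, pr$max_len, FALSE),
    digest_records(decoys, TRUE, pr$max_missed, pr$min_len, pr$max_len, FALSE))
  list(records = records,
       forms = forms_table(pep, pr$max_variable, pr$mass_range))
}

# save/restore the RNG state so deterministic helpers do not disturb
# caller-level seeding
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.blg_panel <- function(x, ...) {
  cat("BLG reference panel\n")
  cat("  species:  ", paste(vapply(x$records, `[[`, "", "species"), collapse = ", "), "\n")
  cat("  consensus:", nchar(x$consensus), "residues\n")
  cat("  peptidome:", nrow(x$peptidome), "unique target peptides\n")
  cat("  forms:     ", nrow(x$forms), " searchable modified forms (",
      sum(x$forms$is_decoy), " decoy)\n", sep = "")
  invisible(x)
}

#' Taxonomic diagnosticity of a peptide sequence
#'
#' The lowest common ancestor of all panel species whose (unmodified)
#' digestion peptidome contains the sequence under the matching equivalence
#' rules (always I=L; optionally N=D, Q=E). `NA` when no panel species
#' contains it.
#'
#' @param sequence Peptide sequence.
#' @param panel A `blg_panel`.
#' @param deamidation_aware Apply the N/D, Q/E collapse (default follows
#'   the panel build).
#' @return Taxon name or `NA_character_`.
#' @export
diagnostic_taxon <- function(sequence, panel,
                             deamidation_aware = panel$params$deamidation_aware) {
  key <- collapse_seq(sequence, deamidation_aware)
  tgt <- panel$peptidome
  # the precomputed table is keyed with the panel's own collapse; recompute
  # species membership when the caller overrides the equivalence rules
  if (identical(deamidation_aware, panel$params$deamidation_aware)) {
    hit <- match(key, tgt$key)
    if (is.na(hit)) return(NA_character_)
    return(tgt$diagnostic_taxon[hit])
  }
  sp <- unique(tgt$species[collapse_seq(tgt$sequence, deamidation_aware) == key])
  if (!length(sp)) return(NA_character_)
  taxon_lca(sp, panel$lineages)
}
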