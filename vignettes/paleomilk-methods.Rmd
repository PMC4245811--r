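---
title: "Methods: detecting milk beta-lactoglobulin in ancient dental calculus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting milk beta-lactoglobulin in ancient dental calculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

β-lactoglobulin (BLG) is the dominant whey protein of ruminant milk. Humans
do not produce it, it survives well in mineralized dental plaque, and many
of its residues vary between dairy species. Finding BLG peptides in a
person's dental calculus is therefore direct evidence that they consumed
milk products, and the peptide sequences can indicate *whose* milk —
cattle, sheep, goat, or only some broader ruminant clade when the peptides
are not species-diagnostic. The package implements the full chain from peak
lists to regional summaries, plus a lactase-persistence (LP) map component
used for framing such surveys against present-day phenotype frequencies.

## Reference peptidome

The panel is read from a FASTA whose headers carry an accession, a species
and a root-to-species lineage path. Digestion is tryptic: cleavage
C-terminal to K or R, suppressed before P (the Keil rule, the common
search-engine default). A *semi-tryptic* mode adds peptides with exactly
one non-tryptic terminus, modelling the nonspecific truncation of degraded
ancient proteins; up to two missed cleavages are allowed. Peptide length is
bounded at 7–30 residues and modified-form mass at 600–3500 Da — a typical
detectable range; both are configurable.

Modifications follow the standard degraded-proteome set: fixed
carbamidomethylation of Cys (from alkylation during extraction) and
variable deamidation (N/Q, +0.98402 Da — the diagenetic hallmark),
N-terminal Gln→pyroglutamate (−17.02655 Da), Met oxidation, Pro
hydroxylation, and protein N-terminal acetylation. At most `max_variable`
(default 2) variable modifications are combined per peptide, one per site —
a compromise between search-space completeness and combinatorial growth;
the simulator draws deamidation patterns inside the same cap so that every
generated form is searchable.

Decoys are whole-sequence reversals, the simplest reproducible scheme:
one decoy record per target, digested with identical parameters.

**Matching equivalence.** Leucine and isoleucine are isobaric and are
always collapsed. Deamidation converts N→D and Q→E in the sample itself,
so under deamidation-aware matching (default on, flaggable off) N≡D and
Q≡E when comparing sequences. A peptide's *diagnostic taxon* is the lowest
common ancestor (LCA) of all panel species whose peptidome contains it
under these rules; a sample's consensus call is the LCA of its peptides'
diagnostic taxa, so extra evidence can only move the call root-ward, never
deeper.

**Consensus sequence.** The panel consensus is built by progressive
pairwise alignment (BLOSUM62, gap open 10 / extend 0.5), folding records in
input order and taking per-column majorities with ties resolved in favour
of the earlier-seen residue. How the original consensus was constructed is
not specified anywhere authoritative, so this documented, deterministic
scheme is the package's own choice; coverage figures are computed against
it, which is why a ±1 percentage-point ambiguity is attached to published
coverage comparisons.

**The bundled panel is synthetic.** The real ortholog set is not
redistributable here, so the package ships a constructed six-species panel:
a bovine-like 162-residue backbone with substitutions at non-K/R/P sites
defining Bovinae- (Bos, Bubalus), Caprinae- (Ovis, Capra), Cervidae-
(Rangifer) and outgroup (Equus) signals, 8–17 diagnostic sites per species.
Cleavage positions are identical across species by construction, which
keeps peptide intervals aligned. Any real panel in the documented FASTA
convention can be substituted.

## Spectral matching and the ion score

Peak lists are read from Mascot generic format, keeping the 200 most
intense peaks (mirroring the usual conversion). Searched precursor charges
are 2–5; spectra without a stated charge are tried at 2 and 3. Candidates
are all modified forms within ±10 ppm of the observed precursor m/z
(symmetric, relative window). Theoretical fragments are the full singly
charged b/y ladders; matching is greedy nearest-peak within ±0.07 Da, each
peak usable once; intensity is ignored (presence-only, the simplest model
consistent with an ion score).

With `k` of `n` fragments matched and per-fragment chance hit probability
`p_hit = n_peaks * 2 * tol / span` (span of the observed m/z range), the
chance probability is the exact binomial tail `P = Pr(X >= k | n, p_hit)`
and the ion score is `-10 log10 P`, floored at zero; degenerate spectra
(fewer than two peaks) score zero. This is a documented approximation, not
a re-implementation of any proprietary scorer; the nominal acceptance
filter — score ≥ 25 *and* `P < 0.05`, applied conjunctively because their
published relationship is ambiguous — is kept, and the synthetic generator
is parameterised so that true matches exceed it by a wide margin.

**Why a background database joins the search.** The original spectra were
searched against entire sequence repositories, so non-milk spectra are
claimed by their own best matches and never surface as BLG candidates. A
panel-only search has no such competitor: a background peptide that is
nearly isobaric with a panel peptide is often close to an anagram of it
(same residue multiset), shares many b/y partial sums, and scores high —
count-based scores *should* accept such evidence, and negative controls
would spuriously light up. The package therefore builds a shuffled-sequence
background database (each panel sequence shuffled, digested, modified, with
its own reversed decoys) and searches it alongside the panel; BLG calls are
accepted PSMs that hit panel targets. The simulator draws its background
spectra from the same database, so the emulation matches the mechanism of
the real workflow.

Target-decoy FDR is estimated as the number of decoy PSMs passing the
filter divided by the number of accepted targets. One best PSM is kept per
spectrum (ties: more matched fragments, then lexicographically smaller
peptide).

## Coverage, samples and cohorts

Accepted peptides are mapped to the leftmost exact occurrence in the
consensus under the matching equivalence; coverage is the union length of
the 0-based half-open intervals divided by the consensus length. Coverage
is monotone under added peptides and invariant to their order — both
property-tested against a position-marking oracle.

A sample is counted BLG-positive from a single accepted spectrum — the
weakest published positive is exactly one spectrum — and spectra counts are
reported so users can apply stricter thresholds. Pooled extracts (several
individuals, one sample) are flagged and counted once. Regional rows report
samples, positives and total spectra; `positive_fraction()` is exact
integer arithmetic reported to one decimal. The bundled
`survey_cohort()` transcription reproduces 19/74 = 25.7% positives across
the Eurasian rows, which the acceptance test checks exactly.

## Lactase-persistence surface

Combined causal-allele frequency `p` (five known LP enhancer variants,
treated as allelic at one locus and summed) maps to phenotype frequency
`1 − (1 − p)²` under Hardy–Weinberg with dominant expression. The surface
is a sample-size-weighted Nadaraya–Watson estimate with a Gaussian kernel
on planar lon/lat degrees — a deliberate simplification matching the
original planar construction; it distorts distances at high latitude.
"Lowest non-overflowing bandwidth" is interpreted as the smallest sigma on
a geometric ladder (0.25° × 1.25ᵏ) for which every grid cell's relative
kernel mass clears a configurable floor (default 10⁻⁶ of total weight);
cells below the floor are flagged unreliable rather than NaN-propagated.
Surface values are convex combinations of inputs, weight-scale invariant
and point-order invariant — all property-tested.

## Synthetic cohorts

The generator draws true spectra from the chosen species' unmodified
mass-eligible peptidome, perturbs fragments with Gaussian error of SD =
tolerance/3 (so ~99.7% of true peaks fall inside the matching windows — the
tolerances stay meaningful without modelling instrument physics), drops
peaks with probability 0.1, adds 30 uniform noise peaks, applies
deamidation per N/Q site at rate 0.3 (a mid-range diagenetic load), and
draws log-normal intensities (only rank matters, via the 200-peak cap).
Controls (blank and protein-standard) carry background spectra only, and
the generator refuses configurations that put true BLG spectra in a
control. Output is deterministic given the seed, down to byte-identical
files.

`cohort_template()` encodes the study-shaped cohort: the bundled per-region
sample and positive counts, per-region spectra totals distributed over the
positives, a pooled extract where the survey had one, and the published
species structure of the positives (4 cattle, 3 sheep, 2 goat,
3 multi-species; remaining positives are simulated as cattle-milk
consumers — some bovid had to produce the protein, and whether
species-diagnostic peptides are *detected* is an outcome of the search, not
an input).

**What passing tests do and do not show.** The generator emulates mass
error, dropout, noise, deamidation, background competition and negative
controls. It does not emulate chromatography, isotope envelopes,
co-isolation chimeras, real bacterial proteomes, or the taphonomic biases
that concentrate surviving peptides in particular protein regions — so
synthetic coverage figures are typically higher than the published
reconstruction, and recovery rates on synthetic data bound the method's
behaviour under the modelled noise only, not its sensitivity on real
calculus.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
desk scale: the end-to-end calibration loop uses 20 seeds of five-sample
cohorts (10 true spectra per positive sample), the cohort-shape check uses
a 33-sample region at reduced spectral load, and the acceptance script
runs the full 74-sample survey shape at half spectral load (~340 spectra).
Ties in PSM ranking are broken deterministically; all file outputs use
fixed numeric formats so identical runs are byte-identical; probabilities
are computed on the log scale (`pbinom(..., log.p = TRUE)`) so scores like
200 (all of 10 fragments matched at p_hit = 0.01) are exact rather than
overflowing to infinity.

## Known limitations

* The ion score is calibrated only through its decoy channel; absolute
  score values are not comparable to any commercial engine.
* Coverage depends on the consensus-construction choice (±1 percentage
  point is a realistic ambiguity band).
* Planar-degree smoothing distorts high-latitude distances.
* The bundled panel is synthetic; species discrimination rates measured on
  it reflect its constructed variability (8–17 diagnostic sites per
  species), not the true ortholog divergence.
* Caseins and other milk proteins are out of scope; the machinery is
  peptide-generic but only BLG panels are bundled and tested.
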