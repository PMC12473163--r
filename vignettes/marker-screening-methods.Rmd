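---
title: "Methods: marker informativeness, supermatrices and distance trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker informativeness, supermatrices and distance trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerscreen)
```

This vignette is the package's own account of the statistics it computes,
the conventions it fixes where the field's practice is ambiguous, and what
its synthetic-data tests do and do not demonstrate.

## The problem

Shallow phylogenies — species and subspecies of a recently diversified
genus — are resolved by concatenating a handful of fast-evolving loci:
chloroplast intergenic spacers and introns, and the nuclear ribosomal
spacers (ITS, ETS). Before sequencing a sampling of populations, one
screens candidate regions *in silico* on the few annotated plastomes
available for the group, scoring each region by how much variation it
carries: substitutions (split into transitions and transversions), indels,
microsatellite arrays, and parsimony-informative sites. The most variable
regions are amplified, aligned, concatenated into partitioned
supermatrices, and handed to ML/Bayesian inference. This package
implements that screen and bookkeeping, plus a lightweight distance-tree
stage and a simulator with exact ground truth so that every detector can
be tested against known events.

## Conventions fixed up front

* **Coordinates.** All intervals are 0-based half-open internally.
  Conversion to 1-based inclusive coordinates happens only at format
  boundaries: GenBank feature locations on input, NEXUS charsets and
  RAxML partition lines on output.
* **Missing data.** The gap character is `-`; supermatrix padding for a
  taxon absent from a locus is `?` (absent data, distinguished from an
  inferred gap); `N` and all IUPAC ambiguity codes are treated as missing
  in every statistic. Extending the gaps-as-missing convention to
  ambiguity codes is deliberate: Sanger chromatograms routinely yield Ns,
  and counting them as states would inflate variation.
* **Taxon matching.** Exact string match after whitespace normalisation —
  no fuzzy matching. tRNA anticodon suffixes in gene names
  (`trnK-UUU`, `trnK(UUU)`) are stripped for matching but kept for
  display, because annotation dialects differ across records.
* **Newick dialect.** Support values are stored as internal-node labels
  (the common RAxML/BEAST convention); labels containing spaces are
  single-quoted on write.

## Region harvesting

The built-in catalogue lists 49 plastome regions (43 spacers, 6 introns)
routinely surveyed when choosing variable chloroplast markers. Extraction
rules:

* A **spacer** is the interval between the two nearest annotated copies of
  its flank genes. The result is orientation-normalised so the first-named
  gene is upstream; consequently a genome and its reverse complement yield
  the *identical* spacer sequence, which is what downstream alignment
  needs. When a gene is annotated multiple times (inverted-repeat copies),
  the copy pair minimising the spacer length is used; an exact tie is an
  error demanding explicit coordinates. Overlapping or abutting flanks
  produce a zero-length result flagged `empty`, not an error. One
  catalogue entry (`trnK-matK-trnK`) names the same tRNA on both flanks:
  it spans the two nearest distinct copies of that gene (the two exons of
  the maturase-carrying intron), so the "two distinct flank genes" rule is
  relaxed for this documented case.
* An **intron** is the interval between consecutive exon parts of its
  host gene, numbered from the gene's 5' end and delivered in the gene's
  orientation. This requires multi-part `join()` locations, which are
  therefore accepted (same strand only); `order()` and mixed-strand joins
  (trans-splicing) are rejected as a documented limitation.

Alignment of homologous copies uses a deterministic center-star procedure:
every sequence is globally aligned to the longest input (ties broken by
input order) under affine gap scoring, and the pairwise alignments are
merged "once a gap, always a gap". The pairwise step is exact affine-gap
dynamic programming (via Biostrings); the defaults — match +1, mismatch
−1, gap open −4, extend −1 per gapped position — are configuration
choices, with no claim that they reproduce any external aligner. The
center-star result is tested against an independently written
dynamic-programming oracle: on two-sequence inputs the achieved score
equals the DP optimum, and degapping any output row always reproduces its
input. For screen-scale loci (< 5 kb, a handful of records) this is
accurate and reproducible without external binaries; it is not a
general-purpose MSA tool.

## Informativeness statistics

* **Indel events.** Per row, maximal runs of `-` are candidate events;
  runs with identical (start, end) in several rows collapse into a single
  event carrying the pooled taxa — the event-counting convention of simple
  indel coding. Overlapping-but-unequal runs stay separate events.
  Terminal runs are excluded by default (ragged Sanger read ends are
  missing sequence, not deletions); `include_terminal = TRUE` restores
  them.
* **Substitutions.** Counted per column against the consensus: the most
  frequent unambiguous state (ties broken alphabetically) is the
  reference, and each distinct non-consensus state present contributes
  exactly one substitution, classified as a transition (A↔G, C↔T) or
  transversion. This is a reproducible formalisation of how a human
  tallies variants in an alignment editor; it is documented precisely so
  that differences from manually produced counts are interpretable. It is
  not a model-based estimate — no ancestral reconstruction, no multiple-hit
  correction — so at high divergence it undercounts events (a property the
  simulator tests assert as an inequality).
* **Microsatellites.** All maximal perfect tandem arrays of 1–6 bp motifs
  meeting per-motif-length repeat thresholds (defaults 10, 6, 4, 3, 3, 3
  for motif lengths 1–6). Motifs are reported in canonical
  (lexicographically smallest) rotation; arrays whose motif is a power of
  a shorter motif are reported once under the shortest motif; overlapping
  reports are suppressed in favour of the longer array. The thresholds are
  package defaults, not a claim about any web tool's settings. Per-row
  arrays are mapped through gaps into alignment coordinates, and arrays
  from different rows with the same canonical motif and overlapping spans
  merge into one counted locus — the package's answer to the (undefined in
  practice) question of whether SSR columns count per sequence or per
  alignment.
* **Parsimony-informative sites.** A column is informative iff at least
  two distinct unambiguous states each occur in at least two rows.

All detectors are verified against naive brute-force implementations
(definition-level column scans, per-start tandem extension) on hundreds of
randomised alignments per run, and all counts are invariant under row
permutation.

## Clade diagnostics

"Sites separating clade A from the rest" admits two readings, and the
package computes both rather than guessing: `fixed_difference` (the
ingroup is monomorphic for a state absent from every non-missing row
outside) and `strict` (additionally the complement is monomorphic).
Rows missing at a column are ignored; a column where either side retains
fewer than two non-missing rows is skipped, so a diagnostic site is always
also parsimony-informative. With two taxa per side minimum, relabelling
and row order cannot change the counts. On simulated data the
fixed-difference count equals the number of clean stem-branch
substitutions (events whose site saw no other event and whose net state
changed); the rare exceptions are genuinely interesting — e.g. a
substitution on the *complement's* stem combined with an outgroup deletion
at the same column produces a real fixed difference that no stem event
planted — and are why the recovery tests at nonzero background rates
report agreement rates rather than asserting blanket equality.

## Locus ranking and supermatrices

The screen's selection rule, "highest substitutions and microsatellite
counts", is formalised as a weighted score: substitutions per kb × `w_subs`
+ SSR locus count × `w_ssr`, defaults 1 and 1, ties broken alphabetically.
Because the original choice is ultimately expert judgement, the weights and
a top-*k* cut are configuration, and a fixed locus list can be pinned
explicitly. Both raw counts and per-kb rates are reported, since a
three-genome screen does not dictate the normalisation.

Concatenation takes the union of taxa in first-seen order and pads absent
taxon×locus blocks with `?`. Offsets are recorded 0-based half-open and
exported in each dialect's convention. The invariants asserted in tests:
total length is additive under any block permutation; per-locus statistics
computed inside the concatenation equal those of the standalone locus; and
padding never changes any statistic. The nuclear ITS block is treated as a
single locus (as amplified, spanning ITS1–5.8S–ITS2), matching how such
loci are reported in marker tables.

## Distance trees

The in-package tree engine is deliberately *not* ML or Bayesian inference:
those belong to external tools fed by the exported files. For verifying
two-lineage structure on desk-scale data, K2P + neighbor-joining +
bootstrap suffices and runs in milliseconds.

* **K2P** is evaluated in closed form, d = −½·ln((1−2P−Q)·√(1−2Q)), with
  pairwise deletion of missing columns (matching the `?`-padded
  supermatrix blocks; complete deletion would discard every column of a
  padded matrix). Outside the logarithm's domain the distance is flagged
  infinite and NJ refuses the matrix, listing the offending pairs. K2P ≥ p
  for every defined pair, with equality exactly at zero — a property test.
* **NJ** is the canonical Q-criterion agglomeration with two determinism
  guarantees: ties in Q are broken by the lexicographically smallest label
  pair, and negative branch-length estimates are clamped to zero with the
  deficit moved to the sister branch (preserving path lengths through the
  joined pair). Correctness is tested two ways: recovery of the generating
  topology on random additive matrices (4–8 taxa, exact property of NJ),
  and topological agreement with an independent NJ implementation.
* **Bootstrap** resamples columns with replacement, rebuilds the tree per
  replicate, and reports the percentage of replicates containing each
  original bipartition; a single integer seed makes runs reproducible.
  Replicates whose resampled matrix falls outside the K2P domain
  contribute nothing rather than aborting the run.

## The simulator and what the tests mean

The generator evolves each locus along a user tree under the same model
family the statistics assume: per-site Poisson substitution events with
transition probability κ/(κ+2) (so the expected transition:transversion
event ratio is κ/2), geometric-length insertions and deletions, and
whole-motif single-step SSR expansion/contraction — the simplest stepwise
model. Sites carry stable integer ids and insertions splice fresh ids into
a global column registry, so the true alignment is maintained *by
construction*: simulator accuracy is never confounded with alignment
error, and the event log replays byte-for-byte to every leaf (a tested
invariant).

The default study regime (`marker_regime()`) fixes the conditions once:
sixteen taxa in two clades plus a distant outgroup, and nine loci whose
aligned lengths (703, 903, 1002, 710, 611, 424, 1057, 702, 408 bp) and
per-locus event targets (tens of substitutions, 10–22 indels, 8–41 SSR
loci, nuclear loci more transition-biased and plastid spacers more
indel-rich) match a published marker-survey regime for this kind of group.
Rates are back-calculated as target/(length × total tree length), and κ
from the target ti:tv ratio (κ = 2·ti/tv). In this fixture indels are
deletions only and SSR steps contractions only, which pins every locus's
aligned length to its configured value — insertions would add stochastic
columns and break the length bookkeeping that the fixture exists to
exercise; the general simulator supports insertions and is tested with
them.

What passing tests show: the detectors recover exactly what the generator
planted, under the generator's assumptions — no rate heterogeneity across
sites, no alignment error (the truth alignment is exact), no coalescent
discordance, no hybridisation, independence across loci. Real data violate
most of these, so the tests validate the *counting machinery*, not the
biological inferences drawn from real alignments. In particular the
simulator cannot adjudicate the open questions above (how a human tallied
substitutions, how a web tool counted SSRs); it shows only that this
package's documented definitions are implemented correctly.

## Numerical and degenerate-input choices

* Center-star tie for the center: first-longest by input order.
* Consensus ties: alphabetical, everywhere, so counts are reproducible.
* NJ on three taxa uses the three-point formulas; negative estimates are
  clamped as above; an all-equal distance matrix resolves arbitrarily but
  deterministically.
* Saturated pairs (K2P domain violations) are `Inf` and rejected by NJ
  with an explicit pair list; zero shared columns give `NaN`, flagged.
* Zero-length spacers are flagged results; a region missing from some
  genomes is scored on the remaining ones and marked `partial`.
* All stochastic code draws from R's generator after a single `set.seed`;
  simulation traverses the tree in a fixed preorder so a seed fully
  determines the output.

## Problem sizes

The shipped tests run on the sizes the methods are meant for: random
alignments up to 20 × 200 for oracle equivalence (500+ per run), additive
matrices of 4–8 taxa (200 instances), bootstrap batches of 50 × 100
replicates on 10-taxon 1-kb matrices, and 100 replicates of the nine-locus
survey regime for calibration — a few minutes end to end on one CPU. These
sizes were chosen as representative of the screening workflows above;
larger supermatrices (hundreds of taxa) would want a compiled distance
kernel before anything else.

## Known limitations

* The aligner is center-star, adequate for close homologs; deep-divergence
  or highly repetitive loci need a dedicated MSA tool (externally aligned
  FASTA is accepted everywhere).
* Substitution counts are observed-variation tallies, not evolutionary
  distances; use the K2P machinery (or external ML) when a model-based
  quantity is needed.
* SSR detection is perfect-repeat only; imperfect/compound arrays are out
  of scope.
* GenBank parsing covers single records with gene/tRNA/rRNA/CDS/exon/
  intron features and simple or same-strand `join()` locations only.
* The tree stage is NJ: it verifies clade structure but does not replace
  ML/Bayesian inference, for which the package only prepares inputs.
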