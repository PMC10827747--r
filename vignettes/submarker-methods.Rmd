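---
title: "Subspecies marker discovery and quantification: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspecies marker discovery and quantification: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`submarker` separates two sister subspecies of one bacterial species in
shotgun metagenomes by building a private marker-gene database from
reference genomes and profiling reads against it. This vignette records the
models behind each stage, the tunable parameters with their defaults and
units, what the bundled simulator does and does not emulate, and the design
choices made where several defensible options existed.

## The marker model

A subspecies marker is a gene family present in (nearly) every genome of
one subspecies, absent from every genome of the sister subspecies, and
absent from other species. The three clauses map onto three stages:

1. **Pangenome construction** (`build_pangenome()`). Genes from all genomes
   are clustered greedily: genes are sorted by decreasing length (ties by
   sequence, making the result independent of input order), and each gene
   joins the first existing cluster whose representative — the founding,
   longest member — it matches at ≥ `identity_threshold` (default 0.95)
   over ≥ `coverage_threshold` (default 0.80) of the shorter sequence.
   Identity is matches divided by alignment columns of a local alignment
   seeded on shared 15-mers and banded (half-width 32) around the dominant
   diagonal, with scores +1/−1 and affine gap cost 2 + (L−1). The defaults
   are conventional pangenome settings: 95% identity is comfortably above
   the ~98% nucleotide identity of sister subspecies, so shared core
   families cluster across the subspecies boundary, while 80% coverage of
   the shorter gene keeps fragments from seeding spurious families.

2. **Candidate selection** (`select_candidates()`). With `n_s` genomes of
   the target subspecies, a cluster qualifies when its presence count is at
   least `ceiling(0.9 * n_s)` *and* it is absent from every genome of the
   sister subspecies. The ceiling form is chosen because it reproduces the
   canonical worked case: for 14 target genomes the minimum qualifying
   count is 13. Genomes labeled `unknown` are ignored entirely — an
   ambiguous reference can only erode specificity — and exclusions (e.g.
   flagged mis-annotations) are an explicit argument, never implicit.

3. **Specificity filtering** (`filter_specificity()`). Candidates are
   aligned against a user-supplied decoy collection of off-target species'
   genes and removed when any hit exceeds 90% identity over more than 50%
   of the candidate's length. The published form of this step runs BLAST
   against a comprehensive nucleotide database; the phrase ">90% alignment
   and over 50% coverage" is ambiguous between BLAST's `pident` and
   `qcovs`, and we mirror exactly those semantics: identity =
   matches/alignment columns of the best local alignment, coverage =
   aligned query span / candidate length. A decoy FASTA replaces the
   100+ GB database deliberately: the filter's correctness is a property of
   the rule, not of the database size, and a curated off-target gene set
   keeps the artifact testable at desk scale. Candidates shorter than the
   15-mer seed are evaluated by full dynamic programming against every
   decoy rather than skipped.

## Mis-annotation detection

Public reference annotations misassign subspecies often enough to poison
the "absent from the sister" clause. `detect_mislabeled()` clusters the
genomes' presence/absence profiles — average-linkage hierarchical
clustering on Jaccard distances, cut at k = 2 — and flags genomes whose
label disagrees with their group's majority label. The clustering method is
a design choice: the underlying observation is only that profiles form two
clear clusters, so any reasonable binary partition works, and on clean
two-subspecies structure the average-linkage cut coincides with the
exhaustive minimum within-group Jaccard partition (a property the test
suite verifies by enumeration on ≤ 12 genomes). Two further choices err
toward surfacing problems: a tie in a group's majority label flags every
labeled genome of the group, and flagged genomes are never dropped
automatically. Per-genome silhouette widths accompany the report so weak
separations are visible.

## Abundance estimation

Reads are mapped to markers by exact-k-mer seeding (k = 17, probes every 8
bases, both orientations) followed by ungapped scoring of each candidate
(marker, diagonal); a hit needs ≥ `min_identity` (default 0.95) over
≥ `min_aligned` (default 40) bases. 0.95 reflects subspecies-level
stringency: the two subspecies' shared genes differ by ~2%, so a read from
the wrong clade's near-homolog generally falls below threshold; markers,
being subspecies-private, are safer still. Each read is assigned to its
best marker. Two tie rules matter:

* best hits in **both clades** within Δidentity < 0.01 send the read to a
  species-level pool — it is confidently from the species but not
  attributable to a subspecies;
* an exact best-identity tie between distinct markers of the same clade
  discards the read as ambiguous.

Per-marker depth is aligned bases divided by marker length, computed over
*all* markers (zeros included). A clade's score is the truncated mean of
its markers' depths — with ≥ 10 markers, the top and bottom 10% are
discarded; with 3–9, the minimum and maximum; below 3, a plain mean. The
trimmed statistic follows the robust-averaging philosophy of marker-based
profilers: a single marker inflated by a conserved stretch or deflated by a
deletion should not dominate. The species pool is spread uniformly over all
markers and aggregated the same way; the **unclassified** remainder is
`max(0, species score − Σ clade scores)`, which is exactly the species
signal the subspecies markers cannot explain. Profiles are normalized so
the mapped share of reads is split across {clade A, clade B, unclassified}
proportionally to scores and **other** carries the unmapped remainder —
entries always sum to 100. Normalization spans only these four reserved
entries because the package profiles one species' subspecies; embedding the
result in a community-wide profile is the caller's composition step.
`clade_shares()` renormalizes within the species (dropping `other`), which
is the scale on which estimates are compared with qPCR. A clade is
*detected* at ≥ 0.5% relative abundance, boundary inclusive.

## Strain profiling

Because reads are already placed on individual markers, the multi-sequence
alignment step of read-based strain callers collapses to a per-position
pileup: a position is called when depth ≥ `min_depth` (default 3) and the
top allele reaches `majority` (default 0.8) of the pileup, else `N`; exact
allele ties are never called. Both defaults are conservative,
consensus-style values; with substitution-only alignments no gap states
arise. A marker is dropped for a sample when under half its positions are
callable, and a sample is kept only when ≥ `min_marker_count` markers
survive — default 50, matching the conventional minimum marker count for
strain-level profiling, scaled down to half the database when the database
itself holds fewer than 50 markers (a hard 50 would make small databases
unusable by construction). Pairwise distance is mismatches over jointly
called sites; a pair with no comparable sites is reported missing, never
zero. Trees are standard neighbor joining on the SNP distance matrix, with
samples sorted lexicographically first (deterministic tie-breaking) and
negative NJ branch lengths clamped to zero, the deficit moved to the
sibling edge. NJ is consistent on additive matrices — the test suite
verifies exact topology recovery on trees of 5–8 taxa — and mixed-strain
samples resolve to the majority (dominant) strain by construction of the
consensus.

## qPCR concordance

The delta-delta Ct method is applied as a within-sample two-target ratio:
replicate Ct values are averaged per target and
`fold = 2^-(Ct_A - Ct_B)`, giving shares `(fold/(1+fold), 1/(1+fold))`.
This within-sample form is the only one that yields a subspecies ratio
without an external calibrator sample. Amplification efficiency correction
(replacing base 2 with per-target efficiencies) is available but off by
default, since efficiencies are typically verified near 2 by dilution
series rather than corrected for. `agreement()` regresses qPCR shares on
computational shares by OLS and reports slope, intercept, R², and the
two-sided t-test p-value on the slope.

## The simulator

`sim_config()`/`simulate_references()`/`simulate_reads()` generate the
study system every test runs on: two subspecies sharing a core genome
(each carries its own variant, diverged 2% by default — sister subspecies
of one species sit near 98% average nucleotide identity, and the figure
must stay above the pangenome clustering threshold for core families to be
recognized as shared); ~200 subspecies-specific genes per side subject to a
7% per-genome dropout, so a typical specific gene lands in about 13 of 14
target genomes; optional genomes carrying one subspecies' repertoire under
the other's label (planted mis-annotations); per-genome strain SNPs on the
specific genes; a decoy set containing ~95%-identity full-length homologs
of a fraction of specific genes plus unrelated genes; and uniform-start,
substitution-error (0.5% default), both-strand 150 bp reads drawn with
per-clade mass proportional to the requested mixture. Ground truth —
realized presence fractions, the realized marker set, planted outliers,
strain SNP positions, decoy homologs — is emitted alongside and is
recomputable from the emitted sequences, a property the tests verify. All
randomness flows through R's RNG under a mandatory seed; identical config
and seed give identical output.

What the simulator does **not** emulate: indels (the error model is
substitution-only, matching the ungapped mapper; indel simulation would
require gapped read alignment), intergenic sequence and operon structure
(genomes are gene concatenations), compositional bias and quality-score
error profiles, horizontal transfer between the subspecies, and a realistic
off-target community (non-target organisms appear only as decoy genes and
unmapped read mass). Passing tests therefore demonstrate correctness of the
algorithms under a clean two-subspecies model, not robustness to every
artifact of real sequencing.

## Problem sizes

The default generator scale mirrors the reference setting (14 + 30 genomes,
~2,000 core and ~200 specific genes of mean length 1,000 bp). The test and
acceptance suites choose smaller gene counts and lengths (tens of genes,
300–500 bp) while keeping the scientifically load-bearing conditions — the
14 + 30 genome split for mis-annotation detection, 200,000-read samples for
mixture recovery, the planted mixture grid {0, 10, 25, 50, 75, 90, 100}% —
so the whole suite completes in minutes on one core.

## Numerical and degenerate-input conventions

All coordinates are 0-based, half-open. FASTA parsing tolerates wrapped
lines and CRLF; lowercase is upper-cased; ambiguity codes other than `N`
are mapped to `N` with a logged count. `N` never counts as a match in any
alignment. Profiles sum to 100 within 1e-6 for every input, including
zero-read samples (which report `other` = 100). Empty decoy sets,
single-clade databases, zero-variance regressions, and distance matrices
with missing entries all fail loudly with instructive messages rather than
degrade silently.

## Known limitations

* The greedy clustering assigns each gene to the first (not best) matching
  cluster; with thresholds far from the data's natural divergence bands
  this can split families that a centroid-updating clusterer would merge.
* The mapper is ungapped; reads spanning genuine indels lose identity
  rather than gaining gaps, which slightly depresses depth near indels in
  real data.
* Exactly two subspecies are supported per run, by design: the marker rule
  is inherently binary, and additional subspecies should be excluded from
  the reference set before discovery.
* The wet-lab concordance values reported for the original cohort require
  that cohort's DNA; the package reproduces the machinery and verifies it
  against simulated ground truth and pseudo-qPCR instead.
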