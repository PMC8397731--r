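---
title: "Methods: clade-aware pangenome partitioning with sedipan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-aware pangenome partitioning with sedipan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedipan)
```

`sedipan` implements the comparative-genomics workflow for clade-structured
archaeal genome collections: protein-family clustering, clade-quantified
pangenome partitioning, single-copy marker selection with supermatrix
assembly, sketch-based ANI, and MAG assembly statistics. This vignette
documents the models and procedures, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does not
establish.

## Pairwise alignment and the identity/coverage statistics

Family membership is defined by three statistics of a pairwise protein
alignment: identity, coverage of the longer sequence, and coverage of the
shorter sequence. `global_align()` computes the optimal **ends-free
semi-global alignment** (global alignment with unpenalised terminal gaps)
under BLOSUM62 with affine gaps (open 11, extend 1; a gap run of length
L inside the aligned core costs `11 + L`). With all four terminal gap runs
free, the optimum is the best-scoring contiguous aligned core, located by a
Gotoh three-state dynamic program implemented in C++. Traceback ties are
resolved deterministically (diagonal over gap-in-query over gap-in-pattern;
the best-scoring cell is the first such cell in row-major order), so results
are bit-reproducible.

From the aligned core we report:

* `identity_short` = identical aligned pairs / length of the **shorter**
  sequence. The shorter-sequence denominator is the global-identity
  convention of greedy clustering tools; published descriptions of the
  thresholds ("identity 35%") leave the denominator implicit, so the choice
  is stated here and recorded in output metadata.
* `cov_long`, `cov_short` = (last − first aligned position + 1) / sequence
  length, measured on each original sequence.

The test suite certifies the dynamic program against an independent oracle
that enumerates *every* alignment path of short sequences and scores it by
the same rules; optimal scores must agree exactly, and the reported match
count must be attainable by some optimal path (co-optimal alignments may
legitimately differ in matches).

Biostrings' pairwise aligner was not used for this statistic: its
"overlap" mode is dovetail-only (it forbids containment — free gaps at both
ends of the *same* sequence), which conflicts with the coverage semantics
above; a short protein fully matching the interior of a longer one must
count as fully covered.

## Greedy family clustering

`cluster_proteins()` reproduces the greedy incremental (star) clustering
scheme of the CD-HIT family at the standard distant-homology setting:

* thresholds: `min_identity = 0.35`, `min_cov_long = min_cov_short = 0.70`;
* sequences are processed longest-first (ties by `seq_id`), so the founder
  of a family is always its longest member and serves as representative;
* each sequence joins the representative with the **highest identity**
  among those meeting all three thresholds (ties: longer representative,
  then smaller family id), otherwise it founds a new family;
* membership is evaluated against representatives only; no transitive
  merging.

Assign-to-best rather than assign-to-first-found is a deliberate
determinism choice: first-found semantics depend on index order internals,
best-identity semantics depend only on the data. Counts on real collections
therefore approximate, not replicate, tools with first-found fast modes.

**Candidate prefilter.** Before alignment, candidate representatives are
collected from an inverted index of length-`word_size` words (default 3).
Word sharing alone is *not* a sound filter near the 35% threshold — a
qualifying pair can share no 3-mer — so the prefilter adds a
residue-composition safety net: for every representative the index missed,
an upper bound on achievable matches, `sum_a min(count_a(query),
count_a(rep))`, is computed, and the representative is aligned whenever the
bound still allows `identity_short >= min_identity`. Because the bound
dominates any alignment's match count, the prefiltered path is provably
identical to exhaustive mode; the suite additionally verifies equality
against an independently-written brute-force oracle
(`brute_force_cluster_oracle()`, plain loops, no prefilter) on randomized
sets that straddle the threshold.

## Presence/absence matrix and clade queries

`build_matrix()` tabulates protein copies per (family, genome); presence is
`count >= 1` (no copy-number weighting — the downstream partitions are
presence/absence semantics). Clade-quantified statements are expressed as
query trees over atoms `present_in(clade, min_genomes)`,
`present_fraction(clade, f, strict)` and `absent_in(clade)` with AND / OR /
NOT; `evaluate_query()` uses exact set semantics, and `strict = TRUE`
implements "> 50%" rather than ">= 50%".

`standard_partitions()` evaluates the nine named family sets. The
operationalizations deserve explicit statement because the narrative
phrases they formalise are ambiguous:

| set | rule |
|---|---|
| `shared2` | present in >= 2 genomes |
| `core_aoa` | >= 1 genome of each of NC, NS, NT, NP |
| `aoa_specific` | core and absent from every outgroup genome |
| `conserved_core` | specific and present in > 50% of genomes of each order |
| `np_specific` | >= 2 genomes, all presences within NP |
| `np_all_subclades` | NP-specific and >= 1 genome of every NP subclade |
| `sediment_specific` | >= 1 genome in each of >= 2 sediment subclades, absent outside them |
| `deep_ocean_shared` | >= 1 genome in each of >= 2 deep subclades, absent from non-deep NP (presence outside NP unconstrained) |
| `sediment_ns_shared` | >= 1 sediment genome and >= 1 NS genome, absent everywhere else |

Open choices resolved here, all configurable: "shared" imposes no
multiplicity (>= 1 genome per side); the sediment rule requires >= 1 genome
per sediment clade across >= 2 clades; deep-ocean sharing constrains only
the NP side because the defining phrase excludes "all other NP subclades",
not non-NP lineages. Which subclades count as "deep ocean" is habitat
knowledge, not derivable from the matrix, so `deep_clades` must always be
supplied by the analyst. Nesting invariants (conserved ⊆ specific ⊆ core;
sediment-specific ⊆ NP-specific) are asserted on every call.

Families are ordered for display from most widespread to most uncommon:
number of orders with presence, then number of genomes, then family id —
the ordering used for presence/absence figures.

## Marker selection and supermatrix assembly

Markers are families present in >= `min_genomes` genomes (the analysis-scale
analog of the 70-of-85 widespreadness rule; the pipeline default keeps the
70/85 ratio) and multi-copy in at most `max_multicopy_fraction` (default
0.05) of their presence genomes. Strict single-copy filtering is available
by setting the fraction to 0; tolerance is the default because MAG
collections contain fragmented bins where occasional apparent duplication
is assembly noise.

Marker alignment is delegated: `build_supermatrix()` consumes pre-aligned
per-marker FASTA (external aligners, or synthetic families, which are
gap-free and equal-length by construction). Columns with gap fraction
strictly greater than `trim_gap_fraction` (default 0.5) are removed — a
simple gap-occupancy trim standing in for entropy-based trimmers, which is
why site counts of published supermatrices are context, not targets, for
this package. Genomes missing a marker are padded with gaps; paralogs are
resolved before assembly (`keep_longest`, ties to the smaller `seq_id`, or
`drop_genome`). Invariants asserted on every build: uniform row length,
width additivity, and partition coordinates that tile `[1, width]`.

## ANI from MinHash sketches

`estimate_ani()` uses bottom-`s` MinHash sketches (default `s = 5000`,
`k = 16`) over canonical k-mers (lexicographic minimum of k-mer and reverse
complement; k-mers containing ambiguous bases are skipped). Hashing is
SplitMix64 over the 2-bit k-mer encoding XORed with a seed-derived mixer,
so sketches are deterministic given `AniParams$seed` and identical across
platforms. The Jaccard index `J` is estimated from the bottom-`s` of the
merged sketch, and ANI is recovered by inverting the k-mer survival model:
under i.i.d. per-site substitution at rate `r`, a k-mer survives with
probability `w = (1-r)^k`, and `w = 2J/(1+J)`, hence

```
ANI% = 100 * (2J/(1+J))^(1/k)
```

This exact inversion is preferred over the familiar logarithmic
(Poisson-distance) form `1 + ln(2J/(1+J))/k`, which is its first-order
Taylor approximation and develops a visible downward bias at higher
divergence (≈ −0.5 ANI points at r = 0.10, where the exact form is
unbiased). Sketch noise at these parameters is ≈ 0.2 ANI points (s.d.) for
500 kb genomes. As with all sketch estimators, values below ~85% ANI are
coarse and should be treated as qualitative; published inter-clade ANI
ranges are therefore context rather than validation targets.

## Assembly statistics and quality tiers

`contig_stats()` computes contig count, total size, longest contig, N50
(length at which the descending cumulative sum first reaches half the
total; the qualifying contig's own length is returned) and GC% over
unambiguous bases (Ns excluded from numerator and denominator). N50 is
tested against a brute-force prefix enumeration on random length lists.

`classify_quality()` tiers MAGs as `very_high` (completeness > 90),
`high` (> 80), `medium` (>= 50), else `low`, with contamination <= 5.5
required for the two upper tiers. The 5.5 ceiling operationalises
"~5% contamination or below" so that bins reported at 5.3–5.4% tier as
high quality, matching how such tables are annotated in practice;
completeness bounds are strict (80.0 is medium). `summarize_mag_table()`
uses the sample (n−1) standard deviation.

## The synthetic-data generator

`generate_collection()` plants families over a clade hierarchy (default: 30
genomes — NC 4, NS 5, NT 4, NP 14 across seven two-genome subclades, plus 3
outgroup genomes). Family ancestors are i.i.d. uniform over the 20 amino
acids (composition does not drive any statistic here; identity thresholds
do), with lengths uniform on 80–200 residues. Per-genome copies are derived
by point substitutions at a rate chosen so that the **expected pairwise
identity between two copies** equals `within_family_identity`: mutating to
one of the 19 other residues at rate `d` gives pairwise identity
`(1-d)^2 + d^2/19`, which is solved for `d` in closed form. The default
target of 0.60 leaves a wide margin above the 0.35 clustering threshold
while remaining far from the cross-family ceiling.

In separable mode (default), ancestors are rejection-sampled so that no two
exceed `cross_family_max_identity` (default 0.20) as measured by the
package's own aligner, and the blueprint refuses configurations with a
within/cross margin under 0.15 — planted structure is then recoverable by
construction. Dropout (default 0.10, matching the 66–99% completeness range
typical of sediment MAG sets; set to 0 for exact-recovery experiments)
removes designated (family, genome) copies independently. Contaminant
families, when enabled, are placed in a single genome each to exercise the
quality-tier semantics. Realized completeness/contamination per genome are
recorded in the emitted metadata.

What passing the planted-truth tests shows: the clustering, matrix, query
and partition machinery is exact on collections whose family structure
satisfies the separability assumptions. What it does not show: behavior on
real proteomes with domain-level homology, indels, fragmented genes and
composition bias — there the thresholds themselves, not the machinery,
dominate the outcome, and counts should be treated as
convention-dependent. The substitution-only model (no indels, no
tree-structured evolution) is deliberate: it makes target identities
analytically controllable; an optional indel mode was considered out of
scope for the validation role the generator plays.

## Numerical and reproducibility choices

* All stochastic steps consume a single integer seed (blueprint seed, hash
  seed, pipeline seed); repeated runs are byte-identical, and the pipeline
  manifest records md5 checksums so end-to-end determinism is checkable.
* Alignment scores under integral scoring matrices are exact in doubles;
  traceback equality tests rely on this.
* Validation problem sizes: the standard planted collection (30 genomes,
  118 families, ~1,300 proteins), twenty randomized oracle-equivalence sets
  of 30–90 proteins spanning identities 0.30–0.90, fifty random matrices
  for partition invariants, and 500 kb genome pairs at substitution rates
  0.02/0.05/0.10 for ANI — sizes at which every assertion is exact or has
  negligible sampling slack, chosen as the package's own desk-scale
  validation conditions.
* Degenerate inputs have defined behavior: empty FASTA yields an empty
  record table; an empty family set yields a 0-row matrix; an empty aligned
  core yields identity and coverage 0; Jaccard 0 yields `NA` ANI; a marker
  trimmed to zero width contributes no partition.

## Known limitations

* Identity/coverage conventions (shorter-sequence denominator, span-based
  coverage, best-identity assignment) are one consistent reading of common
  tool behavior; other tools' counts will differ at the margins.
* The sketch ANI estimator degrades below ~85% ANI and is not a substitute
  for alignment-based ANI at large divergence.
* Gap-fraction trimming is not an entropy-based trimmer; supermatrix widths
  are not comparable to those produced by such tools.
* The generator's completeness/contamination fields are bookkeeping values
  derived from planted dropout/contaminants, not marker-based estimates.
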