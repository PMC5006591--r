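---
title: "Fold-specific substitution matrices: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-specific substitution matrices: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldsub)
```

## The model

`foldsub` estimates, for each protein topology (CATH T level), how freely
each pair of amino acids substitutes for one another when the fold is held
fixed. The data are superposed multiple structure alignments, one per
homology (H) level of the topology — structure alignment is only
well-posed among homologs, so the fold-level signal is assembled from
homology-level pieces.

The estimator (`fit_topology_matrix()`) has three stages.

1. **Counting** (`count_substitutions()`). For every unordered pair of
   structures and every alignment column where both have a residue, the
   C-alpha distance decides the event type: within the cutoff it is a
   substitution and increments the symmetric cell (a, b) of a 21×21 table
   (20 residues + gap); beyond the cutoff the residues are not actually
   superposed, so each residue is charged one (residue, gap) event
   instead. Columns where only one structure has a residue charge a
   single (residue, gap) event. The distance test is the physical basis
   of the matrix: sequence-adjacent but structurally displaced residues
   must not be counted as exchanges.

2. **Normalization** (`normalize_counts()`). Each count C(a, b) is
   divided by the number of times a was replaced by anything *other* than
   b — including conserved a–a events and a–gap events. This replacement
   ratio asks "of everything that happened to a, how much of it was b?",
   which removes the residue-abundance component that raw counts carry.
   The ratio is inherently asymmetric (the denominators of C(a,b) and
   C(b,a) differ), but the final scoring matrix must be symmetric because
   alignment scoring is; we symmetrize by the arithmetic mean
   (M + Mᵀ)/2, the minimal order-independent choice.

3. **Aggregation** (`aggregate_topology()`). Homology-level matrices are
   summed and the whole table is rescaled so the maximum of the 20×20
   block is exactly 1. Normalizing *before* summation keeps large
   families from dominating the topology signal purely by pair count;
   max-normalization puts every topology matrix on a common [0, 1] scale
   so a single weight range is meaningful across folds.

The fold-specific scoring matrix is the anchored blend
`Combined = Standard + x · Topology`, element-wise over the 20 standard
residues (B, Z, X, `*` pass through from the anchor). Since the topology
matrix is bounded by 1, the weight `x` is directly interpretable as "how
many Blosum score units the strongest fold-specific preference is worth";
the useful range is 1–30.

## Evaluation statistic

Discrimination is measured exactly as a remote-homolog benchmark: each
topology contributes one structurally similar but sequence-dissimilar
pair (S, S′) below 30 % identity. The query S is aligned (global
Needleman–Wunsch, affine gaps 10/1) against its own partner and against
every other topology's partner, and

z = (similar score − mean of cross scores) / sd of cross scores.

Choices the z-score definition leaves open, and what we adopted:

* **Cross population per query, not pooled.** Each topology's z uses its
  own cross scores (S against the other partners), matching the pairwise
  enumeration of the benchmark protocol. Pooling across queries would mix
  length effects into the spread.
* **The similar score is excluded from the mean/sd.** Including the
  value being tested in its own null population shrinks z systematically;
  exclusion makes z a clean outlier statistic. Both this and the
  population-sd variant are available via arguments to
  `compute_zscore()`.
* **Sample (n−1) standard deviation**, the default for small cross
  populations.
* **Percent improvement** of the best combined z over the best generic z
  uses |z_generic| in the denominator, so improvements from negative
  baselines are well-defined and positive. With a near-zero baseline the
  percentage is reported as-is (it can be huge or infinite); summary
  statistics over topologies use medians of the finite values.
* **"Improved"** means the combined matrix at its best weight strictly
  beats *every* supplied generic matrix, not just the anchor.

z is invariant under any common positive affine rescaling of the scoring
system (matrix and gap penalties together). This is why evaluation uses
the real-valued working matrices directly: the integer export profiles
(×100-and-round, or round-to-integer for Psi-blast input) exist purely for
interoperability and cannot change the benchmark outcome. A cap on the
scaled integer matrix (historically 20) is available but off by default;
with ×100 scaling a cap of 20 would clip most of the anchor, and since the
statistic is scale-invariant the cap has no evaluative role either way.

## Alignment conventions

The Gotoh three-state kernel charges a gap run of length k as
`open + k·extend` — the first gapped position pays both. Because tools
differ on whether the opening charge includes the first extension,
`convention = "open-inclusive"` provides `open + (k−1)·extend`; the two
differ only by a constant shift of `open`. Terminal gaps are penalized
(true global alignment); `free_ends = TRUE` gives the semi-global
variant. Ties are broken deterministically (diagonal, then gap in the
second sequence, then gap in the first), which fixes the reported
traceback; only the score feeds the benchmark. Scores are validated in
the test suite against exhaustive enumeration of all global alignments on
small instances, under both conventions, and against an independent
global aligner on protein-sized pairs.

## The synthetic data generator

Real CATH-scale input (hundreds of topologies, thousands of superposed
domains) cannot ship with a package, so every moving part is exercised on
synthetic families (`family_spec()`, `make_family()`, `make_study()`)
built to emulate exactly the statistical features the estimator consumes:

* **Planted substitution preferences.** Descendants of a sampled ancestor
  mutate each site with probability `background_sub_rate` (default 0.3);
  replacements are drawn uniformly over the 19 alternatives except that
  designated exchanges (e.g. E↔K) carry an enrichment factor (default
  5×). Each synthetic topology gets its own preferred exchange from a
  pool of chemically plausible pairs, giving fold-specific signal for the
  benchmark to find.
* **Superposition error, not structure.** All structures share an ideal
  α-helix C-alpha trace (rise 1.5 Å, 100° turn, 2.3 Å radius — textbook
  helix geometry) indexed by alignment column, plus independent Gaussian
  jitter (default σ = 0.5 Å). The counting logic only sees coordinates
  and a cutoff, so controllable superposition error is the feature that
  matters; β-sheet geometry would add nothing to what is tested.
* **Indels as deletions.** Each descendant site is deleted with
  probability `indel_rate` (default 0.05), creating alignment gaps.
  Insertions relative to the ancestor would add columns without touching
  any additional code path, so they are not modelled.
* **Held-out test pairs.** `make_pairset()` draws two fresh descendants
  per family at divergence 0.7 (per-site), yielding ~8–15 % identity —
  well inside the remote-homolog regime — from an RNG stream disjoint
  from the training families, so test sequences never appear in matrix
  training.
* **Determinism.** Every draw happens under a seed derived from the spec;
  the same spec yields byte-identical families, and generation restores
  the caller's RNG state.

What the generator does *not* emulate: real fold geometry, correlated
(epistatic) substitutions, position-specific conservation, realistic gap
placement, and database-scale topology counts. Passing tests therefore
demonstrate that the estimator recovers planted exchange preferences and
that fold-specific blending can sharpen discrimination *under the model's
own assumptions* — not that the published CATH-scale improvement figures
are reproduced, which would require the original structure sets.

## Study sizes and the aggregation-breadth calculation

The recovery study asks the fitted topology matrix to rank the planted
E–K exchange above all 189 other off-diagonal cells, in at least 19 of 20
seeded runs. One family of 4 structures (length 120, rate 0.3,
enrichment 5×) generates only ~3 E→K/K→E mutation events; each event
lands in up to 3 (mutant, keeper) structure pairs, so per-cell counts are
small, clustered multiples, and the maximum over 189 background cells —
further perturbed by ancestor-composition noise in the normalizing
denominators — regularly overtakes the planted cell. A rough
compound-Poisson estimate says ~30 planted events are needed for the
planted cell to clear the background maximum with ≥95 % probability; at
~3 events per family that means aggregating ~10 homology-level families
per topology. We therefore model a *well-populated* topology: 10 families
of 4 structures, which is also the regime the aggregation stage exists
for (populous CATH topologies have tens of homology levels). The
discrimination benchmark uses the same design — 10 topologies × 10
families — with weights 0–30 and the class-default cutoffs (3/3/4 Å).
These sizes keep the full suite and the acceptance script in the
seconds-to-minutes range.

At this desk scale the benchmark is intentionally qualitative: with only
9 cross pairs per query, individual z-scores are noisy, and the measured
fraction of improved topologies hovers around one half with a pooled
best-weight z-ratio a few percent above 1 — the direction of the
CATH-scale effect, not its magnitude.

## Numerical choices and degenerate inputs

* Zero normalization denominators yield 0 (no pseudocounts — smoothing is
  deliberately out of scope, as is log-odds conversion).
* An all-zero topology sum is returned as-is with a warning rather than
  rescaled (max-normalization would divide by zero).
* Zero spread in cross scores makes z undefined; it is reported as `NA`
  with a warning and propagated, never silently dropped.
* `X` residues (non-standard, e.g. MSE, or residues lacking a C-alpha)
  occupy alignment columns but contribute to no count cell; the 21-class
  table has no "unknown" class, and inventing counts for unknown residues
  would bias the gap statistics.
* Structures are never paired with themselves, and each unordered pair is
  counted once.
* Matrix files are written with 6 decimals (integers exactly); the
  round-trip contract is exact for integer matrices and 5·10⁻⁷ absolute
  for reals.

## Known limitations

* The counting loop is quadratic in the number of structures per family;
  for the intended family sizes (tens of structures) this is negligible.
* Architecture-level (C.A) aggregation is not offered: coarser pooling
  dilutes exactly the fold specificity the method exists to capture.
* The PDB reader handles single-chain C-alpha traces (first MODEL, first
  chain unless specified) — CATH domains are single-chain extracts, and
  mmCIF or insertion-code arithmetic are out of scope.
* Evaluation requires at least 3 topologies (each query needs ≥2 cross
  scores for a standard deviation).
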