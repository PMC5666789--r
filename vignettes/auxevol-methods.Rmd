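---
title: "Methods: models, parameter choices and assumptions in auxevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameter choices and assumptions in auxevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxevol)
```

`auxevol` implements the computational pipeline of a plant Aux/IAA gene-family
evolution study: motif-composition typing of family members, nuclear
localization signal (NLS) classification, tandem/segmental duplication calling,
Ka/Ks estimation for duplicate pairs, and neighbor-joining phylogenetics —
plus a codon-level simulator used to validate every step against known truth.
This vignette documents the models and the reasoning behind each default.

## 1. Ka/Ks estimation

### NG86 (`estimate_kaks_ng86`)

The Nei–Gojobori (1986) method is implemented exactly in its classical form:

* **Site counting.** Each codon position contributes fractionally to
  synonymous (S) and nonsynonymous (N) site counts according to the fraction
  of the three possible point mutations that are synonymous. Mutations that
  create a stop codon are excluded and the remaining fractions renormalized,
  so S + N equals exactly 3 × (number of codons). Sites for a pair are the
  average of the two sequences' counts.
* **Pathway enumeration.** For codon pairs differing at 2 or 3 positions, all
  orderings of the single changes are enumerated with equal weight. Orderings
  that pass through a stop codon are dropped and the weights renormalized; if
  *every* ordering is blocked, all orderings are used and steps after the
  blocking point are counted as nonsynonymous (a conservative fallback that
  keeps the count total conserved).
* **Distance correction.** Proportions p~S~ = S~d~/S and p~N~ = N~d~/N are
  corrected with Jukes–Cantor, d = −(3/4) ln(1 − (4/3)p). If p ≥ 3/4 the
  distance is saturated and `NA` is returned; likewise if a site class is
  empty (S = 0 can occur for very short sequences), the corresponding rate is
  `NA` rather than a silent 0.

A fully independent brute-force oracle (recursive pathway enumeration built
directly from `Biostrings::GENETIC_CODE`) backs the implementation in the test
suite: agreement to 1e−10 is asserted over all 61 × 61 sense-codon pairs and
over random 200-codon alignments. NG86 is the reference method here because it
has a closed, enumerable definition — every intermediate (S, N, S~d~, N~d~)
can be recomputed by exhaustive enumeration, which makes honest end-to-end
verification possible.

### MYN (`estimate_kaks_myn`)

The modified Yang–Nielsen approximation accounts for transition/transversion
bias and unequal codon usage effects that NG86 ignores:

* kappa is estimated from 4-fold degenerate (pure synonymous) and 0-fold
  (pure nonsynonymous) sites via the Kimura 2-parameter model;
* site counts are kappa-weighted, pathway weights are omega-weighted, and the
  per-class distances use K80 rather than JC corrections;
* the site/pathway/omega system is iterated to a 1e−8 fixed point.

MYN requires at least 10 aligned codons (the kappa estimate is meaningless
below that). In simulation, MYN recovers the generating omega with smaller
bias than NG86 when kappa ≠ 1, which is why both are reported in the
duplicate-pair analysis.

## 2. Protein alignment

Global protein alignment (`align_proteins_global`) is a standard step, not a
contribution of this package, so it delegates to
`Biostrings::pairwiseAlignment` with affine gap costs. Defaults are
**BLOSUM62** with gap open 10 and gap extension 0.1 — the packaged default
substitution matrix (tests pin it against an independent three-state dynamic
programming oracle). `project_to_codons` lifts a protein alignment to a
codon alignment for Ka/Ks, dropping gapped columns and validating frame,
stops and ambiguity codes.

## 3. Motif model and family classifier

Five family consensus motifs (Domains I–IV plus the repression-associated
motif) ship as degenerate consensus patterns and as position weight matrices
built from them. `call_presence` scans a protein with every model and calls a
motif present when the best window scores at least `threshold_fraction = 0.6`
of the model's maximum attainable score — permissive enough to tolerate the
one-to-two substitutions seen in degenerate family members, strict enough
that unrelated sequence does not score (verified on sterile scaffolds, see
§6). `classify_type` maps the 32 possible presence/absence subsets onto the
published Types I–X by exact set equality, with everything else labeled
`other`; the decision table is total (every subset gets exactly one label),
which the test suite asserts by enumerating all 32 subsets. Type IV is
interpreted as *either* of two published compositions ({I, II, repression} or
{II, IV, repression}); the publication's type definitions are not a partition
by construction, so exact set matching with an explicit `other` bucket is the
only faithful encoding.

`discover_motifs_zoops` is an EM fitter for the ZOOPS (zero-or-one occurrence
per sequence) model, used to re-derive motifs from unaligned sequence. EM on
ZOOPS has local optima that are shifted one or two columns from the planted
site; tests therefore assert site recovery up to a small offset rather than
exact coordinates.

## 4. NLS scanner

Three signals are scanned: bipartite Part 1 (`KR`, both positions basic),
bipartite Part 2 (`RxxRK`, positions 1/4/5 basic) and the SV40-like signal
(`KRxRxxK`, positions 1/2/4/7 basic). A match with every required position
basic is `intact`; a match at the right location with some required positions
non-basic is `degenerated`; no acceptable match is `lack`. Search windows are
anchored to the expected domain architecture when the motifs are present;
when they are not, the scanner falls back to thirds of the sequence
(N-terminal / middle / C-terminal), and ties between candidate windows are
broken by distance to the nearest window boundary, then leftmost. Species-
specific variants (`QxxRK`, `KxxNK`) are tagged separately by
`detect_species_variants` rather than being folded into the canonical calls.

## 5. Duplication finder

`find_tandem_pairs` calls a pair tandem when both genes lie on the same
chromosome, within 50 kb (inclusive), non-overlapping, and with global
protein identity above the threshold. Cross-chromosome pairs can never be
tandem by construction. `assign_segmental` marks pairs anchored in
collinearity blocks; a pair that is both collinearity-anchored and
tandem-eligible is labeled `both` (exact conjunction, not a precedence rule).

## 6. Simulator and scaffold planter

`simulate_family` generates a gene family with a known duplication history
(tandem and segmental events logged as truth) and evolves codon sequences
under a kappa/omega mutation–selection sampler. Defaults are **study
conditions**, chosen for realism rather than for any downstream check:

* `omega = 0.2`: purifying selection, the regime reported for the family's
  duplicate pairs;
* `kappa = 2`: the mild transition bias typical of plant nuclear genes;
* `gene_length_codons = 200`: the approximate length of the proteins studied;
* `branch_length = 0.05` expected substitutions per codon site per epoch:
  enough divergence to measure, far from saturation.

`plant_motifs_and_nls` builds protein scaffolds with chosen motif subsets and
NLS statuses. Linkers between planted elements are 12–40 residues drawn from
a **sterile alphabet** (`ACEFHINQSTY`) that contains no basic residues and
cannot spell any motif or NLS by accident, so planted truth is exact.
Internally contradictory plans (e.g. Part 1 anchoring requires the repression
and Domain-II motifs; an SV40 status other than `lack` requires Domain IV)
are rejected with an error rather than silently repaired.

## 7. Phylogeny

`p_distance_matrix` uses pairwise deletion of gapped columns.
`correct_distance` offers a gamma-distributed-rates correction with an
invariant-sites fraction; as the shape parameter alpha → ∞ it approaches the
Poisson correction −(1 − p~inv~) log(1 − d/(1 − p~inv~)), and it is undefined
for d ≥ 1 − p~inv~ (saturation) — near-saturated comparisons should use raw
p-distances instead. `nj_tree` is a direct implementation of
Saitou–Nei/Studier–Keppler neighbor joining; tests assert exact topology and
branch-length recovery on random additive trees (cophenetic distances
reproduced to machine precision). `bootstrap_support` resamples alignment
columns with a deterministic seed, and `extract_sister_pairs` reports
cherries above a support threshold — the candidates for recent duplication.

## 8. Published-table fixtures and open questions

The three published tables ship as plain-TSV fixtures. Two internal
inconsistencies in the source tables are preserved, not repaired:

* one printed Ka/Ks ratio (0.6163) disagrees with its own Ka and Ks
  (0.0429/0.0697 = 0.6155 at 4 decimals); the reproduction analysis reports
  9 of 10 rows consistent and flags this row;
* the per-species family counts sum to 435 while the stated total is 434;
  percentage claims (58.3 %, 52 %) use the published denominator 434.

## 9. Limitations

* NG86/MYN assume no indels within the codon alignment; gapped columns are
  projected out before estimation.
* MYN is an approximate counting method, not maximum likelihood; for
  publication-grade omega estimates on real data a codon ML model is the
  standard of reference.
* The simulator evolves sites independently (no rate variation across sites,
  no indels) and the scaffold planter produces architecturally idealized
  proteins; both are validation instruments, not generative models of real
  Aux/IAA evolution.
* ZOOPS EM is sensitive to initialization; multiple restarts are performed
  but recovery up to a one-to-two column shift is the honest guarantee.
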