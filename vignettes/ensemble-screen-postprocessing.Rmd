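---
title: "Methods: combining, scoring and benchmarking ensemble virtual screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining, scoring and benchmarking ensemble virtual screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evls)
```

## The problem and the model

A docking-based virtual screen assigns every molecule of a library an
empirical binding score against one receptor structure and ranks the library
by that score (lower = better). Receptor binding pockets are plastic: a
conformation extracted from one co-crystal can lodge chemically related
ligands extremely well while sterically rejecting binders that need a
different side-chain arrangement. Against an incompatible conformer a true
binder typically scores *worse than an average decoy*, because small decoys
can still pick up non-specific interactions. Pooled over many
single-receptor-conformation (SRC) runs, the distribution of binder relative
ranks is therefore bimodal: a peak at the very top (binder met a compatible
pocket) and a second peak in the tail (it did not).

Multiple-receptor-conformation (MRC) screening exploits this: dock the
library against each member of a crystallographic ensemble and let every
ligand keep its best outcome. `evls` implements the post-docking half of
that protocol. The two main combination rules are:

* **Best score** (`combine_mrc_score()`): key = the minimum score across
  runs, list sorted ascending. Exact score ties are broken by lower
  molecular weight — the smaller molecule achieving the same score is the
  better ligand-efficiency bet — then lexicographic ligand id for full
  determinism (the last tie-break is this package's choice; published
  protocols are silent beyond molecular weight).
* **Best rank** (`combine_mrc_rank()`): each run is ranked separately and a
  ligand's key is the best rank it achieved anywhere. With k runs, up to k
  molecules share best rank 1, so ties are resolved by score. We use the
  ligand's best score *across all runs*, not the score from the run where it
  achieved its best rank: the published description ("sorted according to
  their score") does not name which run's score, and the global best is
  consistent with best-score semantics. This interpretation is a documented
  design decision; both choices agree whenever the best rank and best score
  come from the same run, which is the common case.

Four alternative schemes are provided for completeness
(`combine_alternative()`): deep rank tie-breaks (second, then third best
rank), a Boltzmann soft-minimum of scores with temperature `T`
(`key = -T log Σ exp(-s_j/T)`, computed with the log-sum-exp shift for
stability; the T → 0 limit recovers best-score), the same key with an
additive molecular-weight penalty `λ·mw` (λ defaults to 0 and must be set
explicitly), and the sum of per-run ranks (consensus). The Boltzmann forms
are this package's own reconstruction of a scheme described only in words;
they are labeled non-canonical and none of the alternatives is expected to
beat the two main protocols.

## Figures of merit

All five metrics derive from the accumulation curve `F_a(k)`, the number of
binders at rank ≤ k, with `n` binders in `N` ligands:

| metric | definition | range |
|---|---|---|
| AUAC | `(1/nN) Σ_k F_a(k)` | `(n+1)/2N` … `1 − (n−1)/2N` |
| ROC AUC | P(random binder outranks random decoy), ties half credit | 0 … 1 |
| EF_χ | `F_a(⌊χN⌋) / (nχ)` | 0 … `min(n,⌊χN⌋)/(nχ)` |
| RIE | `Σ_i e^(−αr_i/N) / [(n/N)(1−e^(−α))/(e^(α/N)−1)]` | see below |
| BEDROC | `(RIE − RIE_min)/(RIE_max − RIE_min)` | 0 … 1 |

Numerical choices worth recording:

* **ROC AUC** is computed by the Mann–Whitney average-rank identity on the
  primary sort key, so score ties across the binder/decoy boundary receive
  half credit; the test suite cross-checks it against explicit pair
  enumeration and against the AUAC linear transform
  `(N·AUAC − (n+1)/2)/(N−n)`, which is exact for tie-free rankings.
* **EF** uses the floor (greatest-integer) form of the top-fraction size.
  Published per-target tables truncate (not round) EF values to one decimal
  — e.g. a ceiling of 46.15 printed as 46.1 — so `truncate_decimals()`
  reproduces that convention for comparisons; the metric functions
  themselves always return full precision.
* **BEDROC** is standardized *numerically*: `RIE_max` and `RIE_min` are the
  RIE formula evaluated at the ideal ordering (ranks `1..n`) and the worst
  ordering (ranks `N−n+1..N`). Closed-form approximations drift at the
  endpoints for finite `N`; the numeric standardization is exactly 0 and 1
  there for every `(n, N, α)`.
* **α = 20** is the conventional early-recognition weight (it concentrates
  ~80% of the weight in the top 8% of the list); `χ ∈ {1%, 10%}` are the
  default report fractions. Both are plain arguments.
* Metrics are undefined without at least one binder (error), ROC also needs
  one decoy. A random ranking has RIE expectation 1, and the suite verifies
  the normalization by Monte Carlo (10⁴ permutations at `N = 100, n = 10`).

## Benchmarking conventions

**Percentile placement.** An ensemble value is placed in the SRC
distribution as `floor(100·(c+1)/(k+1))`, where `c` is the number of runs it
*strictly* outperforms among `k`. Published worked numbers for a
six-conformer screen (85th percentile when beating 5 of 6; 100th when
beating all 6) pin this convention down; it is an inference, not a stated
formula, and other conventions (e.g. `100·c/k`) fail one of the two data
points. Ties never count as outperformed.

**Paired one-tailed t-test.** Protocol superiority across targets is
assessed by pairing each target's ensemble value with that target's *mean*
SRC value — the most literal reading of "the average individual docking
run" — and testing mean difference > 0. The computation delegates to
`stats::t.test(paired = TRUE, alternative = "greater")`; degenerate cases
(zero-variance differences) are resolved first: all-zero → p = 0.5,
constant nonzero → p ∈ {0, 1} by sign.

## Filters

* `drop_all_positive_runs()` removes every run whose minimum score is
  **strictly** greater than 0. A minimum of exactly 0 is kept: the filter
  should only discard runs with literally no favorable score, and published
  descriptions do not address the boundary. An ensemble left with no run is
  flagged `excluded`, not an error — real benchmarks contain targets whose
  entire ensemble is degenerate. An EF-based variant
  (`drop_low_ef_runs()`, default threshold EF₁% < 1) is exposed separately
  rather than assumed equivalent, because the score criterion needs no
  activity annotations while the EF criterion does.
* `cognate_ligand_filter()` **deletes** (does not relabel) binders
  co-crystallized with an in-ensemble conformer, and all binders sharing
  such a binder's chemotype, so the binder count `n` is recomputed on the
  filtered set. Deletion vs relabeling matters: the diversity analysis below
  relabels precisely because it wants `N` fixed. A `cocrystal_of` pointing
  at a conformer absent from the screen warns and removes nothing.

## Chemotype diversity

`chemotype_representative_relabel()` keeps, per chemotype, only the binder
with the best rank in the list being evaluated; other cluster members become
unchemotyped non-binders. `N` stays fixed and `n` drops to the number of
chemotypes, which suppresses the noise of over-represented scaffolds (a
single well-docked scaffold with twenty analogs would otherwise dominate
every early-recognition metric). The representative is recomputed **per
ranked list**: a fixed global representative would score the protocols on
different molecules than the ones they actually ranked well. Ties for best
representative cannot occur because ranks are unique after tie-breaking.
`top_fraction_chemotypes()` reports binder and scaffold counts in the top
`⌊χN⌋` positions with a dash-joined label (e.g. `"1-3-4-9"`).

## The synthetic generator

`generate_screen()` emulates the statistical structure of a retrospective
ensemble benchmark so the whole pipeline is testable without a docking
engine. Mechanism: every binder gets a chemotype; every conformer recognizes
each chemotype independently with probability `compat_fraction`; scores are
Gaussian with three means — compatible binders `mu_active = −35`,
incompatible binders `mu_incompatible = −12`, decoys `mu_decoy = −15`
(`sigma = 5`). The ordering `mu_active < mu_decoy ≤ mu_incompatible` is
enforced: it is what makes incompatible binders rank below an average decoy
and produces the bimodal pooled rank distribution
(`generate_bimodality_check()` tests the two-peak predicate directly).
Defaults, chosen once as desk-scale analogues of curated benchmarks:
10 binders to 430 decoys (≈ 1:43), 2–30 conformers per target, 4
chemotypes, `compat_fraction = 0.5`, molecular weights uniform on 150–550
Da, 25% of binders annotated as co-crystallized with a compatible conformer.
`sigma = 5` places the compatible-binder and decoy populations ~4 SD apart
so single runs are good but imperfect, which is the regime where combining
runs can help.

Degenerate "bad" runs occur with probability `frac_bad_runs = 0.1`: the run
recognizes no chemotype and all its scores are shifted by +30 — plus
whatever small extra shift is needed so its minimum is strictly positive,
guaranteeing the run is exactly what the all-positive filter removes.
Randomness is streamed per target (each target derives its own seed from
the master seed and target index), so target 1's data is byte-identical
whether you generate 1 target or 100.

What the generator does **not** emulate: heavy-tailed score distributions,
score–molecular-weight correlation, decoy induced fit (decoys share one
distribution across conformers), inter-target variation in library size,
and any 3D structure. Passing the synthetic suite therefore demonstrates
correctness of the post-processing arithmetic and the *direction* of the
ensemble effect under an idealized induced-fit mechanism — not docking
accuracy on real systems.

## Problem sizes and determinism

The test suite exercises: exhaustive enumeration of every binder placement
for `N ≤ 8` against naive loop-based oracles; 10⁴-permutation Monte-Carlo
normalization checks at `N = 100, n = 10`; the AUAC–ROC identity on 1,000
random tie-free rankings at 10⁻¹² tolerance; and the central superiority
property on 2,000 synthetic screens (100 seeds × 20 targets at the default
composition), requiring the best-rank protocol's BEDROC to reach at least
the mean SRC BEDROC in ≥ 95% of replicates and the all-positive filter not
to lower mean ensemble BEDROC. These sizes keep the full suite under a
minute or two on one core while leaving the Monte-Carlo standard errors
small (≈ 3 × 10⁻³ on RIE).

All orderings are total: score, then molecular weight, then ligand id. Two
identical inputs produce byte-identical ranked lists, and the pipeline
(`run_pipeline()`) writes byte-identical reports for the same config and
seed; provenance (config, seed, package version) is written alongside every
report set because filter decisions change the conclusions.

## Known limitations

* Chemotypes are consumed as annotations; no structure-based clustering,
  fingerprints or scaffold trees.
* No pose-level merging: combination operates on scores/ranks only.
* No confidence intervals on the figures of merit; percentile placement is
  a descriptive convention, not an inferential one.
* The Boltzmann combination forms are reconstructions (see above) and
  should not be cited as reference implementations.
* With very small libraries `⌊χN⌋` can be 0, in which case EF at that
  fraction is an error by design rather than silently using 1 position.
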