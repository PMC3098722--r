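# evls — post-processing and benchmarking of ensemble virtual ligand screens

Structure-based virtual ligand screening (VLS) docks a compound library
against a receptor structure and ranks the compounds by predicted binding
score, so that experimental testing can be limited to the top-ranked
fraction. A single rigid receptor conformation is a major source of error:
because of induced fit, a binder only docks well against a conformation whose
pocket can actually accommodate it, and against the wrong conformer it often
ranks *worse than an average decoy*. Multiple receptor conformation (MRC,
"ensemble") screening docks every ligand against each member of a
crystallographic conformer ensemble and merges the per-conformer results into
one ranked list.

`evls` is an R toolkit for everything downstream of the docking engine:

* **Combination protocols** — merge per-conformer score tables by best score
  (`combine_mrc_score()`), by best rank with score tie-breaks
  (`combine_mrc_rank()`), and by documented alternatives (deep rank
  tie-breaks, Boltzmann soft-minimum, rank consensus;
  `combine_alternative()`). Score ties are broken by lower molecular weight,
  then ligand id, so every ranking is deterministic.
* **Five early-recognition figures of merit** computed from the accumulation
  curve F<sub>a</sub>(k) (the count of binders at rank ≤ k):
  * AUAC = (1/nN) Σ<sub>k</sub> F<sub>a</sub>(k)
  * ROC AUC (Mann–Whitney form, half credit for score ties; equals the
    linear transform (N·AUAC − (n+1)/2)/(N − n) for tie-free rankings)
  * EF<sub>χ</sub> = F<sub>a</sub>(⌊χN⌋)/(nχ)
  * RIE = Σ<sub>i</sub> e<sup>−αr<sub>i</sub>/N</sup> / [(n/N)(1 − e<sup>−α</sup>)/(e<sup>α/N</sup> − 1)]
  * BEDROC = (RIE − RIE<sub>min</sub>)/(RIE<sub>max</sub> − RIE<sub>min</sub>), exactly 0/1 at the worst/ideal orderings
* **Benchmarking** — percentile placement of an ensemble result within the
  single-conformer (SRC) distribution, paired one-tailed t-tests, per-target
  report tables and histogram summaries (`benchmark_report()`).
* **Filters** — drop degenerate conformer runs that give every ligand a
  positive score (`drop_all_positive_runs()`), and exclude co-crystallized
  binders plus their chemotype analogs (`cognate_ligand_filter()`).
* **Chemotype diversity** — best-ranked-representative relabeling
  (`chemotype_representative_relabel()`) and top-fraction scaffold summaries
  (`top_fraction_chemotypes()`).
* **Synthetic screens** — a generator with explicit induced-fit structure
  (`generate_screen()`): chemotyped binders, conformers that recognize
  chemotype subsets, decoys, and occasional degenerate all-positive runs, so
  the whole pipeline is testable without a docking engine.

Score convention: **lower (more negative) score = better**, as produced by
empirical docking scoring functions; `read_score_table(..., invert_scores =
TRUE)` adapts higher-is-better engines.

## Worked example

Simulate one target with 4 conformers and a 10:430 binder:decoy library
(the ~1:43 ratio of curated decoy benchmarks), combine by best rank, and
score the result:

```r
library(evls)
sim    <- generate_screen(synthetic_config(n_targets = 1,
                                           conformers_range = c(4, 4),
                                           seed = 42))
screen <- sim$screens$T001
ranked <- combine_mrc_rank(screen)
metric_report(ranked, screen$library)
#> <metric_report> target T001, method mrc_rank (n = 10, N = 440)
#>   AUAC 0.9570 | ROC AUC 0.9657 | RIE 14.594 | BEDROC 0.9080 (alpha = 20)
#>   EF: 1% = 40.00, 10% = 9.00
```

EF<sub>1%</sub> = 40 is this library's ceiling (all 4 of the top-1%
positions are binders); BEDROC 0.91 close to 1 means binders are piled at
the very top of the merged list. Benchmarking against the four individual
runs:

```r
bench <- benchmark_report(sim$screens, methods = c("mrc_score", "mrc_rank"),
                          metrics = c("auac", "ef", "bedroc"),
                          chi_values = 0.01)
bench[, c("metric", "method", "src_min", "src_max", "src_mean",
          "value", "percentile", "ideal")]
#>   metric    method src_min src_max src_mean  value percentile ideal
#> 1   auac mrc_score   0.677   0.810    0.731  0.962        100  0.99
#> 2   auac  mrc_rank   0.677   0.810    0.731  0.957        100  0.99
#> 3  ef_1% mrc_score  20.000  40.000   35.000 40.000         40 40.00
#> 4  ef_1%  mrc_rank  20.000  40.000   35.000 40.000         40 40.00
#> 5 bedroc mrc_score   0.244   0.761    0.549  0.919        100  1.00
#> 6 bedroc  mrc_rank   0.244   0.761    0.549  0.908        100  1.00
```

Both ensemble protocols land in the 100th percentile of the SRC
distribution for AUAC and BEDROC (they outperform every single run); for
EF<sub>1%</sub> they match the best run's ceiling, which under the
strict-outperformance percentile convention reads as the 40th percentile.
The top-1% chemotype summary shows the diversity gain:

```r
top_fraction_chemotypes(ranked, screen$library, chi = 0.01)
#> top 1% (4 positions): 4 binders, 3 chemotypes (1-2-3)
```

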