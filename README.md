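# clonofate

Clonal fate analysis of semi-invariant T cell repertoires from paired
single-cell TCR sequencing.

## The problem

Murine thymic MAIT cells (and their iNKT counterparts) split into a
T-bet⁺ type-1 and a RORγt⁺ type-17 effector sublineage while still in
the thymus. Two questions about that commitment can be answered from
paired scTCR-seq alone, because every cell carries its recombined TCR as
a lineage barcode:

* **Is the fate instructed by the TCR?** Cells grouped by *amino-acid*
  receptor identity (**clonotypes**) that arose from independent
  precursors — distinct clones within a clonotype, or the same clonotype
  in different animals/datasets — are biological replicates of one
  receptor protein. If the TCR decided the fate, these replicates should
  agree.
* **Does commitment precede or follow proliferation?** Cells grouped by
  *nucleotide* receptor identity within one animal (**clones**) descend
  from a single precursor. Clones containing both fates prove
  proliferation *before* commitment; observing fewer mixed clonotypes
  than a label-shuffle null predicts proves proliferation *after*
  commitment.

clonofate is for immunologists and computational biologists who want to
run this inference on their own 10x / AIRR paired-chain data, or to
study its statistical behavior on ground-truthed synthetic data.

## What is inside

* **IO + QC** — `read_contigs()` (10x `filtered_contig_annotations.csv`
  or AIRR Rearrangement TSV), `read_cell_meta()`, `filter_cells()` (one
  designated αβ pair per cell: 2×TRB cells dropped as doublets, 0×TRA
  dropped, dual-α cells kept only when exactly one chain uses the
  lineage-defining V segment, e.g. TRAV1).
* **Clonal structure** — `assign_clones()`, `assign_clonotypes()`,
  `annotate_subset()`, `clonal_summary()`, `shared_clonotypes()`.
* **Fate inference** — three permutation null models with a common
  statistic, the number of groups containing both fates, always tested
  on the low tail (instruction/early commitment predict *fewer* mixed
  groups): `mixed_multiclone_test()` (clone labels shuffled within
  multi-clone clonotypes), `cross_dataset_test()` (shared-clonotype
  concordance against a binomial-resampling null), and
  `post_proliferation_test()` (the full cell-label column shuffled).
  Empirical p is `(r+1)/(n_iter+1)`; `enumerate_null()` provides the
  exact pmf by dynamic programming as an independent oracle, and
  `count_mixed_clones()` needs no null at all.
* **Sequence features** — Hamming-1 CDR3β similarity graph
  (`build_similarity_graph()`), cluster position-frequency matrices and
  consensus (`cluster_profile()`), center-aligned physicochemical
  profiles (`physchem_profile()`), length/gene-usage summaries,
  positional enrichment maps from classifier weights.
* **Selection classifier** — one-hot positional (forward + reverse)
  logistic model with `l1 = l2 = 1e-4`, balanced 300-per-class training
  on unique sequences, rank-statistic AUC, leakage-checked evaluation,
  stratified k-fold CV (`train_classifier()`, `evaluate_classifier()`,
  `crossvalidate()`).
* **Toy V(D)J model with exact Pgen** — `recomb_model()`,
  `sample_tcr()`, `pgen_aa()` (exact amino-acid generation probability
  by summation over event paths and codon realizations),
  `compare_pgen_groups()`, and `pgen_provider()` to plug in externally
  computed Pgen tables for real data.
* **Ground-truthed simulator** — `simulate_development()` /
  `make_paired_datasets()`: semi-invariant α, variable β, two
  proliferation rounds flanking a commitment event, four scenarios
  (`stochastic`, `instructed`, `pre_commitment`, `post_proliferation`),
  multi-animal replication, full truth tables.
* **Workflow** — `run_pipeline()` drives everything from one config
  (R list or YAML) and writes a seeded, hash-stamped report bundle;
  `inst/scripts/clonofate.R` is a thin shell wrapper.

## Worked example

Simulate a stochastic-commitment thymus, run the clonal inference:

```r
library(clonofate)

cfg  <- simulation_config(scenario = "stochastic", seed = 42,
                          compute_pgen = FALSE)
sim  <- simulate_development(cfg)
cells      <- sim_cells(sim)            # QC-passed cell table
clones     <- assign_clones(cells)
clonotypes <- assign_clonotypes(clones)

nrow(cells); nrow(clones); nrow(clonotypes)
#> [1] 2130
#> [1] 1199
#> [1] 1007

count_mixed_clones(clones)
#> [1] 132

mixed_multiclone_test(clonotypes, n_iter = 1000, seed = 1)
#> Permutation null model: mixed_multiclone_clonotypes
#>   observed: 43
#>   null median: 48 (95% CI 40-55)
#>   empirical p (low tail): 0.1538  [n_iter = 1000, seed = 1]

post_proliferation_test(cells, n_iter = 1000, seed = 2)
#> Permutation null model: mixed_clonotypes_cell_shuffle
#>   observed: 167
#>   null median: 243 (95% CI 223-260)
#>   empirical p (low tail): 0.000999  [n_iter = 1000, seed = 2]
```

Read the three results together, exactly as one would on real data: 132
clones contain both fates, so precursors proliferate **before**
committing; the observed 43 mixed multi-clone clonotypes sit well inside
the clone-shuffle null (p = 0.15), so commitment looks **stochastic, not
TCR-instructed**; and 167 mixed clonotypes is far below the 243 expected
if cells committed independently after all divisions (p = 0.001), so
cells also proliferate **after** committing. That is the correct
read-out for this generative scenario — commitment is between two
proliferation rounds and ignores the receptor.

Cross-dataset concordance runs from any annotated shared-clonotype
table; the package ships a 19-clonotype example
(`inst/extdata/shared_clonotypes_example.tsv`):

```r
shared <- read.delim(system.file("extdata",
                                 "shared_clonotypes_example.tsv",
                                 package = "clonofate"))
cross_dataset_concordance(shared)
#> Shared clonotypes: 19 | concordant: 6 | discordant: 13
#>          dataset_b
#> dataset_a TYPE1 TYPE17
#>    TYPE1      1      8
#>    TYPE17     5      5
```

Thirteen of nineteen shared receptors change sublineage between
datasets — replicate receptors do not replicate fates. And the exact
enumeration oracle for the smallest interesting shuffle:

```r
enumerate_null(c(2, 2), c("TYPE1", "TYPE1", "TYPE17", "TYPE17"))
#>   value      prob
#> 1     0 0.3333333
#> 2     1 0.0000000
#> 3     2 0.6666667
```

See `vignettes/clonal-fate-analysis.Rmd` for the models, parameter
choices and limitations.

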