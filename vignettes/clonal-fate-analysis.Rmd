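---
title: "Clonal fate analysis of semi-invariant T cell repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal fate analysis of semi-invariant T cell repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonofate)
```

## The question

Innate-like T cells such as MAIT and iNKT cells complete their effector
differentiation inside the thymus, splitting into a T-bet-driven type-1
and a RORgt-driven type-17 sublineage. Because each cell carries a
recombined TCR whose nucleotide sequence is essentially a lineage
barcode, paired single-cell TCR sequencing lets one ask two questions
that pure transcriptomics cannot:

1. **Is sublineage commitment instructed by the TCR?** If the receptor's
   amino-acid sequence (hence ligand affinity) decided the fate, then
   independent precursors that happen to carry the *same* amino-acid
   receptor should commit to the *same* fate.
2. **When does commitment happen relative to proliferation?** If
   precursors committed before any division, no clone could contain both
   fates; if commitment happened only after all divisions, cells would
   commit independently of their clonal origin.

clonofate implements the full inferential machinery around these two
questions, plus the sequence-level analyses (similarity graphs,
positional profiles, a selection classifier, generation probabilities)
that characterize what the type-1 and type-17 repertoires look like.

## Units of analysis: clones and clonotypes

A **clone** is the set of cells from one animal sharing the identical
*nucleotide* sequence of both TCR alpha and beta chains (same V and J
genes, same CDR3 nucleotides). Nucleotide-level generation probabilities
of observed receptors are so small (on the order of 1e-43 to 1e-12 under
inferred recombination models) that nucleotide identity within one
animal is a reliable proxy for descent from a single precursor.

A **clonotype** is the set of cells sharing the identical *amino-acid*
sequence of both chains. Distinct clones inside one clonotype — or the
same clonotype observed in different animals or datasets — are
*biological replicates of the same receptor protein*, produced by
convergent recombination. By default the clonotype key includes the V/J
gene names alongside the CDR3 amino acids (full-chain amino-acid
identity); `assign_clonotypes(cdr3_only = TRUE)` relaxes this.

Groups are annotated from their member cells' subset labels: TYPE1 if
they contain at least one type-1 cell and no type-17 cell, TYPE17
symmetrically, TYPE1_TYPE17 ("mixed") if both, and OTHER if only
immature/intermediate/cycling cells. Mixed clones are direct evidence of
proliferation before commitment; the *rate* of mixed clonotypes carries
the signal about TCR instruction.

## The three permutation null models

All three tests share one statistic family — the number of groups
containing both fates — and one logic: hold the grouping structure
fixed, randomize the labels, and ask whether the observed count is lower
than the null predicts (instruction and early commitment both push the
mixed count *down*, so the low tail is the alternative of interest).

* `mixed_multiclone_test()` pools the labels of pure TYPE1/TYPE17 clones
  inside clonotypes that contain at least two such clones and permutes
  them across clone slots. Only pure clones enter the pool; clones
  annotated mixed or OTHER are set aside rather than disqualifying their
  clonotype.
* `cross_dataset_test()` compares the subset annotation of clonotypes
  shared between two independent datasets. The default mechanism
  (`resample_binomial`) redraws each side's label with that dataset's
  observed type-17 frequency. A fixed-margin relative permutation is
  also provided (`permute_within_datasets`), but note its discordance
  count moves in steps of two (for margins a/b it is `a + b − 2C`, with
  `C` the concordant TYPE1 overlap), so its support has a fixed parity —
  one reason the resampling mechanism is the default.
* `post_proliferation_test()` permutes the full cell-label column —
  preserving the number of cells, the subset ratio, and the clonotype
  size distribution exactly — and recounts mixed clonotypes. Stage
  labels (immature/intermediate/cycling) are shuffled as-is, exactly as
  they sit in the column.

Conventions, fixed once: the empirical p-value is `(r + 1)/(n_iter + 1)`
with `r` the number of null samples at or below the observed value; the
"95% CI" of a null sample is its 2.5th–97.5th percentile (type-7 linear
interpolation); `n_iter` defaults to 1000; every result records its
seed, and identical seed plus inputs gives identical output.

**The enumeration oracle.** `enumerate_null()` computes the *exact*
probability mass function of the mixed-group count under uniform label
placement, by dynamic programming over groups with multivariate
hypergeometric allocation weights. It exists so the Monte-Carlo engines
can be validated against an independent exact computation (the test
suite checks total-variation agreement below 0.02 at 10,000 shuffles,
and checks the DP itself against exhaustive permutation on tiny
structures). It errors, advising Monte Carlo, when the number of
distinct placements exceeds its limit.

## Sequence-feature analyses

* `build_similarity_graph()` connects clonotypes whose CDR3b sequences
  differ by exactly one substitution (equal length, Hamming distance 1);
  indels are excluded because unequal-length sequences have no aligned
  positions for the downstream positional analyses. Edges are found by
  single-position wildcard hashing and verified in tests against an
  all-pairs scan.
* `cluster_profile()` turns one connected component into a position
  frequency matrix with an argmax consensus, ties broken alphabetically.
* `physchem_profile()` averages a per-residue scale at each position
  relative to the CDR3 center; position `p` (0-based) of a length-`L`
  sequence maps to offset `p − floor(L/2)` (center-right convention for
  even lengths). Offsets supported by fewer than `min_support = 5`
  sequences are suppressed. Bundled scales: Kyte–Doolittle hydropathy,
  gas-phase basicity (a true basicity scale, in kcal/mol), and
  Chou–Fasman helix propensity; any named 20-vector can be substituted.
* `repertoire_summaries()` reports CDR3b length histograms with the
  short-sequence fraction over the inclusive 10–14 window, CDR3a
  frequency tables, and V gene usage.

## The selection classifier

`train_classifier()` is a linear logistic model over a one-hot
positional encoding of CDR3b: each sequence activates one feature per
(direction, position, residue) reading both from the N terminus
(positions 0, 1, …) and from the C terminus (positions −1, −2, …), up to
depth 25 per direction. The penalty is `l1·||w||1 + l2·||w||2^2` with
both strengths defaulting to 1e-4; the fit is performed by glmnet's
elastic net with `lambda = l1 + 2·l2` and `alpha = l1/lambda`,
unstandardized, which reproduces exactly that penalty up to glmnet's
1/n likelihood scaling. Training deduplicates to unique sequences
(classifying clonotypes, not cells), balances classes by subsampling 300
per class, and is deterministic given the seed. Evaluation refuses any
train/test sequence overlap; the AUC is the Mann–Whitney rank statistic
with ties counted half, cross-checked against the threshold-sweep
trapezoid. `crossvalidate()` does stratified k-fold (default 5).
`positional_enrichment()` reshapes a trained model's weights onto
forward/reverse positional grids; trained against a
recombination-generated background, positive weights mark selected
residues. Alpha-chain features are deliberately excluded — the
near-invariant alpha would make any subset-vs-control discrimination
trivial.

## The toy recombination model and exact Pgen

`recomb_model()` draws a V remnant (germline string minus 3' deletions),
an insertion run, and a J remnant (minus 5' deletions), each from
explicit bounded distributions, so the whole event space is enumerable.
`pgen_aa()` computes the amino-acid generation probability exactly: it
sums, over every event skeleton of compatible length, the product over
codons of the probability that the (partly germline-fixed, partly
free-insertion) codon encodes the target residue.

Conditioning is a real choice here. By default `pgen_aa()` conditions on
*in-frame* output only, under which the hand-enumerable examples are
exact (for a model emitting `CAF` with no insertions half the time and
three uniform insertions otherwise, `pgen("CAF") = 1/2` and
`pgen("CAGF") = 1/2 · 4/64`, four of the 64 codons encoding glycine),
and probabilities sum to one over all achievable translations including
stop-containing ones. `conditioning = "productive"` additionally
renormalizes over stop-free output, under which the 20-letter space sums
to one (`pgen("CAF")` becomes 64/125 in that example). Both are tested.

Paired-clonotype Pgen is the product of the chain Pgens (independent
rearrangement of the two loci). `pgen_provider()` gives the same lookup
interface for the toy model and for externally computed tables, so real
datasets can use Pgens from a full inferred model. Group comparisons use
the two-sided Wilcoxon rank-sum on log10 Pgen, optionally stratified by
clone count to separate convergence effects from residual sequence
effects.

## The developmental simulator

`simulate_development()` generates ground-truthed datasets under a
four-stage model: recombination of a semi-invariant alpha (one V/J pair
whose germline join is the canonical CAVRDSNYQLIW, rare 3-nt
deletions/insertions, so the germline junction dominates at roughly
three quarters of productive chains) and a variable beta (three V, two
J, up to six deletions per side, up to nine insertions); a first
proliferation round; a commitment event; a second, fate-biased
proliferation round; and Bernoulli sampling of the final cells. The four
scenarios move the commitment event: `stochastic` (i.i.d. with
`p_type17 = 0.5` after round 1), `instructed` (commitment probability a
logistic function of CDR3b mean Kyte–Doolittle hydropathy — an arbitrary
but documented stand-in for affinity, slope 20 centered at −0.2, which
splits the beta repertoire into strongly committed halves),
`pre_commitment` (fate fixed at the precursor), and `post_proliferation`
(fate drawn i.i.d. per final cell).

Defaults, chosen once as this package's study conditions: 800 precursors
per animal, three animals, geometric offspring with round-1 mean 2 and
round-2 means 2 (TYPE1) versus 4 (TYPE17) (type-17 cells expand more),
truncated at 12; sampling fraction 0.15, giving datasets of roughly one
to two thousand cells; 20% of sampled cells relabeled
immature/intermediate/cycling to mimic stage admixture. These sizes make
convergent amino-acid recombination common enough that a typical
stochastic replicate carries at least ~50 multi-clone clonotypes — the
regime in which the calibration and power properties of the multi-clone
test are asserted.

One deliberate departure from a literal event-space simulation:
`resample_synonymous_nt` (default on) re-draws each junction's
nucleotide realization uniformly among synonymous codons after the event
draw. A bounded enumerable toy event space cannot reproduce the
astronomically small *nucleotide* Pgens of real junctions; without the
re-draw, independent precursors frequently collide at the nucleotide
level, which would merge distinct lineages into one "clone" and destroy
the defining property of the clone as a lineage barcode. The re-draw
leaves the amino-acid generative law — everything `pgen_aa()` describes
— untouched. Consequently, nucleotide sequences should be treated as
lineage barcodes, not as draws from the event model.

What the simulator does **not** emulate: transcriptome noise in the
subset labels (labels are true fates with a clean stage admixture),
dropout of chains (every simulated cell yields exactly one alpha and one
beta), dual-alpha cells, doublets, ligand or structural affinity (the
instructive score is a hydropathy proxy), and microbiota- or
niche-driven modulation of expansion. Passing tests on synthetic data
therefore validate the inferential machinery, not the upstream label
quality of any real dataset.

## Numerical and degenerate-input choices

* Empirical p never returns 0 by construction; a label pool with a
  single label class is flagged `degenerate` and returns p = 1.
* `post_proliferation_test()` warns when no clonotype has two or more
  cells (the null is then a point mass).
* Consensus ties break alphabetically; clone/clonotype ids are assigned
  in deterministic key order; summaries are input-order invariant.
* glmnet is run unstandardized with a single fixed lambda;
  serialization uses 17 significant digits so models and scores
  round-trip bit-exactly.
* Barcode matching is exact string equality; an option strips the 10x
  `-1` suffix. Contigs identical up to UMI count collapse to the
  highest-UMI record before chain counting. V/J allele suffixes (`*01`)
  are stripped: the analysis reasons at gene level.
* The dual-alpha rule keeps a cell with two alpha chains only when
  exactly one uses the lineage-defining V segment (TRAV1 for MAIT,
  TRAV11 for iNKT); that chain defines specificity and the cell is
  flagged `dual_alpha`.

## Problem sizes in the test suite

The suite exercises the calibration property on 200 simulated stochastic
replicates at the default dataset size (testing uniformity of the
multi-clone test's p-values by Kolmogorov–Smirnov at alpha = 0.01,
with 400 shuffles per replicate), the forced zero-mixed-clone property
on 200 pre-commitment replicates, and power on 100 instructed
replicates (rejection at p <= 0.05 in at least 80%). Oracle-equivalence
checks run 10,000 shuffles per structure. These sizes are the package's
chosen trade-off between statistical resolution and a test suite that
runs in minutes.

## Known limitations

* The cross-dataset null mechanism underlying published "expected
  range" statements is not uniquely identifiable from a printed 2x2
  table; both implemented mechanisms are exposed and the parity argument
  above documents why the resampling variant is the default.
* Real-data generation probabilities require an externally inferred
  recombination model; the toy model is exact but not mouse-realistic,
  and enters real-data workflows only through `pgen_provider()`'s
  external-table source.
* The classifier reproduces the *behavior* (AUC regime) of the
  reference selection-model encoder; weight values depend on the
  optimizer and are not comparable across implementations.
* Clones cannot span animals by definition, so barcode collisions
  between animals (hashtag misassignment) would surface as convergent
  clonotypes, not as merged clones.
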