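---
title: "Building partitioned phylogenomic supermatrices with supermat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building partitioned phylogenomic supermatrices with supermat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcriptome-based phylogenomics produces thousands of per-orthogroup
amino-acid alignments over a shared but incompletely sampled taxon set: each
orthogroup (a set of sequences, at most one per taxon, descending from one
ancestral gene) is missing the taxa whose transcriptomes did not capture it,
contains columns of doubtful alignment, and evolves at its own rate.  Before
tree inference these loci are filtered and concatenated into a *supermatrix*
— one character matrix with absent taxa filled by missing symbols and a
partition scheme mapping columns back to loci.  `supermat` implements that
construction as a reusable, deterministic pipeline:

1. **Site masking** (`mask_sites`): per-column confidence scores in the
   ZORRO 0–10 convention; columns scoring below a threshold (default 5) are
   discarded.
2. **Occupancy selection** (`select_by_occupancy`,
   `min_taxa_for_fraction`): keep orthogroups present in at least *k* taxa,
   where *k* realises a target gene-occupancy fraction (e.g. 50%).
3. **Rate-tail trimming** (`trim_rate_tails`): rank loci from slowest- to
   fastest-evolving using mean percent pairwise identity as the rate proxy,
   then discard a fraction at each extreme (default 20% + 20%).
4. **Dayhoff recoding** (`recode_alignment`): collapse the 20 amino acids
   into six exchange-prone classes (`0`=AGPST, `1`=FWY, `2`=C, `3`=HKR,
   `4`=ILMV, `5`=EDNQ) to reduce compositional heterogeneity and
   saturation; output states are digits so multistate inference programs
   can consume the matrices directly.
5. **Concatenation** (`concatenate`): join the survivors, fill absent taxa
   with `?`, and emit FASTA, relaxed PHYLIP, RAxML/NEXUS partition files
   and an occupancy report.

## The rate proxy

For a locus with informative rows \(x_1,\dots,x_m\), pairwise identity of a
row pair is

\[
\mathrm{PID}(x_i, x_j) \;=\;
\frac{\#\{\,c : x_{ic} = x_{jc},\ \text{both canonical}\,\}}
     {\#\{\,c : \text{both canonical}\,\}},
\]

and the locus conservation score is the mean of PID over all unordered
pairs (`locus_conservation`; the raw accumulated sum over pairs is
available with `statistic = "sum"`).  High conservation means a
slow-evolving locus; \(1-\text{conservation}\) orders loci by rate.  Two
gap policies are offered: the default `exclude_pairs_with_gap` drops
positions where either row is a gap/missing/ambiguity symbol from the
denominator, because gap-rich loci would otherwise conflate missingness
with divergence; `count_as_mismatch` uses the full alignment length.  A
locus with fewer than two informative rows has no defined score and is
excluded from ranking (with a warning).

Trimming removes `floor(q_low * N)` loci from the conserved (low-rate) end
and `floor(q_high * N)` from the fast end, `N` counting rankable loci; ties
in conservation are broken by orthogroup id so results are deterministic.

## Occupancy arithmetic

Published matrices state occupancy targets as fractions but implement them
as counts, and printed fraction/count pairs do not always follow one
rounding rule (50% of 108 taxa appearing as 55, 70% as 77).
`min_taxa_for_fraction` therefore makes the policy explicit: `ceil`
(default), `floor_plus_one`, or `explicit`, which passes a published count
through unchanged and logs its implied fraction.  For replicating a
published matrix we recommend `explicit`.  In taxon-subset (clade-enriched)
runs, `run_pipeline` resolves fractions against the subset size, not the
full universe.

## Missing data

Absent taxa are filled with `?`, never `-`, so no-data cells stay
distinguishable from alignment gaps.  Both are "missing" for statistics:
`missingness` reports `100 * #({'?', '-'}) / (ntax * L)`, and the occupancy
report also carries the absent-fill-only percentage, since published
missing-data figures rarely say which convention they use.

## What the simulator emulates

`simulate_dataset` generates orthogroup sets with the three features the
pipeline exists to handle, each with ground truth:

* **Occupancy heterogeneity** — each taxon has a capture probability
  \(c_i \sim \mathrm{Beta}(6, 2)\) (mean 0.75) shared across loci; a
  taxon's row is dropped from a locus with probability \(1 - c_i\).
  Dropout is whole-row, matching orthogroup semantics.
* **Rate heterogeneity** — each locus has a multiplier
  \(r_g \sim \mathrm{Lognormal}(0, 0.5)\).  Sequences evolve along one
  shared random tree (`ape::rtree` topology, exponential branch lengths of
  mean 0.05 substitutions/site, giving mean pairwise tip depths around 0.5
  on 20 taxa) under a 20-state equal-exchangeability Markov model in which
  the expected substitutions on a branch of length \(t\) are \(r_g t\).
  That model was chosen over an empirical exchangeability matrix because it
  has the closed-form transition probability
  \(p_\text{same} = \tfrac1{20} + \tfrac{19}{20}
  e^{-\frac{20}{19} r t}\), which makes the simulator itself checkable
  against hand arithmetic.
* **Unreliable columns** — a fraction (default 10%) of columns per locus is
  overwritten with i.i.d. uniform residues and scored from U[0, 3];
  clean columns score U[6, 10].  The distributions straddle the
  conventional threshold 5 with a gap, so masking has an exact ground
  truth.

Default sizes (20 taxa, 100 loci of 100–350 columns) keep a full simulated
study in the order of seconds while leaving enough loci for rank statistics
to be stable; the package's own validation uses these defaults, with
500-locus runs for occupancy-recovery checks.  All draws flow from a single
seed, and identical parameters give byte-identical datasets.

What the simulator deliberately does **not** emulate: indels (gaps enter
real alignments through the aligner; simulated alignments are gap-free
until masking empties rows), compositional heterogeneity across lineages
(the phenomenon Dayhoff recoding is meant to dampen — recoding is therefore
validated by its algebraic properties, not by tree inference), alignment
error beyond the injected uniform-noise columns, and paralogy.  Passing the
recovery tests shows the pipeline computes its statistics correctly under
the generating model, not that those statistics denoise real data.

## Numerical and design choices

* **Stage order is fixed**: mask → occupancy → rate-trim → recode →
  concatenate.  Masking precedes occupancy selection because culling
  columns can empty a taxon's row and so lower occupancy.
* **Taxon and locus order** are lexicographic by default (a user-supplied
  taxon order is honoured), so every output file is reproducible
  independent of filesystem order.
* **Ambiguity letters** (B, Z, J, X, U, O), `?` and `*` recode to `?`, even
  when every expansion of the ambiguity falls in one Dayhoff class (B = D/N
  would both be class 5): collapsing silently would hide the ambiguity.
  Gaps pass through recoding unchanged.
* **Score tracks** must match their alignment's column count exactly;
  mismatches are hard errors, never truncated, because silently misaligned
  scores corrupt masking.
* **Undefined identities** (no comparable columns between two rows) are
  excluded from the conservation mean; a locus with no defined pair at all
  is an error and is excluded from ranking by `rate_table`.

## Limitations

The rate proxy is identity-based and so saturates for very fast loci;
ranking near the fast tail of deeply divergent datasets is less reliable
than in the middle of the distribution.  Occupancy thresholds treat all
taxa equally — there is no per-clade occupancy constraint.  The pipeline
stops at matrix construction: model selection, tree inference and support
estimation belong to the downstream tools the partition files are written
for.

## A worked run

```{r, eval = FALSE}
library(supermat)

cfg <- list(
  simulate  = list(n_taxa = 20, n_loci = 100),
  occupancy = list(fraction = 0.5, rounding = "ceil"),
  trim      = list(q_low = 0.2, q_high = 0.2),
  seed      = 1,
  out       = "run_out"
)
manifest <- run_pipeline(cfg)
manifest$stages    # loci surviving each stage
manifest$matrix    # dimensions and missing-data percentages
```

The same run from a shell, via the bundled CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/supermat-cli.R", package = "supermat"))') \
  run config=cfg.yaml
```
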