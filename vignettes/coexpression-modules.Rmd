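---
title: "Annotating genes by coexpression module membership: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating genes by coexpression module membership: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

## The problem

Microarray compendia for crop species such as rice contain many experiments,
each probing a planned set of treatments — developmental series, stress
panels, tissue atlases. Genes that respond coherently to those treatments
form coexpression modules, and module membership is a useful annotation for
the large fraction of plant genes with no functional assignment. coexmod
implements the full chain from probe-level data to annotated modules, in two
modes: *condition-dependent* analysis, where each experiment is analyzed on
its own against its own treatments, and *condition-independent* analysis,
where all experiments are pooled into one compendium first. The package also
ships a synthetic-data generator with planted ground truth, so that every
stage of the chain can be validated quantitatively — something that is
impossible on real compendium data, where no true module labels exist.

## From probes to gene expression

Affymetrix probe sets (11 probes of 25 bases on the Rice GeneChip) are
assigned to genes by exact matching of each probe against transcript
sequences (`index_transcripts()`, `assign_probe_sets()`):

* a set is **assigned** when nine or more of its probes match a single
  transcript perfectly (full-length, ungapped, exact);
* a set reaching nine perfect matches on two or more transcripts is
  **discarded**;
* anything else is **unassigned**.

"Perfect" is taken literally — no mismatch allowance — because soft matching
would need an arbitrary threshold the assignment rule does not define.
Matching checks both the probe and its reverse complement (GeneChip probes
are antisense to the mRNA and archived probe sequence files vary in
orientation); this is configurable via `revcomp = FALSE`. Probes containing
`N` never match. When two or more probe sets are assigned to one gene, the
gene's expression is the arithmetic mean of the sets' signals per sample,
taken on the linear signal scale *before* log2 transformation
(`summarize_gene_expression()`), so the mean is a mean of signals rather
than of logarithms.

## Preprocessing and the CV filter

Expression values are log2-transformed, replicate arrays are averaged per
treatment (biological and technical replicates treated identically), and
genes are filtered by coefficient of variation across the treatment-level
profile: `cv = sigma / mu` with the n−1 standard deviation, keeping genes
with `cv >= cutoff`. The filter removes constitutively expressed,
unexpressed and weakly varying genes; lowering the cutoff passes more genes.
Two conventions of "CV" circulate (sigma/mu and its reciprocal); coexmod
uses sigma/mu with a keep-if-greater rule, the only orientation under which
smaller cutoffs pass more genes, and offers `invert = TRUE` for the
reciprocal convention. The boundary is inclusive (`cv == cutoff` keeps the
gene) for determinism. A gene with nonpositive mean log2 expression has no
meaningful CV; it is dropped and flagged.

## The unsigned weighted network

For the genes passing the filter, over treatment-level profiles:

1. Pearson correlation matrix `r` (`correlation_matrix()`);
2. unsigned soft-thresholded adjacency `a = |r|^beta`
   (`soft_adjacency()`) — unsigned so that positively and negatively
   correlated genes can share a module, soft so that weak correlations are
   suppressed without a hard cutoff;
3. topological overlap
   `omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
   `l_ij = sum_{u != i,j} a_iu a_uj` (`topological_overlap()`), which scores
   two genes by their direct connection *and* their shared weighted
   neighbors; the unsigned single-step form is used;
4. average-linkage hierarchical clustering of the dissimilarity
   `d = 1 - omega` (`cluster_genes()`, backed by `stats::hclust`);
5. a **static tree cut** (`cut_modules()`): every maximal subtree whose
   internal merge heights all lie at or below `tree_cut` is a candidate
   cluster, and candidates with at least `min_module_size` genes become
   modules. The cut is implemented directly over the merge list with an
   inclusive boundary; because average-linkage heights are monotone, the
   assigned-gene count is provably non-decreasing in `tree_cut`.

The static cut was chosen over adaptive ("dynamic") variants because it is
deterministic, has a provable monotonicity in its one parameter, and makes
the tunables' effects transparent; an adaptive cut can be layered on top
without touching the rest of the chain. `min_module_size` defaults to 30,
below the smallest module size this kind of analysis typically reports
(about 40 genes).

Modules are named by the standard color sequence (turquoise, blue, brown,
...) in order of decreasing size, ties broken by the smallest first-gene
index; the fifteenth color is midnightblue. Unassigned genes keep the
reserved label `"unassigned"` and are reported individually with singleton
trend profiles rather than as a pseudo-module.

`beta` and `tree_cut` are data-set-specific choices (published analyses of
the rice compendium used beta 4–30 and tree cuts 0.6–0.95 per experiment).
`pick_beta()` recommends the smallest power whose scale-free fit index —
the signed R² of the log10 frequency vs log10 connectivity regression over
ten equal-width connectivity bins — reaches `rsq_cut` (default 0.85), but an
explicitly configured beta always wins: the recommendation is frequently
inconclusive on designed-treatment experiments, where connectivity need not
be scale-free.

## Eigengenes, sign groups and trends

Each module's eigengene is the first principal component of its z-scored
gene × treatment submatrix, oriented to correlate non-negatively with the
module's mean z profile; a gene's sign group is the sign of its correlation
with the eigengene (zero counts as positive). The negative group holds the
module's anti-correlated members — the reason for using unsigned
correlations in the first place. Z-scores use the n−1 standard deviation
throughout (the same convention as the CV), so each non-constant gene's
profile has mean 0 and sd 1 across treatments. Module trend summaries
(`trend_summary()`) are the mean z per treatment within each sign group.
When a module splits exactly 50/50 into anti-correlated halves the
eigengene's orientation is mathematically arbitrary; the two sign groups are
still well defined.

## Domain enrichment

Each (module, domain) pair with at least one annotated module gene is tested
with the upper-tail hypergeometric probability (via `stats::phyper`, which
works in log space), Bonferroni-corrected at alpha = 0.01. Two choices are
deliberate and configurable because the convention is not standardized:

* the background universe is the set of genes analyzed in that experiment
  (those passing the CV filter) — the pool modules were actually drawn from
  — not the whole genome;
* the Bonferroni family is the count of (module, domain) pairs actually
  tested within one analysis.

## Comparing analyses

`membership_profiles()` / `membership_distribution()` tabulate in how many
experiments each gene was assigned to a module (genes never assigned are
excluded, matching how such tables are conventionally reported);
`venn_counts()` gives the four-way assigned/unassigned split over genes
analyzed under both strategies; `module_overlap_matrix()` cross-tabulates
condition-dependent against condition-independent modules with explicit
`unassigned` and `not_analyzed` columns so row sums equal module sizes
exactly.

## The synthetic-data generator

`generate_experiment()` works directly on the log2 scale:

```
x[g, s] = b_g + s_g * lambda_g * trend_m(treatment(s)) + noise
```

with baselines `b_g ~ U(4, 12)` log2 units (the intensity spread of
expressed genes), per-gene loadings `lambda_g ~ U(loading_range)`, signs
`s_g` (a planted fraction of members is anti-correlated), i.i.d. Gaussian
noise (`noise_sd`, default a quarter of the mean loading), plus pure-noise
background genes and near-constant housekeeping genes whose noise sd is
`noise_sd / 10` — guaranteeing their removal by any practical CV cutoff.
Generation on the log2 scale avoids modeling raw chip intensities, which
the analysis chain never sees.

Two generator choices deserve emphasis:

* **Loadings default to 8–12 log2 units with unit-variance trends.** The CV
  filter at cutoffs 0.6–0.9 on log2 data selects genes whose expression
  swings span much of the intensity range — on/off, tissue-specific
  behavior. Planted dynamic genes must be the kind of gene that filter
  keeps, so their swings are sized accordingly (CV roughly 0.65–3 over the
  baseline range), while background genes (CV below about 0.4) and
  housekeeping genes (CV about 0.03) fall below the cutoffs.
* **Reference trends are orthogonalized** (`orthogonal_trends()`). With
  only 12 treatments, independently drawn Gaussian trends can correlate
  strongly by chance, and two "distinct" planted modules would then
  genuinely coexpress — the planted partition would not be an identifiable
  ground truth. QR-orthogonalized, unit-variance trends make distinct
  modules exactly uncorrelated drivers, so recovery failures are
  attributable to the method, not to an ill-posed truth.

`reference_synthetic_spec()` fixes the benchmark conditions used throughout
the test suite: five modules of 40–120 genes, 30% anti-correlated members,
12 treatments × 3 replicates, 500 background and 100 housekeeping genes,
noise at a quarter of the mean loading; analyzed with CV 0.6, beta 6, tree
cut 0.95, minimum module size 30.

The probe layer (`generate_probe_layer()`) gives every gene a random
transcript and an 11 × 25-base probe set drawn from it, plus planted
rule-boundary fixtures: degenerate sets with exactly 8 perfect matches
(expected outcome: unassigned) and multi-mapping sets matching two
transcripts through a shared cassette (expected: discarded). Transcripts
are uniform-random nucleotide strings; 25-mer collisions between unrelated
random transcripts have probability of order `len / 4^25` and are ignored.
No biological sequence realism is attempted — the layer exercises the
mapping rules, nothing else.

`generate_annotations()` draws each (gene, domain) pair independently at a
background rate; members of a module with a planted domain carry it at
`fold × rate`, capped at 1, with `fold = Inf` meaning certain carriage.

What the generator does *not* emulate: raw probe intensities and
normalization artifacts, chip-level quality failures, correlated noise
between samples, batch effects, and realistic annotation co-occurrence
structure. Passing the planted-recovery benchmarks therefore demonstrates
the correctness of the chain's logic under its own model, not performance
on real arrays.

## The obscuring benchmark

The central comparative question is whether pooling unrelated experiments
obscures condition-specific modules. `obscuring_benchmark()` plants two
shared modules in every one of three experiments (with independent trends,
loadings and signs per experiment) and one module `M` only in experiment 1;
in the others, M's genes are pure noise. Recovery is scored per run as the
adjusted Rand index between planted and recovered labels over all
planted-module genes analyzed in that run, keeping `unassigned` as its own
recovered label (restricting to M's genes alone would make the true
partition a single class, for which the ARI degenerates). Both runs use
identical parameters (CV 0.6, beta 6, tree cut 0.95, minimum size 30) so
the comparison isolates the effect of pooling. The condition-dependent run
is expected to recover M at least as well as the pooled run; with three
experiments the dilution is mild and ties are common, and the margin grows
with the number of pooled unrelated experiments.

## Numerical choices and degenerate inputs

* n−1 denominators for all standard deviations (CV, z-scores).
* CV boundary inclusive; static-cut boundary inclusive (`height <=
  tree_cut`).
* Zero-variance genes: an error in `correlation_matrix()` (they cannot
  survive a positive CV cutoff), exclusion with a warning in
  `trend_summary()`.
* A gene with zero correlation with its module eigengene joins the positive
  sign group.
* Fewer than two genes passing the CV filter: the pipeline returns an empty
  partition with a warning rather than failing.
* All connectivities identical: the scale-free fit index is undefined and
  returned as `NA` with an explanation attribute.
* Errors are classed (`coex_param_error`, `coex_data_error`) and name the
  offending gene, sample or probe set.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data at
desk scale: reference recovery uses 1,000 genes × 36 arrays per seed over
20 seeds; the obscuring benchmark pools three 230-gene experiments over 20
seeds; oracle checks use 20-gene networks (50 replicates × 3 powers)
against a literal triple-loop overlap formula and all 3,184 hypergeometric
instances with N ≤ 12 against exhaustive enumeration; enrichment error
control uses 200 label permutations. These sizes were chosen so the whole
validation runs in well under a minute while leaving the statistical
assertions (pass fractions over seeds) comfortably powered. Full-compendium
inputs (tens of thousands of genes) are supported by the same code paths;
the TOM computation is dense matrix algebra with O(n²) memory, so analyses
beyond roughly 20,000 genes need the CV filter to do its job first —
which is also how the original compendium analyses were run.

## Known limitations

* Only the static tree cut is provided; adaptive tree-cut variants can
  assign more genes on real dendrograms with gradual merges.
* Unsigned networks only; no signed adjacency, no eigengene meta-networks,
  no module preservation statistics.
* The probe mapper is exact-match only, by design; it is not a general
  aligner and does no genomic placement.
* The enrichment module implements Bonferroni control only; FDR procedures
  are out of scope.
* The generator's independence assumptions (noise, annotations) make
  synthetic power estimates optimistic relative to real data.
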