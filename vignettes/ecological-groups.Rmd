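---
title: "Ecological groups and assembly processes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological groups and assembly processes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asgroups)
```

This vignette is the package's account of its statistical machinery: the
models behind each classification, the parameters that matter and their
defaults, what the synthetic generator does and does not emulate, and the
numerical decisions taken where the methods literature leaves room.

## The data model

The working object is an integer OTU-by-sample count matrix (rows =
OTUs, columns = samples; the classic QIIME orientation, used by every
function in the package). Counts are reads of a marker gene (16S rRNA)
surveyed at several sites — in the motivating setting, activated-sludge
samples from full-scale wastewater treatment plants in two cities.
Depths are uneven across samples, so analyses begin by rarefying each
sample to a common depth (7,000 reads is the package default, a typical
choice for bacterial amplicon tables; archaeal tables are usually deeper,
e.g. 12,000). Rarefaction is a multivariate hypergeometric draw —
subsampling *without* replacement — and samples below the target depth
are dropped rather than up-sampled, because subsampling cannot create
reads. All-zero OTU rows are kept by default (`drop_empty = FALSE`) so
that group labels computed on a parent table remain addressable.

## Core and satellite taxa

The core/satellite distinction rests on spatial aggregation. Under
random (Poisson) placement of an OTU's reads across $n$ samples the
variance equals the mean, and the scaled dispersion
$D_\mathrm{classic} = (n-1)\,s^2/m$ follows $\chi^2_{n-1}$. The package
also implements the occurrence-weighted form used in the ecological
literature this package serves, $D_\mathrm{occ} = (s^2/m)\cdot o$ with
$o$ the occupancy; both are referred to the same
$\chi^2_{n-1}$ band at probabilities `alpha_band = c(0.025, 0.975)`.
Two points deserve emphasis:

* $D_\mathrm{occ}$ has no exact $\chi^2$ null — the occupancy factor
  replaces $n-1$, so the test is conservative for low-occupancy OTUs and
  anticonservative at full occupancy relative to the classic statistic.
  Both modes are exposed; `"classic"` is the one whose 5% type-I error
  under an i.i.d. Poisson null the test suite verifies, and
  `"occurrence"` is the default because it is the form used in the
  surveys this package mirrors. No claim is made that either mode
  reproduces any particular published OTU count.
* Over-dispersion alone does not make an OTU "widely distributed and
  locally abundant": an OTU whose reads all sit in one sample maximizes
  aggregation. Core therefore additionally requires occupancy at least
  `core_min_occupancy_frac` (default 0.5) of samples; over-dispersed
  OTUs below that threshold are classed satellite, and under-dispersed
  (below the 2.5% quantile) or all-zero OTUs are `unclassified`. The
  published surveys this mirrors likewise leave a large remainder that
  is neither core nor satellite.

## Habitat generalists and specialists

Occurrence alone confounds abundance with niche breadth — abundant taxa
are everywhere by sampling alone. The null model therefore preserves
each OTU's total reads, each sample's depth, *and* the table's number of
non-zero cells (fill), and asks whether the OTU's observed occurrence is
extreme against that null. Null tables are generated by the count-matrix
quasiswap scheme: a Patefield (conditional-uniform, fixed-margins) start
followed by random $2\times2$ swap updates that remove surplus non-zero
cells until the observed fill is restored. The package delegates the
randomization to vegan's C implementation (`nullmodel(x,
"quasiswap_count")`); `patefield_sample()` wraps `stats::r2dtable`. With
`n_null = 1000` tables (the conventional setting; at least 100 are
required), the 2.5th/97.5th empirical percentiles of the null occurrence
bracket each OTU: above ⇒ generalist, below ⇒ specialist, otherwise
nonsignificant. A normal-approximation interval (null mean
± 1.96 sd) is available via `ci_method = "normal"` because the
descriptions of this procedure in the literature are ambiguous between
the two; percentile is the default as it makes no distributional
assumption on a discrete, often skewed null.

Levins' niche breadth $B_i = 1/\sum_j p_{ij}^2$ (on the OTU's
across-sample proportions) is offered as an alternative metric
(`metric = "levins_b"`), matching the niche-breadth flavor of some
reference implementations; occurrence is the default.

One structural limitation is worth knowing: occurrence is capped at the
number of samples. An OTU abundant enough that its null occurrence is
always $n$ can never be called a generalist by occurrence — the
observed value cannot exceed a degenerate null interval. Detectable
generalists are therefore taxa of modest total abundance spread more
evenly than the null allows. The planted generalists in the synthetic
scenario are built accordingly (one read per sample).

## Abundance-based β-null deviation

For a given ecological group, deterministic assembly shows up as
between-sample dissimilarity different from what stochastic sampling of
the regional pool would produce. The null model preserves (i) each
sample's group read total ("local community size") and (ii) the group's
regional relative abundance distribution (group row totals summed over
samples, normalized), and redraws each sample's composition
multinomially. For each of the `n_null = 999` null metacommunities the
pairwise Bray-Curtis matrix is computed; the per-pair expectation is the
mean over nulls, and the **deviation** of a pair is observed minus
expected. Three documented choices, each genuinely open in the
literature:

* **Counts, not transformed abundances.** Observed dissimilarity is
  computed on the rarefied counts because the null generates counts;
  Hellinger transformation is reserved for ordination and the
  group-structure tests.
* **Per-pair deviations, not a single mean.** The mean deviation is
  reported (and equals the mean of the pairwise deviations by
  construction), but the full per-pair vector is retained so that
  distributions can be plotted and groups compared by Wilcoxon rank-sum
  tests, which is how the deterministic-vs-stochastic contrast is
  actually assessed.
* **With-replacement draws.** Multinomial sampling is the default; a
  without-replacement variant (`replace = FALSE`, shuffling the pooled
  reads across samples) is provided and agrees closely at survey depths,
  where the pool is far larger than any one sample.

Interpretation is by magnitude: deviations near zero mean the observed
turnover is what regional sampling alone produces (stochastic);
deviations away from zero — positive when sites are more differentiated
than the null, negative when they are more homogeneous — indicate
deterministic structuring. Samples with zero group reads carry no
information about the group and are excluded from its pairwise set with
a warning, which is why a group confined to two sites yields a single
pair and is not compared against groups spanning all sites.

## The synthetic metacommunity generator

Real raw sequence data are deliberately not required; the generator
supplies study-shaped tables with known truth. Defaults are the survey
conditions the package mirrors: 13 samples, 7,000 reads per sample, 500
regional OTUs, and a lognormal regional SAD with `sdlog = 2` — several
orders of magnitude between dominant and rare taxa, which reproduces the
strong positive abundance-occupancy relationship seen in such surveys
(and verified by the test suite: Spearman correlation of log mean
abundance with occupancy above 0.8 under neutral sampling). Two assembly
modes:

* **neutral** — every sample is one multinomial draw from the shared
  regional pool; the β-null deviation of such tables is ~0 by
  construction, which the tests use as a calibration target
  (|deviation| < 0.02 across replicate seeds).
* **niche** — each OTU receives an optimum uniform on the environmental
  range and a Gaussian response of breadth `niche_sd` (default 0.15 on a
  [0, 1] axis — narrow enough that the 13 evenly spaced sites see
  substantially different effective pools); sample probabilities are the
  SAD weighted by the response, renormalized. This produces strong
  between-site turnover and a strongly positive deviation.

The environmental axis is one-dimensional; real surveys have many
covariates (ammonium, organic C/N, heavy metals, …), but one axis
suffices to create deterministic structure for recovery tests. Planted
groups are appended rows: core OTUs draw per-sample Poisson counts whose
rates share a lognormal site effect (`core_mean = 60`,
`core_site_sd = 1`), making them both ubiquitous and strongly
over-dispersed; satellites concentrate ~30 reads in 1–2 random samples;
generalists spread one read to every sample; specialists place 100 reads
in two designated samples. These settings were fixed once, by pilot
runs of the independent oracles, so that each planted class sits well
inside its intended detection region rather than on a boundary.

What the generator does **not** emulate: sequencing error, chimeras and
PCR bias (upstream of the package's scope), phylogenetic correlation
among OTUs, multi-dimensional environments, and temporal dynamics.
Passing recovery tests on these tables therefore demonstrates the
correctness and calibration of the statistics, not their field
performance on real communities.

## Numerical and interface decisions

* Percentages intended for comparison with published tables are rounded
  half-up to one decimal (`round_half_up()`), not banker's rounding.
* Permutation P-values use the `(hits + 1)/(n_perm + 1)` convention and
  so are never zero; with six samples the permutation machinery
  enumerates the complete set, making the P-values exact (the tests
  verify them against brute-force enumeration over all label
  arrangements).
* ANOSIM and Wilcoxon use average ranks for ties; the Wilcoxon switches
  from exact enumeration to the continuity-corrected normal
  approximation when samples are large or tied.
* PCoA reports negative eigenvalues (possible for Bray-Curtis) with a
  warning rather than applying Lingoes/Cailliez corrections; proportions
  of variance are computed over positive eigenvalues only.
* Bray-Curtis between two all-zero samples is defined as 0 (with a
  message), so distance matrices are always complete.
* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; nothing touches the global stream. The pipeline
  derives per-stage sub-seeds by hashing the stage name with the master
  seed, so adding a stage never perturbs earlier stages' randomness.
* Degenerate inputs are contracts, not crashes: all-zero OTU rows are
  "untestable" in the dispersion test; a single-row or single-column
  margin forces the Patefield table outright; rarefaction refuses depths
  no sample reaches with a named error.

## Problem sizes

The test suite runs the statistics at the scale the package targets —
13 samples × 500–580 OTUs × 7,000 reads — with 150–1,000 null tables
and 99–999 null metacommunities depending on what the check needs;
type-I calibrations use 4,000–10,000 simulated OTUs and a few hundred
replicate tests. The complete suite takes well under a minute; the
`analysis/` scripts and `scripts/acceptance.R` regenerate everything
they report at run time.

## Known limitations

* The occurrence-weighted dispersion statistic's null is approximate
  (see above); exact published OTU counts from any particular survey are
  not reproducible from the statistic alone, and the package does not
  claim them.
* Occurrence-based generalist detection is blind to abundant ubiquitous
  taxa (null ceiling); consider `metric = "levins_b"` where that
  matters.
* The β-null deviation compares against one specific null (fixed local
  sizes, regional SAD, multinomial composition); it quantifies departure
  from stochastic sampling of a common pool, not the identity of the
  deterministic process.
* Groups occupying few samples yield few pairwise deviations and
  correspondingly weak Wilcoxon comparisons; the functions refuse or
  warn rather than silently proceeding.
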