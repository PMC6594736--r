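# asgroups

Ecological-group partitioning and assembly-process analysis for
multi-site microbiome count tables, built for activated-sludge (AS)
surveys of wastewater treatment plants but applicable to any
taxa-by-samples OTU table.

Microbial communities in engineered systems are mixtures of ecologically
distinct assemblages: **core** taxa (widespread and locally abundant),
**satellite** taxa (rare and restricted), **habitat generalists**
(occurring at more sites than their abundance warrants) and **habitat
specialists** (occurring at fewer). Whether each assemblage is put
together by deterministic processes (environmental filtering, species
interactions) or stochastic ones (dispersal, drift) is the central
question this package addresses, using three statistics:

1. **Core/satellite partition** — a chi-squared test of the index of
   dispersion. For OTU *i* with counts across *n* samples, mean *m*,
   unbiased variance *s²* and occupancy *o* (samples with count > 0),

   D_occ = (s²/m) · o       or       D_classic = (n−1) · s²/m,

   compared to the 2.5/97.5% quantiles of χ²(n−1). Inside the band the
   OTU is randomly (Poisson-)distributed; above it, aggregated. Core
   OTUs are over-dispersed **and** occupy ≥ 50% of samples (threshold
   configurable); over-dispersed but restricted OTUs, and in-band OTUs,
   are satellite; under-dispersed or all-zero OTUs are unclassified.
   `D_classic` has χ²(n−1) as its exact Poisson null and is used for
   calibration checks; `D_occ` is the occurrence-weighted form common in community ecology
   and the default.

2. **Generalist/specialist classification** — observed occurrence of
   each OTU against the 95% interval of its occurrence in 1,000
   quasiswap null tables (row sums, column sums and number of non-zero
   cells all preserved; Patefield start + swap updates, vegan's
   `quasiswap_count` scheme). Occurrence above the interval ⇒
   generalist; below ⇒ specialist. Levins' niche breadth
   B = 1/Σ_j p²_ij is available as an alternative metric.

3. **Abundance-based β-null deviation** — per ecological group, the
   observed mean pairwise Bray-Curtis dissimilarity minus its
   expectation over 999 null metacommunities that preserve each sample's
   group read total and the regional species abundance distribution
   while randomizing composition. Deviations near zero ⇒ stochastic
   assembly; away from zero ⇒ deterministic assembly. Groups are
   compared by Wilcoxon rank-sum tests on their pairwise deviations.

Around these sit the standard toolkit: rarefaction to even depth,
Hellinger transformation, PERMANOVA (Adonis) / ANOSIM / MRPP / Mantel
permutation tests, PCoA, abundance-occupancy regression, per-group
taxonomic composition, and a synthetic metacommunity generator
(`simulate_metacommunity()`, `plant_group_structure()`) that produces
lognormal-SAD multinomial tables under neutral or niche assembly with
planted ground-truth groups, so every claim the package makes is tested
against known truth.

## Worked example

```r
library(asgroups)

# a 13-sample, 7000-reads/sample neutral metacommunity with 20 planted
# OTUs per ecological group
sim <- simulate_metacommunity(metacommunity_scenario(seed = 11))
pl  <- plant_group_structure(sim$table, seed = 2)

cs  <- core_satellite(pl$table)                              # chi-squared dispersion
gs  <- generalist_specialist(pl$table, n_null = 1000, seed = 3)  # quasiswap null
asg <- assign_groups(cs, gs)
group_summary(pl$table, asg)
#>        group n_otus pct_otus reads read_fraction
#> 1       core     29      5.0 29222       0.24095
#> 2  satellite    425     73.3 91393       0.75358
#> 3 generalist     24      4.1   308       0.00254
#> 4 specialist     40      6.9  2383       0.01965

core_bn <- beta_null_deviation(pl$table, asg$otu_id[asg$cs_label == "core"],
                               n_null = 999, seed = 4, group_label = "core")
core_bn
#> beta-null deviation [core]
#>   observed mean beta: 0.4819
#>   expected mean beta: 0.1487 (999 nulls, sd 0.0011)
#>   deviation mean:     +0.3332 over 78 sample pairs
```

The core group's dissimilarity sits far above its null expectation (its
planted members carry deterministic site-to-site structure), while the
satellite group — background OTUs drawn from the shared regional pool —
sits at its null:

```r
sat_bn <- beta_null_deviation(pl$table,
                              asg$otu_id[asg$cs_label == "satellite"],
                              n_null = 999, seed = 5, group_label = "satellite")
compare_group_deviations(core_bn, sat_bn)
#> core vs satellite: median diff +0.327, Wilcoxon P = 4.26e-27
```

All 20 planted OTUs of every group are recovered by the partition in
this run (`analysis/02_partition.R` reports the recovery table).

## Analysis workflow

`analysis/01_simulate.R` … `04_group_stats.R` are thin, numbered drivers
over the package that regenerate the whole study on synthetic data:
simulate neutral/niche/planted tables, partition, compute per-group
β-null deviations, and run the group-structure statistics; each writes
its tables under `results/`. `run_pipeline(pipeline_config(...))` chains
the same stages programmatically and writes a JSON manifest for exact
reproduction.

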