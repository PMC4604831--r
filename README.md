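# quartetcoal

Coalescent analysis of four-taxon species trees under incomplete lineage
sorting (ILS) and gene flow.

When four species diverge in quick succession from large ancestral
populations, most genomic regions carry gene trees that disagree with the
species tree, and post-divergence migration adds reticulate signal on top.
This package implements, end to end on synthetic data, the analysis chain
used to resolve such systems (the motivating case is the black-and-white
flycatcher complex: collared C, pied P, Atlas A, semicollared S):

* a structured-coalescent simulator for isolation-with-migration
  demographies — per-branch diploid `Ne`, split times in generations,
  directional `Nm` migration, infinite-sites mutation at
  `mu = 2.5e-9`/site/generation, optional outgroups — emitting gene trees,
  FASTA alignments and polarized variant tables;
* windowed gene-tree discordance statistics: canonical topology spectra from
  leaf subsampling with outgroup rooting, the genealogical sorting index
  (gsi), a topology diversity index `tdi = (1 - Σp_i²)/(1 - Σ(1/I)²)`,
  relative LCA depth, 500-kb aggregation and genome-wide topology rankings;
* exact multispecies-coalescent expectations (under a star species tree the
  15 rooted four-taxon topologies occur at 1/18 ≈ 5.6% each for the 12
  caterpillars and 2/18 ≈ 11.1% for the 3 balanced shapes, by ranked-history
  enumeration) and a rooted-triple pseudo-likelihood species-tree estimator
  (triple concordance `1 - (2/3)e^{-t}` in coalescent units);
* joint 2D-SFS composite-likelihood fitting of four candidate
  isolation-with-migration models with ΔAIC/Akaike-weight comparison and
  block-resampling confidence intervals;
* ABC model choice (rejection + weighted multinomial logistic regression on
  60 summary statistics) and parameter estimation (SIMPLS partial
  least-squares reduction, regression-adjusted posteriors, 90% HPD
  intervals) with leave-one-out cross-validation.

See `vignettes/quartetcoal-methods.Rmd` for the models, assumptions and
numerical conventions, and `analysis/01…06_*.R` for the narrative workflow
over the package.

## Worked example

Simulate 500 unlinked gene trees under a strong-signal asymmetric species
tree (((P,A),C),S) with both internal branches at one coalescent unit, count
topologies, and fit the species tree by pseudo-likelihood:

```r
library(quartetcoal)
N <- 5e4
dem <- demography(species = c("C","P","A","S"), topology = "(((P,A),C),S);",
  split_times = c(AP = 2e5, ACP = 2e5 + 2*N, ACPS = 2e5 + 4*N),
  ne = c(C = N, P = N, A = N, S = N),
  ne_anc = c(AP = N, ACP = N, ACPS = N), mu = 2.5e-9)
des <- sample_design(haplotypes_per_species = 2, n_loci = 500, seed = 7)
trees <- simulate_gene_trees(dem, des)
cfg <- quartetcoal:::lineage_config(dem, des)
sm <- setNames(cfg$species, cfg$labels)
keys <- vapply(trees, function(tr) {
  sel <- vapply(dem$species, function(s) tr$tip.label[sm[tr$tip.label]==s][1], "")
  canonical_key(ape::keep.tip(tr, sel), sm)
}, "")
head(sort(table(keys), decreasing = TRUE), 3)
#> (((A,P),C),S) ((A,P),(C,S)) (((A,P),S),C)
#>           284            49            48
fit_species_tree(keys, dem$species)
#> Pseudo-likelihood species tree: (((A,P),C),S)
#>   internal branches (coalescent units): 1.055, 1.038
#>   log pseudo-likelihood: -1232.138
```

Even with strong signal only 57% of gene trees match the species tree — ILS
at work — yet the pseudo-likelihood fit recovers the generating topology and
both branch lengths (truth: 1.0 and 1.0). The analytic star-tree reference
points for a single topology are:

```r
round(100 * star_tree_topology_probs(c("C","P","A","S"))[
  c("(((A,P),C),S)", "((A,P),(C,S))")], 2)
#> (((A,P),C),S) ((A,P),(C,S))
#>          5.56         11.11
```

so the observed 57% for one caterpillar against a 5.6% star-tree baseline is
what "resolved internal branches" looks like in topology-frequency space.

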