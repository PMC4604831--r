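---
title: "Methods: coalescent species-tree analysis of a four-taxon system with gene flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent species-tree analysis of a four-taxon system with gene flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Four closely related species — collared (C), pied (P), Atlas (A) and
semicollared (S) flycatchers — split within the last one to two million
generations from ancestors with effective population sizes in the hundreds of
thousands. Under these conditions most genomic regions have genealogies that
disagree with the species tree: incomplete lineage sorting (ILS) is pervasive
because internode times are short relative to ancestral coalescent times, and
post-divergence gene flow adds reticulate signal on top. `quartetcoal`
implements, on synthetic data, the full analysis chain used to resolve such a
system: coalescent simulation of the study design, windowed gene-tree
discordance description, analytic multispecies-coalescent (MSC) expectations
with a rooted-triple pseudo-likelihood species-tree estimator, joint
site-frequency-spectrum (SFS) composite-likelihood model comparison, and
approximate Bayesian computation (ABC) model choice.

# The generating model

A demography (`demography()`) is a rooted species tree over the four ingroup
labels with:

* `ne` — current diploid effective size per species (individuals);
* `ne_anc` — diploid size of each ancestral branch, keyed by the sorted
  member labels of its clade (e.g. `"AP"`);
* `split_times` — generations before present, strictly increasing toward the
  root;
* `migration` — `Nm` values (migrants per generation, forward in time) for
  directional pairs `"X<-Y"` among extant species;
* `mu` — mutation rate per site per generation, default `2.5e-9`;
* optional outgroup species joining beyond the ingroup root.

Internal time is always generations. A `gen_time` field (years per
generation) is carried for unit conversion on input/output only and has no
default: no value is assumed, and no internal computation uses it. Split
times quoted in years in the source material are used as generation counts
for synthetic truth; because the mutation rate is per generation, this is a
labeling convention that rescales nothing downstream.

The simulator is a structured coalescent run backward in time (compiled
code): within a population of diploid size `N`, each lineage pair coalesces
at rate `1/(2N)` per generation; a lineage in recipient species X migrates
(backward) to donor Y at rate `Nm[X<-Y] / (2 N_X)`; at each split time the
daughter populations merge and adopt the ancestral `Ne`. Migration between a
pair is active only while both are unmerged leaf populations, matching the
`Nm` parameterization of the fitted models. Mutations follow the
infinite-sites model on a finite sequence with collision redraw, so every
variant is biallelic and derived carriers are exactly one clade of the
genealogy — the assumption every downstream statistic makes.

Loci are unlinked and internally recombination-free; the study design this
emulates spaces loci at least 50 kb apart precisely to justify that
approximation. Sequencing error, selection and within-locus recombination
are deliberately out of scope, so passing tests say nothing about
robustness to mis-phasing, paralogy or error-driven singletons in real data.

## The four candidate demographies

Only the winning topology `(((P,A),C),S)` has published parameter estimates.
The recovery experiments need equally parameterized competitors, so the other
three candidates reuse the same values positionally — first split
(561,326; ancestral Ne 256,334), second split (638,933; 1,067,020), root
(1,218,623; 304,660), current sizes (C 449,385; P 304,853; A 244,520;
S 238,722) and the six directional `Nm` values among C–P, P–A and C–S. This
makes the four models exchangeable in information content; none is
privileged by its parameterization.

Prior ranges (`model_priors()`) are log-uniform for all population sizes and
migration rates and uniform for split times, with ordering enforced by
rejection; the default fixture demography (`default_demography()`) sits at
the prior midpoints (geometric midpoints on log scales).

# Gene-tree discordance statistics

Windows carry multi-leaf gene trees; one leaf per species (including
outgroups) is drawn per subsampling round, the subtree is rooted on the
deepest outgroup (oldest attachment; ties broken by lexicographic label),
outgroups are dropped and the rooted four-taxon topology is recorded as a
canonical key (children sorted at every node). 200 rounds per window is the
reference setting. Genomic intervals are 0-based half-open everywhere
internally and in BED files; variant positions are 1-based in files.

* **tdi** = `(1 - sum p_i^2) / (1 - sum (1/I)^2)` over the `I = 15` rooted
  topology classes: 0 when a window contains a single topology, 1 when all
  15 are equifrequent. Aggregation over 500-kb spans averages the member
  windows' frequency vectors and recomputes tdi on the average (rather than
  averaging per-window tdi), so a run of internally sorted but mutually
  discordant windows correctly aggregates to a high value.
* **gsi** for a focal species with `n` leaves is
  `gs = (n-1) / sum(d_u - 2)` over the internal nodes of the minimal subtree
  uniting the focal leaves from their MRCA (`d_u` = node degree; the root
  counts 2), rescaled between its tree-specific minimum (all internal nodes
  needed) and 1; it is 1 exactly at monophyly. The test suite pins this to a
  brute-force oracle computed from all-pairs node paths.
* **LCA relative depth** is the height of the ingroup MRCA over the height
  of the root, heights being maximum path length to a descendant leaf.
* Polytomies are never resolved arbitrarily: a subsampling round that hits
  one flags the window (typed condition) and is excluded from the spectrum
  denominator.
* Support-based filtering (mean of the two internal species-defining branch
  supports below a threshold, reference value 50) is applied only when node
  labels carry supports; support computation itself is out of scope.

# Pseudo-likelihood species tree

Each gene tree contributes its four rooted triples. For a candidate rooted
topology with internal branches `t1, t2` (coalescent units), the restriction
to a species triple has a concordant cherry with probability
`1 - (2/3) exp(-tau)` and each discordant resolution `(1/3) exp(-tau)`,
where `tau` is the sum of the candidate branches between the triple's cherry
join and its MRCA. The fit maximizes the product of the four multinomial
likelihoods over `t1, t2 >= 0` for each of the 15 candidates by coordinate
golden-section search (interval `[0, 30]` coalescent units, tolerance 1e-6,
up to 60 sweeps; the one coupled triple makes the problem 2-D but it remains
smooth and effectively unimodal). Candidates within 1e-9 log-units of the
best are reported as a tie set — a star-tree input ties all 15 at zero
branch lengths — and unresolved triples contribute only their resolved
counterparts.

The star-tree limit is computed exactly by enumerating the 18 ranked labeled
coalescent histories of four lineages: each asymmetric (caterpillar)
topology owns one history (1/18 ≈ 5.6%), each symmetric (balanced) topology
two (2/18 ≈ 11.1%).

A deliberate scope note: the estimator assumes no gene flow. Under the
fourth candidate demography the fitted C↔S migration (about half a migrant
per generation) makes the symmetric topology the single most frequent gene
tree, and the pseudo-likelihood fit converges on that symmetric tree even
with thousands of loci. The recovery experiment reports this honestly — it
is the package's clearest demonstration that gene flow can positively
mislead an ILS-only species-tree method, while the migration-aware SFS and
ABC routes below recover the generating topology.

# SFS composite likelihood

Observed data are the six pairwise joint derived-allele spectra over 24
chromosomes per species, including both monomorphic cells, accumulated over
independent 100-bp windows (100,000 windows at reference scale; windows with
more than 20% repeat-masked sites are excluded when a mask is supplied;
sites lacking 24 callable chromosomes in any species are excluded in all).
Down-projection to 24 chromosomes is the deterministic hypergeometric
expectation.

Expected spectra are simulation-based: for each configuration `(i, j)`, the
length of branches subtending exactly `i` and `j` sampled tips of the pair,
relative to total tree length, averaged over simulated genealogies, scaled
by the per-site mutation probability `mu * E[T_total]`, with the remainder
assigned to the monomorphic (0,0) cell. Both averaging conventions are
implemented: mean of per-genealogy ratios, and ratio of means
(`ratio_of_means = TRUE`). Fits default to ratio-of-means because it is the
estimator consistent with Poisson mutation placement (the probability a site
shows configuration `(i, j)` is `mu * E[length_{ij}]`); the mean-of-ratios
variant is visibly biased for high-frequency configurations and is kept as a
documented toggle.

The composite log-likelihood sums `count * log(p)` over all cells of all six
spectra with a floor of 1e-12 on every probability; empty cells contribute
nothing. Fitting maximizes it over the 16 parameters (log scale for sizes
and migration rates; split times mapped through an ordering-preserving
transform) by multistart Nelder–Mead with a relative stop criterion of
0.001. Within a fit every likelihood evaluation re-seeds the genealogy batch
identically (common random numbers), making the noisy surface deterministic;
the returned likelihood is then re-evaluated once with a much larger
simulation batch so that AIC comparisons between models are not limited by
Monte-Carlo noise of the small within-fit batches. Model comparison uses
`delta AIC` and Akaike weights.

Desk-scale choices, stated as the package's own experiment sizes: 30,000
observed windows (3 Mb of sites), 300 genealogies per within-fit evaluation,
6,000 for the final evaluation, 150 Nelder–Mead iterations and two starts
per model. Blind multistart from random corners of a 16-dimensional box does
not reach any model's optimum in that budget; the recovery experiments
therefore anchor the first start of *every* candidate at the same positional
parameter values (the shared values of the four candidate demographies), so
all models start from identical information and the comparison reflects
model structure rather than optimizer luck. Confidence intervals come from
repeating the window subsampling (50 replicates at reference scale, reduced
run counts) and taking empirical 5th–95th percentiles (interpolation as in
`quantile` type 7).

# ABC

Summary statistics are the mean and variance over loci of five pairwise
statistics — segregating sites, shared-polymorphism proportion,
fixed-difference proportion, dXY, and an AMOVA-style PhiST on haplotype
pairwise differences — for each of the six species pairs: 60 labeled values
in a fixed order (pair-major; statistic; mean before variance). Shared and
fixed proportions are normalized by the pooled segregating-site count by
default (per-bp variants are also emitted). PhiST uses haploid units,
matching the haplotype-sampled loci. With complete synthetic data every one
of these statistics reduces to per-site species-level derived-allele counts,
which is what the fused compiled kernel computes; the genotype-matrix route
remains available (`engine = "r"`) and the two are cross-checked in the test
suite.

Rejection standardizes each statistic by its median absolute deviation
(robust to the heavy-tailed variance statistics; this standardization is a
package choice, documented rather than inherited) and retains the closest
rows by Euclidean distance. Model choice fits a weighted multinomial
logistic regression (Epanechnikov weights in the retained set) of the model
label on the standardized statistics, evaluated at the observed vector, with
a frequency fallback when the regression degenerates.

Reference scale is 2×10⁶ simulations per model with 0.1% tolerance — 8,000
retained rows feeding the regression. At desk scale (4,000 rows per model,
1,000 loci of 2 kb, 12 haplotypes per species) the binding constraint is not
the rejection radius but the regression sample: a multinomial fit of 60
statistics on fewer than a few hundred rows is separable and unstable. The
desk-scale configuration therefore keeps the *retained count* at 8,000
pooled rows, letting the distance weights supply locality. Parameter
estimation follows the reference pipeline: a hand-implemented SIMPLS partial
least-squares reduction (10 components by default; an RMSE-per-component
curve on held-out rows is reported), rejection in PLS score space, and a
weighted local-linear regression adjustment per parameter with Epanechnikov
weights; posterior modes come from a weighted kernel density and 90% HPD
intervals from the same density, both clipped to the prior support. If the
local regression degenerates the unadjusted rejection sample is returned,
flagged. Cross-validation is leave-one-out over rows of the reference
tables, reporting the misassignment matrix and the mean posterior
probability of the true model.

A frank note on desk-scale ABC power: with 4,000 rows per model the
recovery experiments identify the generating model in only roughly half to
three quarters of replicates, and the confusion structure varies between
reference-table realizations, because the multinomial decision boundary is
estimated from prior-wide rows that cover the 16-dimensional parameter
space sparsely. This is a table-size effect, not an information deficit:
the 60 statistics separate the four truth-parameterized models perfectly in
a nearest-centroid sense, and at reference scale the retained 8,000 rows
are genuinely local. Even there, the reference analysis reports up to 28%
misassignment for the hardest model pair (the symmetric/asymmetric trees
sharing the pied–Atlas cherry), so ABC is the weakest of the three
model-choice routes at any scale; the acceptance suite reports the
desk-scale recovery rates as measured.

# Numerical and degenerate-input conventions

* Coverage-outlier site filtering excludes sites strictly greater than
  mean + 5 SD of per-site mean coverage, both moments estimated once per
  dataset; boundary sites are retained. Filters are independently
  toggleable and audited per rule.
* Polarization requires both outgroup individuals monomorphic for the same
  allele; any missingness, heterozygosity or disagreement yields an
  undetermined site, treated as missing in all individuals.
* An empty topology spectrum has undefined tdi (`NA`, never 0); diversity
  and pairwise statistics require two haplotypes (two per species for pair
  statistics) and return errors or `NA` otherwise; PhiST of an invariant
  comparison is `NA`.
* All stochastic stages take explicit integer seeds; per-locus streams are
  derived deterministically from the master seed, and identical
  configuration plus seed reproduces byte-identical artifacts (verified via
  the pipeline manifest's MD5 checksums).

# Known limitations

* The pseudo-likelihood module fits the four ingroup species only; whether
  including outgroups changes the ranking is not addressed.
* The composite likelihood multiplies the six pairwise spectra although they
  share underlying sites; this mirrors the reference procedure and inflates
  nominal confidence, which is why comparisons rely on large AIC gaps.
* ABC desk scale trades neighborhood locality for regression stability; at
  reference scale (2×10⁶ rows) the same code applies the nominal 0.1%
  tolerance unchanged.
* The simulator's infinite-sites guard caps mutations at one per site per
  locus; for the parameter ranges used the collision probability is
  negligible, but extremely long loci with extreme sizes should be split.
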