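---
title: "Landscape genomics from GBS data: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape genomics from GBS data: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`landgen` implements a desk-scale landscape-genomics pipeline for a selfing
annual plant sampled in a small number of local groups along an environmental
transect. Its three questions are the classic ones of the field: which SNPs
covary with climate once population structure is accounted for
(genotype–environment association), which loci are more differentiated among
groups than drift can explain (Fst outliers), and whether structural
presence/absence variation revealed by reduced-representation sequencing
coverage tracks the environment (CCA of P/A regions). This vignette documents
the models, the tunable parameters, the synthetic world the package tests
itself against, and the design decisions that were genuinely open.

## The data model

A `genotype_matrix` holds biallelic dosages (0/1/2, `NA` missing) for samples
assigned to groups, with 1-based locus coordinates. Standard filters are a
minor allele frequency of at least 0.05 (computed over non-missing calls,
boundary inclusive) and a per-locus call rate of at least 0.80 — the usual
GBS hygiene for association work. Missing genotypes are never imputed
globally; each estimator states its own missing-data contract (mean
imputation for kinship, PCA and the regression engines; per-locus exclusion
for Fst and allele counts; pairwise deletion for P distances).

Coverage is a bins × samples count table on a fixed 1,000-bp grid. BED-style
inputs (coverage bins, TE mask) are 0-based half-open; VCF and GFF3 are
1-based. All internal interval logic is 0-based half-open, converted at the
I/O boundary.

## Geography and environment

Site distances use the haversine formula on a sphere of radius 6378.137 km
(the WGS84 equatorial radius). The radius is a deliberate choice:
back-calculating the reference distance table for the nine sampling sites
shipped in `inst/extdata/sampling_sites.tsv` reproduces those values
(e.g. 739.2 km) only with 6378.137; the volumetric mean radius 6371 gives
738.3.

The environment table (19 BioClim-style variables plus altitude) is reduced
by PCA after z-normalizing each variable, making the decomposition invariant
to per-variable units. Signs of principal axes are arbitrary; we orient each
loading vector so its largest-magnitude entry is positive. The first three
PCs are the association responses and the CCA constraints.

## Presence/absence regions and TE enrichment

A bin is a P/A bin when every sample of at least one group has exactly zero
reads while at least one other group averages `min_presence_mean` reads per
sample. Depth rules of this kind are sometimes stated as thousands of reads
per sample on average, a figure whose referent (per bin? genome-wide?) is
ambiguous — 1,000 reads in a single 1-kb bin is implausible for GBS — so the
depth requirement is an explicit parameter with a conservative default of 1
read/sample, and larger values remain selectable. Adjacent P/A bins
merge into a region only when their group-presence patterns are identical,
keeping each region interpretable as a single presence/absence event.

TE enrichment compares the masked fraction of P/A bins against the whole
genome and against an equal number of control bins sampled uniformly (by
count, not length-matched) without replacement under a fixed seed.

## Population genetics

Fst is the Weir–Cockerham theta with the diploid a/b/c variance components,
combined across loci as a ratio of sums. The observed-heterozygosity term is
retained even though selfers are nearly homozygous, matching the standard
estimator used by the common population-genetics tools; raw (possibly
slightly negative) values are reported. Kinship is the VanRaden genomic
relationship matrix G = ZZ'/(2·Σp(1−p)) with missing dosages mean-imputed.
Sample trees are neighbour-joining on uncorrected P distances with bootstrap
over loci; support attaches to bipartitions. Cryptic clusters come from
k-means on genotype PC scores with silhouette-based selection of k — a
deterministic stand-in for admixture-model Bayesian clustering, documented
as a substitution.

## LD blocks and the multiple-testing correction

Pairwise D′ is estimated from unphased genotypes by the two-locus EM
(double heterozygotes are the only ambiguous class; the allele-frequency
margins are fixed by the genotype counts). Confidence bounds of |D′| come
from the normalized likelihood profile over a |D′| grid with margins held at
their estimates — the Gabriel/Haploview convention, 90% interval with 5% in
each tail. The genotype likelihood assumes random mating within the sample;
in a selfing population this is an approximation, used here because it is
the convention the block definition was built on.

Blocks follow the Gabriel rules: a candidate is a contiguous run whose
outermost pair is in strong LD (CI lower > 0.7, upper > 0.98) and in which
at least 95% of informative pairs are strong; pairs with CI upper < 0.9
count as recombination evidence (they are non-strong); overlapping
candidates resolve greedily, largest first, ties leftmost. Informative
pairs require both MAFs ≥ 0.05 and ≥ 20 jointly non-missing samples. The
0.95 fraction and the conflict rule are the Haploview defaults; the source
analysis names only the bound cutoffs.

The multiple-testing threshold is `alpha_target / (blocks + singletons)`
with `alpha_target = 0.1` (one tolerated false association in ten). A
partition of 654 blocks + 80 singletons, for example, gives 0.1/734 =
1.362e-4; the package reports full precision rather than a rounded value.

## The two association engines

Both engines test each locus against each environmental PC.

**Mixed model (EMMA-style).** Y = Xβ + Zu + e with u ~ N(0, σ²_g K) and
VanRaden K. The variance ratio is estimated once by REML on the null model
(Brent search on the log-ratio in [−10, 10]) through the spectral
decomposition of K; each SNP is then a GLS Wald t test. Kinship
"compression" is omitted: at n ≈ 90 the exact model is cheap, and
compression is an optimization, not a model change. When K = I and no
covariates are present the engine reduces exactly to OLS (tested to 1e-10).
Q defaults to the first five genotype PCs; cluster-membership covariates
are available but off by default because they over-correct in this design.

**Latent-factor regression.** The deterministic least-squares formulation
of the latent factor mixed model: `n_factors` latent axes are the leading
left singular vectors of the centered genotype matrix *after partialling
out the tested environmental variable*, each locus is regressed on the
environment given the factors, and z-scores are recalibrated by the
median-based genomic-inflation factor. The partialling step matters: it is
what the joint least-squares solution implies, and extracting factors from
the raw matrix instead lets them swallow the tested axis, collapsing power
to near zero. The original engine's MCMC sweep counts are therefore not
parameters here. With `n_factors = 0` the engine is plain regression.

**Power asymmetry, documented.** With nine sampling locations the
environmental response is constant within groups, so any signal is a
group-level cline living in an 8-dimensional between-group space. The
kinship correction leaves roughly one effective unit per group, and five
PC covariates remove five of the eight between-group dimensions. The mixed
model is therefore structurally conservative here (it recovers 30–70% of
injected clines at the corrected threshold in the synthetic world), while
the latent-factor engine recovers essentially all of them — the asymmetry
these two engine families are known for on designs with few sampling
sites. The pipeline's
EAS set is the union of both engines' flags; loci flagged by both are the
strong candidates.

## Fst outlier scan

Per-locus, per-group allele counts enter a beta-binomial (two-allele
multinomial-Dirichlet) likelihood in which logit(Fst_ij) = α_i + β_j: a
locus effect shared by all populations and a population effect shared by
all loci. α_i carries a spike-and-slab indicator with fixed prior odds
(default 10:1 against inclusion) and a N(0, 1) slab — an equivalent
marginal model to reversible jump, with a simpler correctness argument.
β_j has a diffuse N(−1, 1.8) prior on the logit scale; ancestral
frequencies are uniform. Updates are Metropolis-within-Gibbs, vectorized
across loci; proposal scales adapt during burn-in to 25–45% acceptance and
then freeze, so chains are deterministic given the seed. The q-value of a
locus is the mean of (1 − inclusion probability) over all loci ranked at
or above it; the flag threshold is q ≤ 0.05.

The model assumes an island configuration (one β per group). Under strong
hierarchical structure (two deep clades) neutral clade-differentiated loci
can exceed the island-model null — the known structural bias of this class
of scan, discussed and not corrected here (hierarchical extensions are out
of scope). The recovery tests therefore plant outliers on an island-model
background matching the scan's assumptions.

## Positional annotation

A locus is `genic` if inside any annotated gene span, else `upstream5kb`
if within 5 kb of a gene's 5′ start on the coding strand (before the start
of `+` genes, after the end of `−` genes, gene body excluded), else
`distal`. A locus both genic and upstream of another gene is counted once,
as genic; an upstream locus lists every gene whose window contains it. The
5-kb window is the conventional cis-regulatory reach and is a parameter.
Upstream windows are often applied without regard to strand; 5′ regulatory
logic demands strand awareness, so the window is strand-aware by design.

## CCA of P/A regions

The groups × regions binary matrix is treated as a 0/1 abundance
contingency table and fit by ter Braak's algorithm (via vegan) with the
environmental PCs as constraints. Total inertia equals the scaled
chi-square statistic of the table; the headline quantity is the constrained
inertia fraction. The permutation test permutes rows of the constraint
matrix (site-level labels, the standard scheme for this design; the source
names only a permutation count) and reports
p = (1 + #{perm ≥ observed})/(n_perm + 1). A permutation p can never be
below 1/(n_perm+1); analysis reports quoting p < 2.2e-16 alongside 999
permutations are a parametric-printing artifact, and this package reports
the honest grid value.

## The synthetic world

`simulate_dataset()` emulates the sampling design the pipeline targets:
9 local groups × 10
samples on a linear transect of ~740 km, selfing rate 0.99 (equilibrium
inbreeding s/(2−s) ≈ 0.98, giving observed heterozygosity well under
0.05), two deep clades assigned alternating along the transect so that
structure does not mirror geography (distant groups may share a clade),
and 19+1 environmental variables loading
on a single latent gradient with noise s.d. 0.3 so that environmental PC1
is monotone in transect position.

Neutral allele frequencies are hierarchical Balding–Nichols draws
(ancestral → clade at F = 0.5, clade → group at F = 0.1), calibrated so
that the realized between-clade Weir–Cockerham theta at 2,000 loci sits
within ±0.05 of the clade-level knob, while pairwise group Fst spans the
strong local fixation expected of a selfer. Linkage blocks are geometric runs
(mean 3 loci) sharing a haplotype pattern with a 5% per-sample escape
rate. Injected environment-associated loci have group frequencies exactly
logistic in the gradient (slope `eas_effect`, default 3); injected
outliers are Balding–Nichols draws at F = `outlier_fst` (default 0.9,
near per-group fixation). Injected P/A regions (1–4 bins, guarded so they
never merge) are exactly zero in their absent groups; covered bins are
negative-binomial (mean 30, size 5), which makes a spurious all-zero
group essentially impossible, so noiseless exact recovery is a property
of the stated world, not luck. The TE mask places one interval per bin
with binomial length around a 15% base density, multiplied by
`pa_te_enrichment` (default 3) inside P/A regions — enough to make the
TE-driven enrichment ordering (P/A > genome > matched control)
recoverable.
With `pa_env_effect > 0` absence probabilities become logistic in the
gradient, the regime the CCA tests use.

What a green test does **not** establish: the generator has no coalescent
or recombination-map realism, no read-level error model, a single
chromosome, and groups of equal size; real GBS data add depth imbalance
between libraries, reference bias and batch structure that the pipeline
does not model.

## Numerical choices and degenerate inputs

REML is a one-dimensional Brent optimization on log-delta in [−10, 10];
collinear SNP designs are detected by a failed Cholesky and reported as
missing p-values. The EM for haplotype frequencies runs a fixed 100
iterations (convergence is geometric; the margins are fixed). The |D′|
profile grid step is 0.005. Monomorphic loci are dropped before kinship
(mandatory) and flag pairs uninformative in LD. Empty filter results,
all-zero Jaccard rows, empty TE masks and constant Mantel matrices warn
or return defined values rather than erroring. All stage seeds derive
from one master seed by fixed offsets, and identical configurations give
byte-identical outputs.

## Known limitations

Nine groups bound the resolution of every group-level inference: Mantel
tests, CCA permutations (minimum p 1/(n_perm+1)) and mixed-model power
all reflect that. The outlier scan's island-model null is conservative
or anti-conservative under hierarchical structure depending on the
contrast. Bootstrap support values summarize splits, not the
split-network topology of the original figures. None of these limits the
package's own acceptance surface, which is tested at desk scale.
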