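---
title: "Models and methods for diagnostic-SNP hybrid-zone analysis"
author: "HybridPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for diagnostic-SNP hybrid-zone analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HybridPanel)
```

# Setting

HybridPanel analyses the contact zone between two divergent lineages —
call them "northern" and "southern" — genotyped on a small panel of
unlinked biallelic SNPs chosen to be diagnostic (large allele-frequency
differential between the lineages). The default panel size of 96 loci
matches the common 96.96 microfluidic array format. Genotypes are coded
0/1/2 as copies of the southern-lineage allele, so a pure northern
homozygote reads 0 at a diagnostic locus; `orientPanel()` establishes this
orientation from a designated southern reference population at load time
(ties at frequency 0.5 keep the incoming orientation, and flipped loci are
recorded in the object metadata).

Throughout, missing genotype calls are handled by per-locus pairwise
deletion: statistics drop the missing cell, never the whole individual,
mirroring how array no-calls are treated by the standard tools in this
field.

# The twelve-category model

At an unlinked locus, a diploid's two gene copies descend from the
northern and/or southern ancestral gene pools. Every hybrid category is
fully characterised by its probability triple over unordered origin pairs,
(p~NN~, p~NS~, p~SS~). The twelve categories are the two parentals, F1,
F2, the two first-generation backcrosses, and all six second-generation
backcrosses; later-generation hybrids (F3, F4, ...) are deliberately not
separate classes because their genotype-frequency signatures are not
distinguishable from F2 on unlinked biallelic loci — results involving F2
should be read as "F2 or later generation".

Triples are computed by gamete-origin recursion (`categoryTable()`): a
category with triple (p~NN~, p~NS~, p~SS~) transmits a northern gamete
with probability p~NN~ + p~NS~/2, and the offspring triple is the outer
product of the parents' gamete distributions. The test suite verifies all
twelve triples against an independent exhaustive enumeration that pushes
ordered origin-pair distributions through each pedigree explicitly.

Two assumptions matter:

* **Unlinked, freely recombining loci.** Origin pairs are independent
  across loci within an individual. This is why the class-based simulator
  (draw an origin pair per locus from the triple, then draw alleles) and
  the pedigree simulator (simulate the parents, drop gametes with a coin
  flip per locus) agree in distribution — a property the tests check by
  chi-square at n = 10,000 per category.
* **Known category structure.** Only the twelve classes above are
  modelled. A population containing, say, F5 hybrids or continuous clines
  will be absorbed mostly into F2/backcross classes.

# Hybrid classification

`classifyHybrids()` is a plug-in empirical-Bayes version of the
genotype-frequency-class model popularised by NEWHYBRIDS. Parental pool
frequencies are estimated from baseline populations with an additive
pseudocount (default 0.5 per allele, a Jeffreys-style shrinkage that keeps
likelihoods finite when a baseline is fixed); the per-category likelihood
of an individual multiplies, over called loci, the mixture
$\sum_w p_w \, P(g \mid w)$ with the origin-pair kernels

* NN: Hardy-Weinberg at the northern frequency,
* SS: Hardy-Weinberg at the southern frequency,
* NS: one copy per pool, so P(het) = p~N~(1−p~S~) + (1−p~N~)p~S~.

The prior over categories is uniform (no population prior is assumed);
the posterior is the normalised prior × likelihood. Individuals with no
called loci are flagged unclassifiable rather than silently dropped.
Replacing the full MCMC over frequencies and mixing proportions with a
plug-in estimate makes the classifier deterministic and unit-testable; the
companion `classifyHybridsGibbs()` samples the pool frequencies from their
Beta posteriors to propagate baseline uncertainty and attach credible
intervals, and agrees with the plug-in on clear-cut cases.

Identifiability has a sharp structure worth knowing: F1 and F2 share the
same expected admixture proportion (½) and every F1 genotype also occurs
in F2, so F1 is separated only by the *absence* of recombinant homozygous
genotypes across many loci, while F2 is separated by their presence. On a
fully diagnostic 96-locus panel the model places the mean posterior
confidence of correct F2 assignment near 0.94 (computed in the tests);
parental individuals are assigned with posterior ≈ 1, and simulated F1
never fall into parental or backcross classes. The
`powerSimulation()` harness reproduces this blind-reassignment study at
10,000 individuals per category (120,000 total), with baselines simulated
independently of the queries to keep the reassignment honest.

# Diversity and differentiation

Observed heterozygosity is the fraction of called heterozygotes averaged
over loci; expected heterozygosity uses Nei's unbiased correction
2n/(2n−1); allelic richness uses hypergeometric rarefaction to a common
number of gene copies g (default: twice the smallest per-locus called
sample), which removes the sample-size dependence of allele counts.
Across-population comparisons use one-way ANOVA on per-locus values — the
locus is the observational unit, which reproduces the "no statistical
differences among samples" behaviour expected for homogeneous panels.

Pairwise F~ST~ is the two-population Weir–Cockerham θ with per-locus
variance components combined as a ratio of sums (the multilocus estimator
Arlequin reports). The estimator is unbounded below and negative estimates
are reported as computed, not truncated — weakly differentiated samples
legitimately produce small negative θ. Significance comes from permuting
individuals between the two samples, with p = (1 + #{θ\* ≥ θ})/(n~perm~+1)
and a default of 10,000 permutations. The temporal-pooling rule applies
this test within each location sampled in two years and pools the years
iff p ≥ α (default 0.05); locations that fail are split into year-suffixed
populations so downstream stages treat them separately.

# Structure inference

PCA follows the smartPCA convention: genotype columns centred at 2p̂ and
scaled by √(p̂(1−p̂)); missing entries are imputed to the post-centring
mean (0) for this stage only. Axis significance uses the sequential
Tracy–Widom procedure: an effective marker count
n′ = (m+1)(Σλ)² / ((m−1)Σλ² − (Σλ)²) is estimated from the remaining
spectrum, the normalised leading eigenvalue is centred/scaled with the
(m, n′) Tracy–Widom moments, and testing proceeds down the spectrum until
the first non-significant axis (α = 0.05). Tail probabilities of the
TW(1) distribution are evaluated with the Chiani shifted-gamma
approximation, whose error on the p scale (below 10⁻³ in the working
range: it reproduces the published 0.05/0.01/0.001 quantiles 0.9793,
2.0234, 3.2724 as 0.979, 2.014, 3.247) is far below the 0.05 decision
threshold; this avoids shipping and interpolating a quantile table. Two caveats are
documented rather than patched: the test is mildly conservative for later
axes, and it loses power in the degenerate regime where one axis carries
nearly all variance (the tested eigenvalue then dominates its own
null-spectrum estimate); at realistic differentiation — a leading axis
explaining ~15–30% of variance — detection is essentially certain, as the
acceptance tests measure. Fully diagnostic two-cluster panels are rank-1
after centring and have no null spectrum at all; `pcaPanel()` then returns
the decomposition with `tw = NULL`.

Admixture proportions are estimated by maximising the binomial admixture
likelihood g~il~ ~ Binomial(2, Σ~k~ q~ik~ f~kl~) with an EM algorithm
(missing loci marginalised, i.e. skipped). The log-likelihood is
non-decreasing by construction and asserted so in tests. Numerical
choices: frequencies clamped to [10⁻⁹, 1−10⁻⁹]; random uniform
initialisation of q and f per replicate seed; convergence when the
log-likelihood gain drops below 10⁻⁶ (the acceptance run relaxes this to
10⁻⁵ with a 600-iteration cap to keep fifty replicate fits fast);
non-convergence flags the result instead of raising. This replaces the
Bayesian MCMC with correlated allele frequencies used by STRUCTURE: the
decision surface (K, per-individual q) is the same, runs are reproducible
from seeds, and ten replicate fits per K stand in for independent MCMC
runs. The correlated-frequency prior is intentionally out of scope.

Model choice uses Evanno's ΔK = mean(|L(K+1) − 2L(K) + L(K−1)|)/SD(L(K))
across replicates, defined for interior K only; a zero replicate SD is an
error (the statistic is undefined), and label switching across replicates
is resolved by the best column permutation against the first replicate.
Because EM likelihoods vary across replicates far less than MCMC ones,
ΔK contrasts are sharp; the two-lineage acceptance panel selects K = 2
decisively. An individual's "admixture proportion" is summarised as its
minor-cluster ancestry 1 − max~k~(q~ik~), with 10% as the default
admixed/non-admixed threshold.

# Introgression

The ABBA-BABA implementation is frequency-weighted: per locus, with
derived frequencies p₁, p₂, p₃, p~O~ (derived = the allele that is *not*
the outgroup major allele; loci without outgroup calls are dropped, and a
polymorphic outgroup is flagged), abba = (1−p₁)p₂p₃(1−p~O~) and
baba = p₁(1−p₂)p₃(1−p~O~). These weighted "counts" are non-integers by
construction. D = Σ(abba−baba)/Σ(abba+baba); both raw sums and per-locus
means are reported since different tools rescale differently. The variance
of D comes from a delete-one-locus jackknife (block = 1 locus is
appropriate for unlinked array SNPs; a `block_size` argument exists for
linked data), Z = D/SE with a two-sided normal p. Degenerate inputs are
explicit: identical blocks give SE = 0 and an undefined p with a flag, and
fewer than three informative blocks is an error in the jackknife (the
D point estimate is still returned). Antisymmetry under P1↔P2 swap and
invariance to monomorphic padding are asserted in tests.

# The synthetic-data generator

`makeLineageFrequencies()` draws per-locus differentials uniformly from
[δ, 1] and places the southern pool at the higher B-allele frequency; the
defaults are 96 loci and δ = 0.9, an idealisation of a curated diagnostic
array (a panel screened to near-fixed differences), and δ = 1 gives the
fully diagnostic boundary case used by the power study. Parental genotypes
are Binomial(2, pool frequency) — Hardy–Weinberg and linkage equilibrium
within lineages — and hybrid categories are sampled from their origin-pair
triples. Missingness is independent per entry (default 0). Simulation
scales follow the study design they emulate: 10,000 individuals per
category × 12 categories for marker power; 1,000 loci and 20 diploids per
population × 200 replicates for the null-D study; these sizes are also
what the acceptance script re-runs.

What the generator does *not* emulate — and hence what passing tests do
not certify about field data: linkage between loci; genotyping error and
allele dropout (missingness is random, not genotype-dependent); parental
frequency drift between the baseline sample and the hybrid zone;
within-lineage substructure; selection against particular hybrid
genotypes; and frequency uncertainty is not propagated through the
simulator (frequencies are treated as truth there — the classifier deals
with uncertainty separately via the pseudocount and the Gibbs variant).

# Defaults worth knowing

| parameter | default | where | rationale |
|---|---|---|---|
| `diagnosticity` | 0.9 | generator | curated diagnostic panel; 1 = fully diagnostic |
| `pseudocount` | 0.5 | classifier | Jeffreys-style shrinkage of baseline frequencies |
| prior over categories | uniform | classifier | no population prior assumed |
| `n_perm` | 10,000 | F~ST~ tests | p resolution 10⁻⁴, Arlequin-like |
| pooling α | 0.05 | temporal pooling | conventional test level |
| `threshold` | 0.10 | admixture summary | admixed = minor ancestry > 10% |
| confidence threshold | 0.9 | power report | "high confidence" convention |
| TW α | 0.05 | PCA axes | conventional; sequential stop |
| jackknife block | 1 locus | D statistic | unlinked array SNPs |

# Limitations

Real-study quantities that depend on the deposited empirical genotypes
(pairwise θ between named sampling sites, PCA variance fractions,
site-specific hybrid compositions, the exact confidence percentages of the
original power study) require those data; everything this package's tests
and acceptance script report is computed from its own simulators and
printed toy examples. The classifier assumes the twelve-category universe
and two parental pools; the admixture model assumes unlinked loci and no
inbreeding; the D statistic assumes the (((P1,P2),P3),O) topology and a
mostly ancestral outgroup.
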