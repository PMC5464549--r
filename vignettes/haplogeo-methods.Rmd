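---
title: "HaploGeo: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HaploGeo: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

HaploGeo implements the standard analysis chain for haploid
(mitochondrial) phylogeography: within-sample diversity, hierarchical
AMOVA, pairwise FST and gene flow, isolation by distance, median-joining
networks, and expansion-oriented historical demography, together with a
structured-coalescent generator that produces study-scale synthetic data.
This vignette records the statistical models behind each stage, the
numerical choices, and the places where the design was genuinely open.

## Data model and distances

A `HaploAlignment` holds equal-length sequences over the alphabet
A/C/G/T/N/`-` with one metadata row per sequence (`sample_id`,
`location`, `area`, optional coordinates). The metadata is the single
source of the location-to-area mapping, and each location must belong to
exactly one area.

All comparisons use **pairwise deletion**: a site contributes to a pair
only when both sequences carry an unambiguous base, so an N or a gap
masks that site for that pair alone. Programs differ here (complete
versus pairwise deletion), which is why the choice is fixed, documented,
and recorded in the pipeline provenance log. Haplotype identity is exact
string equality after uppercasing — sequences containing N collapse only
with identical strings, matching the granularity of deposited haplotype
sets and keeping the operation deterministic.

## Diversity

Haplotype diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with his sampling
variance
$V(h) = \frac{2}{n(n-1)}\Bigl\{2(n-2)\bigl[\sum p_i^3 - (\sum p_i^2)^2\bigr]
+ \sum p_i^2 - (\sum p_i^2)^2\Bigr\}$.

Nucleotide diversity is the mean over unordered pairs of the per-pair
proportion of differing sites. Its default standard deviation is the
no-recombination **total** variance (stochastic plus sampling),
$V(\pi) = \frac{n+1}{3(n-1)}\frac{\pi}{L}
+ \frac{2(n^2+n+3)}{9n(n-1)}\pi^2$, the convention most sequence-analysis
programs report. Because closed-form *sampling-only* variances differ
between textbook editions, the alternative offered here is a
nonparametric bootstrap over sequences (`varMethod = "bootstrap"`)
rather than a second formula.

Pooled per-area rows of `diversityTable()` are computed on the
concatenated samples, never by averaging location values. Reported
precision follows the field's convention: *h* to 3 decimals, π to 4.

## AMOVA

`amova()` is the Excoffier–Smouse–Quattro nested analysis of molecular
variance on squared distances, with the pairwise nucleotide-difference
count taken as the squared Euclidean distance between haploid sequences
(the haplotypic-data convention). Sums of squares come from block sums of
the distance matrix (SS = Σd²/n within blocks); variance components are
solved from the expected mean squares with the unequal-sample-size
coefficients

* n′ = (N − Σ_g Σ_{p∈g} n_p²/n_g)/(P − G),
* n″ = (Σ_g Σ_{p∈g} n_p²/n_g − Σ_p n_p²/N)/(G − 1),
* n‴ = (N − Σ_g n_g²/N)/(G − 1),

giving Φ_CT = σ²_a/σ²_T, Φ_SC = σ²_b/(σ²_b+σ²_c),
Φ_ST = (σ²_a+σ²_b)/σ²_T. Negative component estimates are reported as
computed. Degenerate designs (a single area; no replicate locations
within areas; zero total variance) yield warnings or NA Φ rather than
silent output.

Permutation schemes follow the hierarchy: Φ_ST permutes individuals
among locations over the whole data set, Φ_SC permutes individuals among
locations within their area, Φ_CT permutes whole locations among areas.
All permutation p-values use the (+1)/(n+1) correction; the default is
10000 permutations, and every stochastic entry point takes an explicit
seed. Note the resolution limit of the Φ_CT scheme: with few locations
the number of distinct location-to-area partitions bounds the smallest
attainable p.

## FST, gene flow, isolation by distance

Pairwise divergence defaults to Hudson/Slatkin's
FST = 1 − H_w/H_b (mean within-group pairwise differences, averaged over
the two groups, against the mean between-group difference). This
estimator is the one whose haploid island-model inverse
Nm = (1 − FST)/(2 FST) reproduces published divergence/gene-flow pairs
exactly; it is therefore the default, with the AMOVA-based Φ_ST
(`estimator = "phi"`, accepted alias `"weir"`) as the alternative — the
two are exposed because reference programs disagree on which one feeds
the IBD analysis. Negative FST estimates are kept as computed and
clamped only for the Nm conversion (FST ≤ 0 maps to infinite gene flow
with a warning).

`mantelTest()` uses Z = Σ_{i<j} X_ij Y_ij with random label permutations
of one matrix, or exhaustive enumeration of all n! permutations for
n ≤ 7. Geographic distances are user-supplied when available (over-water
distances cannot be reconstructed from coordinates); the built-in
fallback is the Haversine great-circle distance in kilometres and is
labelled as such in output.

## Median-joining networks

`medianJoiningNetwork()` follows the Bandelt–Forster–Röhl scheme:
iterate the minimum-spanning network at tolerance ε (default 0) with the
addition of median vectors, until closure. A link (u,v) is feasible when
d(u,v) ≤ minimax(u,v) + ε, the minimax path distance coming from a
Kruskal MST whose ties are broken by lexicographic sequence order, so
the network is deterministic and invariant to input order. Median
vectors are computed site-wise by majority over triplets (u,v,w) in
which v links both u and w in the current network; site ties resolve
toward the lexicographically first member. Among new medians only those
with minimal connection cost (≤ λ + ε) are added per round. After
convergence, median vectors of degree ≤ 1 are pruned. The export is an
edge list in mutational steps plus a node table; no layout is computed.

`subnetworkSeparation()` reports, per group pair, the minimum path
weight between groups with intra-group edges costing zero; groups may
overlap (a haplotype observed in both groups makes the separation zero).
Exact step counts between published sub-networks depend on the original
software's internal ε and post-processing, so the package asserts the
recovery of discrete sub-networks rather than byte-identical step
counts.

## Historical demography

The observed mismatch distribution is the histogram of all n(n−1)/2
pairwise difference counts, computed on individual sequences pooled by
area (not on haplotypes). The sudden-expansion model gives the expected
distribution: with equilibrium
$\hat F_j(\theta) = \theta^j/(\theta+1)^{j+1}$ and a = (θ₁+1)/θ₁,

$$F_j(\tau,\theta_0,\theta_1) = \hat F_j(\theta_1)\,P(j+1, a\tau)
  + e^{-a\tau} \sum_{k=0}^{j} \frac{\tau^k}{k!}\hat F_{j-k}(\theta_0),$$

where P is the regularized lower incomplete gamma function. The vector
is truncated at the largest observed class and renormalized, with the
truncated mass recorded. Two limits pin the implementation down and are
unit-tested: τ → 0 recovers the *pre-expansion* equilibrium
$\hat F(\theta_0)$, and θ₀ = θ₁ gives the equilibrium for every τ.

`fitExpansion()` minimizes the sum of squared deviations between
observed and model frequencies by bounded L-BFGS-B from 20 starts (one
moment-based, the rest random; bounds τ ∈ [0, max(4·mean, 20)],
θ₀ ∈ [0, 100], θ₁ ∈ [0, 10⁵]). The SSD p-value is a parametric
bootstrap: B samples of size n are simulated under the fitted expansion
(coalescent with expansion time τ/θ₁ and growth factor θ₁/θ₀ in units of
the present size), each refitted (with the parent fit as one start), and
p = (#{SSD_sim ≥ SSD_obs}+1)/(B+1). Bootstrap histograms are pooled into
the observed class range so that refit cost stays bounded when θ₁ runs
to its upper bound. Harpending's raggedness
r = Σ_{i=1}^{d+1}(x_i − x_{i-1})² (boundary term x_{d+1} = 0; the
convention is unit-tested because program editions differ) is tested
against the same bootstrap null — a pragmatic choice, since reference
programs do not document whether their r test shares the SSD bootstrap
or uses separate coalescent simulations. B defaults to 1000
(configurable; reference software often uses 10000).

Fu's F_S uses θ̂ = mean pairwise differences (Fu's original choice, not
Watterson's θ), k = number of distinct sequences, and
S′ = Pr(K ≥ k | θ̂, n) under the Ewens sampling distribution
Pr(K = k) = |s(n,k)| θ^k / θ_{(n)}, computed in log space from the
unsigned-Stirling-number recurrence; F_S = ln(S′/(1−S′)), with k = 1
guarded as a flagged boundary. Significance comes from neutral
constant-size coalescent simulations conditioned on θ̂ (the common
program convention; conditioning on S is a possible alternative that is
deliberately not the default), with
p = fraction of simulations with F_S ≤ F_S,obs.

## The synthetic-data generator

`simulateGenealogy()` is a haploid n-island structured coalescent:
demes of equal present size nested in areas, exponential waiting times,
per-lineage emigration rate mig/2 (destination uniform among eligible
demes) with separate within-area and between-area rates on the Nm scale
— for two demes Hudson's FST equals 1/(1 + 2 Nm) exactly, matching the
package's gene-flow identity. Looking backwards, coalescence is
`growthFactor` times faster before `expansionTime` (a sudden expansion),
and at `mergeTime` all demes collapse into one ancestral deme; a finite
merge time is required when isolated areas are sampled, otherwise the
between-area TMRCA would be infinite.

`mutateSequences()` scatters Poisson(θ/2 × branch length) mutation
events over the non-invariant sites (a fixed fraction `pInv` of sites is
invariant), drawing the root from the HKY stationary frequencies and
each mutation's target base with probability proportional to the HKY
rates away from the current base — multiple hits are allowed, so the
number of polymorphic sites stays below the locus length as in real
protein-coding mtDNA. An infinite-sites mode (every mutation its own
site) exists for analytic checks such as Watterson's E[S].

The default scenario (`defaultSimConfig()`) emulates a 13-location,
three-area, 312-sequence, 537-bp COI study: per-deme sample sizes 18–29,
HKY frequencies (0.227, 0.166, 0.187, 0.420), and — chosen once to place
the synthetic data in the empirically observed regime of high haplotype
but low nucleotide diversity with dominant among-area divergence —
θ = 6 per locus, within-area Nm = 10, between-area migration 0 with a
merge at 4 coalescent units, expansion at 0.6 units with factor 150,
κ = 5 and pInv = 0.7 (κ and pInv are field-typical values for
protein-coding mtDNA since only the model family and base frequencies
are published for such data sets). Under this scenario within-location
h falls in ≈0.70–0.98, within-location π in ≈0.003–0.018, about 120–130
haplotypes arise with no sharing between areas, among-area variance
exceeds 60% with Φ_CT ≈ 0.75, and genealogies are star-like within
areas. What the generator deliberately does not emulate: recombination
(none in mtDNA), selection, sequencing error, and the geography itself —
coordinates in simulated metadata are a synthetic grid, which is why the
Mantel stage treats geographic distances as user input with a labelled
great-circle fallback. Passing tests on synthetic data therefore
demonstrates correctness of the estimators and calibration of the tests
under the island-model assumptions, not robustness to artefacts real
data may carry.

## Determinism, sizes and limits

Every stochastic entry point accepts a seed, and `simulateStudy()` is
byte-reproducible from its config seed. The test suite uses reduced but
statistically meaningful problem sizes, chosen to keep the full run in
the tens of minutes: 500 panmictic replicates for the Φ_ST type-I error
envelope, 200 replicates for Mantel-p uniformity, 60 for the SSD
bootstrap null, 100 expansion simulations (n = 50, B = 60) for τ
recovery, and 10 seeded default-scenario data sets for the structure
regime. Known limitations: the AMOVA permutation floor with few
locations (above); the median-joining implementation targets data-set
sizes typical of single-locus studies (hundreds of haplotypes), not
genome-scale inputs; and the expansion fit's θ₁ is weakly identified
when the observed mismatch is consistent with a pure star genealogy, in
which case it runs to its bound without affecting τ — the reason
bootstrap histograms are pooled into the observed range. A related and
deeper caveat: because near τ = 0 the expected curve barely constrains
θ₁, least squares on a stationary sample often selects star-like
parameter sets whose bootstrap worlds carry much less genealogical
variance than the data-generating stationary coalescent, so the SSD
bootstrap test is measurably anti-conservative under a stationary
single-locus null at small n (the suite's calibration checks quantify
this); its p-values should be read with that in mind, and Fu's F_S —
whose coalescent null is exact — is the more reliable expansion test
here, as it is in practice.
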