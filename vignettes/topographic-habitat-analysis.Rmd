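---
title: "Methods: topographic habitat association for soil microbiome counts"
author: "topomicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topographic habitat association for soil microbiome counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomicro)
```

`topomicro` analyses quadrat × OTU amplicon count tables sampled on a
gridded forest plot that spans terrain habitats (valley, mid-slope,
ridge). This vignette is the package's account of the statistical
methods: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## The torus-translation habitat test

### Model and null

The central question is whether an OTU is over- or under-represented in
a terrain habitat relative to what its spatial distribution would give by
chance. Naive permutation of habitat labels across quadrats destroys the
spatial autocorrelation of both the species field and the habitat map and
badly inflates false positives for spatially aggregated taxa. The
torus-translation null instead moves the *entire habitat raster* rigidly
around the grid, treated as a torus: every translation of the R × C
raster, each also in its column-mirrored, 180°-rotated and
mirrored-rotated form, giving exactly 4·R·C candidate maps including the
identity. Each map preserves the habitat label multiset and the internal
spatial structure of both layers; only their alignment changes.

The test statistic for OTU *i* and habitat *h* is the mean per-quadrat
relative abundance

$$S_{ih} = \frac{1}{|Q_h|} \sum_{q \in Q_h} \frac{x_{qi}}{\sum_j x_{qj}},$$

i.e. counts are normalized within each quadrat before averaging, so
quadrats with unequal sequencing depth contribute equally. This mirrors
the relative-density statistic of the classical plant-ecology torus test
while respecting the compositional nature of sequencing data.

With $p^{+}_{ih}$ the share of null maps whose statistic is at least the
observed one and $p^{-}_{ih}$ the opposite tail, classification uses two
one-sided tests at $\alpha/2$ each (default $\alpha = 0.05$): *positive*
if $p^{+} \le \alpha/2$, *negative* if $p^{-} \le \alpha/2$, otherwise
*neutral*. Both tails cannot fire at once because the observed map is a
member of the null set, which also guarantees $p^{+}, p^{-} \ge 1/(4RC)$
— no p-value is ever zero. Ties ($S_\text{null} = S_\text{obs}$) count
toward both tails, the conservative convention.

### Rare-taxon filter

OTUs whose overall mean per-quadrat relative abundance is below
`minRelAbund` (default $10^{-4}$, i.e. 0.01%) are set aside as
*filtered* before testing: with a handful of reads spread over a few
quadrats, the statistic is dominated by sampling noise and the discrete
tie structure below makes small p-values unreachable anyway. Association
summaries always print their denominators (total, tested, filtered OTU
counts) because percentages of "associated OTUs" are meaningless without
them.

### Properties and limitations of the torus null

Three behaviours of the method are worth knowing; the test suite and
`scripts/acceptance.R` measure all of them on simulated designs.

**Tie-induced conservativeness on sparse taxa.** For an OTU present in
only a few quadrats, many torus maps select exactly the same subset of
its occupied quadrats, so their null statistics tie exactly with the
observed one; with ties counted in both tails, both p-values inflate.
On dense, exchangeable fields the type-I rate is very close to nominal;
on realistic sparse tables the non-neutral call rate falls somewhat below
$\alpha$. We keep the conservative tie rule — a deliberate trade of power
for validity.

**Band geometry limits resolution.** Habitats assigned along an
elevation gradient form near-parallel bands. Torus maps that shift along
the band direction (or mirror across it) move few quadrats of a given
habitat, so a sizeable fraction of the 4·R·C maps nearly reproduce the
observed overlap; the effective size of the null set is smaller than its
nominal count, which costs power, and the cost depends on how ragged the
band edges are. Relatedly, *negative* association with a habitat whose
band never overlaps the OTU's home band under many translations is hard
to establish: the null statistics tie at zero. These are properties of
the torus design itself, not of the implementation; detection of
positive (home-habitat) association is affected far less.

**Non-grid designs.** The torus group needs a complete rectangular grid.
When the samples do not form one, the package falls back to
`fallbackNPerm` seeded random permutations of the habitat labels
(observed labelling included). This fallback does *not* preserve habitat
spatial structure and is anti-conservative for strongly autocorrelated
taxa; it is a pragmatic second choice, clearly recorded in the result's
`nullType`.

## SparCC correlation networks

Relative abundances are compositional: correlations computed on them are
distorted by the closure. SparCC estimates correlations among the latent
*basis* abundances from the log-ratio variation matrix
$T_{ij} = \mathrm{Var}\,\log(x_i/x_j)$, using the decomposition
$T_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$ and
the sparsity approximation that most $\rho_{ij} \approx 0$, which turns
the row sums of $T$ into a linear system for the basis variances
$\omega$. Strongly correlated pairs violate the approximation, so the
strongest pair above `exclusionThresh` (default 0.1) is excluded and the
system re-solved, up to `xIter` (default 10) rounds; a pair is never
excluded if that would leave a component attached to fewer than two
partners, and estimated variances are floored at $10^{-12}$ before the
square root. Sampling noise in the fractions is handled by `nEst`
(default 20) Dirichlet resamples with unit pseudocounts, aggregated by
the component-wise median — the median, not the mean, because the
iterative exclusion makes individual estimates occasionally unstable.
Correlations are clipped to $[-1, 1]$.

Edge significance uses the original SparCC bootstrap idea: each OTU's
counts are permuted independently across samples, destroying all
between-OTU association while keeping marginals; the two-sided pseudo
p-value $(1 + \#\{|r_\text{null}| \ge |r_\text{obs}|\})/(1 + n_\text{perm})$
is bounded below by $1/(n_\text{perm}+1)$, so `nPerm = 100` is the
minimum for the default `pThresh = 0.01` to be attainable (a warning is
raised below 99). Edges keep pairs with $|r| > 0.7$ and $p < 0.01$, the
conventional strong-and-significant thresholds for these networks.

Module detection runs seeded Louvain on $|r|$ edge weights — the sign is
kept separately — and reports Newman weighted modularity Q. The "network
stability" of the ecological literature is reported purely descriptively
as the proportion and mean strength of positive edges within and between
modules (communities held together mainly by strong positive
correlations are read as less stable); no dynamical stability model is
fitted. Ten quadrats per habitat is very small for SparCC, so
per-habitat inference warns whenever fewer than 20 samples back an
estimate.

## Community structure and environmental drivers

*Richness* is the number of OTUs with count > 0 per quadrat, computed on
raw counts (rarefaction is reported separately; the simulator's equal
depths keep the contrast comparable). The habitat contrast is the
tie-corrected Kruskal–Wallis test; when every richness value is
identical the tie-correction denominator vanishes and H is defined as 0
with p = 1. A one-way ANOVA on the same values is reported alongside,
since both contrasts are conventional here; Kruskal–Wallis is the
default because richness counts are bounded, skewed and
heteroscedastic.

*Venn partitions* call an OTU present in a habitat when its summed count
there is positive; an optional minimum-relative-abundance presence
threshold exists but defaults to off, because presence/absence is the
convention and any threshold choice is arbitrary. Percentages are
rounded to two decimals for reporting.

*NMDS* minimizes Kruskal stress-1 with monotone (isotonic) regression,
primary tie treatment, via `vegan::monoMDS`. Start 1 is the classical
metric-scaling configuration — on metric-compatible input it already
sits at the optimum — and the remaining `nStarts − 1` starts are seeded
random; the best stress is returned, so more starts can never report a
worse configuration under the same seed.

*Rarefaction* uses the closed-form hypergeometric expectation
$E[S_d] = \sum_i [1 - \binom{N-N_i}{d}/\binom{N}{d}]$, which is exact and
monotone in depth; depths above any sample total are an error rather
than an extrapolation.

*Ternary enrichment* coordinates are the per-habitat mean relative
abundances normalized to sum to one; the assigned habitat is the argmax,
with ties broken in the fixed order valley, midslope, ridge; OTUs absent
everywhere are flagged and excluded rather than given arbitrary
coordinates.

*Environmental vector fitting* regresses each covariate on the
ordination axes; R² is the coefficient of determination and significance
comes from permuting the covariate's raw values across samples (the
classical procedure when there are no covariables), with the +1
pseudo-count correction. R² is invariant under rigid rotation of the
ordination. Constant covariates get R² = 0, p = 1 and a flag. The
implementation is the package's own (a QR projection vectorized over all
permutations); `vegan::envfit` serves as an independent cross-check in
the test suite rather than as the implementation.

*RDA* projects the column-centered community matrix onto the
environmental space and reports the constrained variance proportion and
axis eigenvalues via `vegan::rda`. The Hellinger transform is applied by
default — the standard choice that makes Euclidean RDA geometry sensible
for species abundances — with `transform = "none"` available. Collinear
environmental columns are detected by QR rank before fitting and raise
an error naming the dependent columns, rather than being silently
aliased.

## The synthetic study-design generator

The generator emulates the field design the package targets: a
contiguous `nRows × nCols` grid of square quadrats (default 5 × 6 of
20 m, i.e. 30 quadrats) with a smooth monotone elevation gradient plus
seeded noise; habitats assigned by elevation terciles (lowest third
valley, then midslope, then ridge, sizes differing by at most one),
which yields the contiguous-ish habitat bands a real mountainside
produces while staying reproducible. Whether a real 30-quadrat survey
forms one contiguous grid or three separate clusters is a design
question the generator resolves in favour of one grid, since that is
what the torus null requires; the permutation fallback covers the other
reading.

Counts are Dirichlet-multinomial. Expected log abundances are a
log-normal rank-abundance baseline (SD 1.5, a typical microbiome shape)
plus `effectLogFold` (default log 8) for specialist OTUs inside their
habitat, plus a Gaussian field with exponential spatial kernel (range
two quadrat widths, marginal SD 0.5) independent across OTUs; the
per-quadrat softmax of these gives expected relative abundances, a
Dirichlet draw with precision `1/overdispersion` (default precision 200)
adds per-sample overdispersion, and a multinomial at `depth` (default
10⁴) produces counts. A ground-truth table records each specialist's
habitat and effect, enabling parameter-recovery tests. One master seed
drives deterministic sub-streams per stage, so stages can be regenerated
independently and tables are reproducible bit-for-bit.

What the generator does *not* emulate: taxonomy and phylogeny,
chimeras/sequencing error (tables are downstream of OTU clustering by
assumption), unequal sequencing depth, zero-inflation beyond what the
Dirichlet-multinomial induces, between-OTU ecological interactions
(fields are independent given the habitat structure), and the real
plot's elevations. Passing tests therefore show that the methods behave
correctly under a faithful *abstraction* of such data, not that any
particular field result is reproduced.

Two consequences of the defaults are worth stating plainly, because the
calibration and recovery simulations in `scripts/acceptance.R` measure
them. At Dirichlet precision 200, a low-abundance OTU's expected
relative abundance fluctuates severalfold between quadrats; this is
realistic for amplicon data but it costs the torus test real power on
rare specialists, and together with the tie effects above it keeps
measured specialist recovery below, and the null non-neutral rate
somewhat below, their idealized values. Turning overdispersion off
(`overdispersion = 1e-4`) restores near-complete recovery, which is how
the test suite separates method behaviour from data noise.

## Numerical choices

- Tie comparisons in the torus test use an absolute tolerance of
  $10^{-12}$ so that identical subset sums evaluated in different
  summation orders still tie.
- The observed map/labelling is always a member of the null set (torus
  and permutation nulls alike), bounding p-values away from zero.
- `alpha/2 < 1/(4RC)` (grid too small for any non-neutral call) raises a
  warning rather than an error.
- SparCC basis variances are floored at $10^{-12}$; degenerate Dirichlet
  draws fall back to the expected fractions.
- Louvain and every other stochastic step take an explicit seed;
  identical seeds give bit-identical results, including the pipeline's
  JSON report.
- Reported percentages are rounded to two decimals; all underlying
  values are kept at full precision in the returned objects.

## Problem sizes used in the tests

The suite exercises the study-scale design (30 quadrats, 300 OTUs,
depth 10⁴) for the torus test; 50 samples × 20 OTUs for SparCC recovery
and null behaviour with 100-permutation significance; 500 replicate
vector fits at 199 permutations for envfit calibration; and 10⁴
Monte-Carlo subsamples for the rarefaction cross-check. These sizes give
Monte-Carlo errors comfortably inside the asserted tolerances while
keeping the default test run quick.
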