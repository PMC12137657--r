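---
title: "Reconstructing a multi-source invasion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a multi-source invasion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spreadgen reconstructs the history of a spreading invasive population
from two complementary data streams: dated, verified point occurrence
records (typically citizen-science observations) and genome-wide
biallelic SNP genotypes sampled across localities. The motivating
system is a pond-breeding amphibian invading a river valley from
several introduction points, with a canal acting as a dispersal
barrier — but every stage is generic. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## Geographic profiling

Occurrence locations are modelled as i.i.d. draws from a mixture over
an unknown number of sources $k$: each record is bivariate normal
$N(\mu_k, \sigma^2 I)$ around its source, with a single shared
dispersal scale $\sigma$. The partition of records over sources follows
a Chinese restaurant process (a Dirichlet-process mixture), so the
number of occupied sources is inferred rather than fixed. Priors:

* $\mu_k$ uniform on the record bounding box expanded by a 10 km guard
  band (`guard_km`), so sources just outside the sampled extent remain
  admissible;
* $\sigma^2$ inverse-gamma. The user-facing prior is stated on
  $\sigma$ in km: `sigma_prior(mean_km = 5, variance_km2 = 10,
  shape = 1.5)`. The triple is over-determined; the implementation
  honours the mean and the shape and reports the achieved variance
  (14.27 km² here) with a warning rather than silently substituting.
  For a 12-year colonisation window a 5 km mean corresponds to most
  dispersal staying within 5/10/15 km of a source (the one-dimensional
  68/95/99% normal quantile convention);
* CRP concentration $\alpha = 1$ (exposed as `alpha` for sensitivity
  analysis).

The Gibbs sweep reallocates each record by CRP weight times likelihood,
using Neal's auxiliary-component device (`m_aux = 3` fresh uniform
centres per sweep) because the uniform centre prior is non-conjugate
for opening components; updates each occupied centre from its normal
posterior truncated to the frame (rejection with a clamping fallback);
and updates the shared $\sigma^2$ from its conjugate inverse-gamma
posterior pooling all records. The sampler is written in C++ and uses
R's RNG, so `set.seed()` gives bit-for-bit reproducibility; multiple
chains run from one seeded stream and convergence is summarised by the
Gelman–Rubin statistic on the $\sigma$ chains
($\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$; note that for literally
identical chains this formula gives $\sqrt{(n-1)/n}$, not exactly 1).

The reported surface is the posterior predictive source-location mass:
per sample, each occupied centre contributes $n_k/(n+\alpha)$ to its
cell and $\alpha/(n+\alpha)$ is spread uniformly for unseen sources.
The **hit score** of a cell is the fraction of the study area with
strictly higher posterior density plus half the ties — the proportion
of area to search before reaching that cell; tie-averaging makes the
uniform surface score 0.5 everywhere. The source count is reported as
the posterior mode of the number of occupied components, always
alongside the full posterior, because any single decision rule on a
DPM component count is fragile: the DPM posterior over the number of
components is not consistent under model misspecification, and a
multi-generation invasion cloud (dispersal compounding over years) is
genuinely not a normal mixture. This is why the shipped recovery
experiments use young (one-to-two-year) invasion pulses, where sources
are identifiable; on old diffuse invasions the profiler reports its
uncertainty honestly rather than hitting the simulated truth.

Before profiling, records are thinned exactly as a practitioner would:
records after the cutoff year are dropped (post-ban observations are
assumed to reflect natural dispersal), remaining records are clustered
by single linkage at the deduplication radius (200 m default), and only
the earliest record per cluster is kept, ties broken by smallest id.

## Occupancy and expansion speed

The extent of occupancy (EOO) for year $y$ buffers every record
observed up to $y$ by 1 km (colonised ponds are assumed to stay
occupied, so the series is cumulative) and reports the area of the
union of discs. The union area is computed exactly with circular-arc
geometry: by Green's theorem the union area equals the line integral
over the exposed boundary arcs, so each disc's boundary is reduced to
the angular intervals not covered by any other disc. This is a
deliberate departure from polygonal approximation of the circles — it
removes the only approximation in the stage — and a Monte-Carlo
rejection-sampling oracle in the tests bounds agreement to well under
0.5%.

The expansion-speed formula in the source literature,
$E = \sqrt{C/\pi}$, maps an area to an equivalent-circle radius but is
ambiguous about whether $C$ is the cumulative extent or its yearly
increase. Both readings are computed: `radius-difference`
($E_y = r_y - r_{y-1}$, the advance of an equivalent circular front)
is the default because it is the only reading dimensionally consistent
with a steadily expanding front; `increment-radius`
($E_y = \sqrt{\Delta C_y/\pi}$) is reported alongside. The two agree on
a colonisation from nothing to area $\pi$ (both give 1 km/yr).

## Diversity, structure and differentiation

Per locality (after full-sib filtering, below): per-locus observed
heterozygosity is the heterozygote fraction among non-missing calls;
expected heterozygosity uses the unbiased correction
$2p(1-p)\cdot 2n/(2n-1)$; locality values are means over loci, and
$F_{IS} = 1 - \sum H_o / \sum H_e$ over polymorphic loci (a ratio of
multilocus sums — monomorphic loci carry no information about
inbreeding and drop out). Localities with fewer than two genotyped
individuals carry no statistics, matching the treatment of the three
single-individual localities in the packaged reference table
(`table1_fixture()`).

Pairwise differentiation is Weir–Cockerham $\theta$ with the
ratio-of-sums multilocus combination; negative estimates are reported
as computed. Note a property that surprises on toy data: because of the
finite-sample correction, two literally identical small samples give a
markedly negative $\theta$ (e.g. $-1/3$ for duplicated three-individual
tables); $\theta$ is unbiased in expectation, not per realisation.

Admixture clustering is a STRUCTURE-style Gibbs sampler with
uncorrelated allele frequencies: Beta(1,1) priors on cluster
frequencies, a latent cluster label per allele copy, and
Dirichlet($\alpha=1$) admixture proportions. Replicate runs are
consolidated by exhaustive label alignment (maximising summed column
correlation over cluster permutations, $K \le 8$) and averaging. Model
choice uses the Evanno $\Delta K$ table; since $\Delta K$ cannot assess
$K=1$, a best $K>1$ is accepted only when it improves the mean
log-likelihood over $K=1$ by at least 1% of $|\ln L|$ — on panmictic
data the sampler otherwise has a mild tendency to overfit lumps.
Hierarchical application assigns a locality to a cluster when its
individuals' mean $q \ge 0.6$ and recurses into clusters with at least
two localities until the best $K$ is 1 or indeterminate. Desk-scale
MCMC sizes (hundreds of iterations, hundreds of loci) are the package
defaults for the shipped experiments; the field-scale settings
(10,000 burn-in / 100,000 iterations, $K$ up to 20, ten replicates) are
a `pipeline_config()` away.

PCoA mean-imputes missing calls with the locus mean allele value and
eigendecomposes double-centred Euclidean distances (base `cmdscale`).
AMOVA partitions squared Euclidean genotype distances into among- and
within-cluster components ($\Phi_{ST}$), with significance by permuting
individuals across clusters and the add-one convention so p is never 0.
Mantel tests correlate off-diagonal distances under simultaneous
row/column permutation; the statistic is cross-checked against vegan in
the tests, and its permutation p against exhaustive relabelling on
six-label toys.

## Kinship

Pairwise relatedness uses the similarity-category moment framework of
Wang's estimator. At a biallelic locus a pair falls in one of three
observable categories (identical genotypes; homozygote–heterozygote
sharing an allele; opposite homozygotes), whose expectations are linear
in the pair's one- and two-pair IBD coefficients $(\phi, \Delta)$ with
coefficients that are polynomials in the allele moments
$a_m = \sum_i p_i^m$. With two alleles the system is exactly
identified, so the estimator solves it per pair and reports
$r = \phi/2 + \Delta$. Allele moments are estimated from the full
sample with factorial-moment (small-sample) corrections and loci are
weighted by $1/(2a_2 - a_3)$, down-weighting near-fixed loci. Two
practical notes: parent–offspring pairs also estimate $r \approx 0.5$
(it is relatedness, not the IBD-class vector, that is estimated), and
when the reference frequencies come from the sample itself the mean
pairwise estimate within the sample centres near $-1/(n-1)$ rather
than 0 — the recovery experiments therefore pass the generator's true
frequencies, and `wang_relatedness(freq = )` exposes that mode.

Full-sib filtering removes, among same-locality pairs at or above
$r = 0.5$, one random member per qualifying pair until none remains
(seed-controlled, with a removal log); cross-locality pairs at
$r \ge 0.35$ are reported as kin edges — candidate recent dispersal
events — rather than filtered.

## Directional migration

For each ordered pair of localities a hypothetical pool with averaged
allele frequencies is formed; the directional rate into a locality
reflects that locality's closeness to the pool (a deme receiving many
migrants resembles the mixture). Differentiation from the pool is
summarised by Nei's $G_{ST}$ and Jost's $D$ jointly; each is converted
to a Wright-style migrant number $(1/x - 1)/4$ and the two are combined
by geometric mean — the published combination of the two statistics is
not reproducible in detail from the sources available here, and because
all rates are finally divided by the global maximum (so the largest
rate is 1), any monotone combination yields the same relative
structure. Immigration $I$, emigration $E$ and $R_{I/E} = I/E$
summarise each locality; clusters are compared by Mann–Whitney U
(exact by enumeration for combined $n \le 20$ without ties, otherwise
the tie-corrected normal approximation), and the source–sink question
is an ordinary least-squares fit of $R_{I/E}$ against distance to the
nearest inferred source with per-locality Cook's distances so
influential localities are identifiable before being dropped.

## Resistance and diversity surfaces

The isolation-by-distance trend between individuals is fitted as
genetic distance (Prevosti, on within-individual allele frequencies)
$= a + b \log(1 + \text{geographic distance})$ over pairs closer than
`d_max` (2/5/10 km scales); the log form is a single-transform monotone
concave choice — the original tool's exact functional form is unstated
— and is pluggable. Pair residuals, rescaled to $[-1, 1]$ by the
maximum absolute residual, are draped along the straight segment
between the pair members: each crossed cell (exact grid traversal,
validated against a supersampling oracle) averages the residuals of the
segments crossing it. Significance is empirical: each cell's mean is
compared with `n_resample = 1000` draws of the same number of residuals
from the pool without replacement, classifying cells as barriers (above
the $1-\alpha/2$ quantile), corridors (below $\alpha/2$), or neither —
a two-sided 2.5%-per-tail split, since the original tail convention is
not printed.

The diversity surface pools individuals within a window × window cell
block (10 × 10 default) around each cell and, controlling sampling
intensity by rarefaction, averages the mean individual heterozygosity
of 100 seeded draws of `rarefaction_n` individuals; cells below the
rarefaction size are nodata and are filled by ordinary kriging with an
exponential variogram fitted to the defined cells (zero nugget, so
defined cells are reproduced exactly; inverse-distance weighting is the
flagged fallback when the variogram fit fails). The association between
diversity and the geoprofile is a Pearson correlation of the two
surfaces extracted at the sampled localities: a significantly negative
correlation (diversity eroding away from sources) is the
serial-founder-effect signature; its absence is evidence for
long-distance dispersal or multiple introductions.

## The synthetic generator

The generator provides ground truth for every stage, emulating: several
point sources with staggered introduction years; per-year bivariate
normal dispersal with scale `sigma_true` plus a rare long-distance tail
(the same kernel scaled ×5 with probability `ldd_rate` — a stand-in for
flood-mediated transport, not an inference target); a barrier polyline
enforced by segment-intersection rejection (redraw on the same side);
imperfect detection (`detection_prob` per occupied point per year); two
founder allele-frequency pools at a Balding–Nichols target $F_{ST}$;
stepping-stone Wright–Fisher drift along the river axis (deme size
$N = 50$: stable frequencies, visible drift at desk scale) with reduced
exchange across the barrier; optional serial founder bottlenecks along
the chain; and clutch sampling, where clutch-mates share two parents
and are recorded as true full sibs. Everything is deterministic under a
seed.

It does **not** emulate: habitat heterogeneity or suitability,
observation effort gradients (detection is spatially uniform),
overlapping generations or stage structure, linkage, selection, or
coalescent-scale genealogies. Passing tests therefore demonstrate that
the estimators recover the processes the generator contains — drift,
divergence, barriers, founder clines, family structure — not that real
citizen-science or GBS data are free of the biases those missing
features create.

## Problem sizes and numerical choices

The shipped experiments are sized for a desk: profiling runs use
hundreds of MCMC iterations over 2–3 chains on tens-to-hundreds of
records (the field-scale 1000/10,000 × 5 chains remain the function
defaults); genotype experiments use 250–1000 loci and 8–40 individuals;
resistance nulls use 200–1000 resamples. Other numerical choices:
projection is local equirectangular about the record centroid (study
extents of tens of km make the distortion negligible against 1-km
buffers, and it keeps the math core dependency-free; raw coordinates
round-trip to < 1e-6 degrees within 100 km); rasters follow the ESRI
ASCII convention (lower-left origin, top row first) everywhere;
permutation p-values use the add-one convention; river networks fuse
polyline endpoints within 1 m and snap localities to the nearest point
without adding the snap offset to path lengths.

## Known limitations

* The DPM source count is a posterior mode over an inconsistent
  quantity; treat `k_posterior` as the result, the mode as a summary.
* Directional migration rates are relative by construction; they
  support ordering and asymmetry statements, not absolute migrant
  numbers.
* The admixture model ignores linkage and uses uncorrelated
  frequencies; closely related founder pools will look like admixture.
* Kriging assumes second-order stationarity of the diversity field;
  with very few defined cells the variogram fit is weakly constrained
  and the IDW fallback may engage.
* All geometry is planar; do not use the package across extents where
  a local projection is inappropriate (hundreds of km or high
  latitudes with wide longitude spans).
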