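# spreadgen

Reconstructing the history of a biological invasion from occurrence
records and SNP genotypes.

When an invasive species spreads through a landscape, two data streams
accumulate independently: dated point observations (often
citizen-science records) and, later, genome-wide genotypes sampled
across the invaded range. Each stream answers only part of the
question. `spreadgen` implements the full joint reconstruction for a
multi-source invasion — the motivating system is a pond-breeding
amphibian spreading along a river valley from several introduction
points, with a canal acting as a dispersal barrier — and ships a
synthetic-invasion generator with complete ground truth so that every
stage is testable without any field data.

The pipeline stages, each a documented R function:

| Stage | Model / statistic |
|---|---|
| Geographic profiling | Dirichlet-process mixture of bivariate normal sources, $x_i \sim \sum_k w_k\,N(\mu_k, \sigma^2 I)$, CRP partition prior, inverse-gamma prior on $\sigma^2$; Gibbs sampler (C++), hit-score search surface, Gelman–Rubin $\hat R$ |
| Occupancy | cumulative extent of occupancy as exact union of 1-km discs; expansion speed $E = \sqrt{C/\pi}$ in both its readings |
| Diversity | $H_o$, unbiased $H_e$, $F_{IS} = 1 - \sum H_o/\sum H_e$ per locality |
| Differentiation | Weir–Cockerham $\theta$ (ratio-of-sums), chord and Prevosti distances, AMOVA $\Phi_{ST}$, Mantel tests of isolation by distance |
| Clustering | STRUCTURE-style admixture Gibbs sampler, Evanno $\Delta K$, hierarchical reapplication with the $q \ge 0.6$ assignment rule |
| Kinship | Wang-type similarity-category moment estimator of relatedness, full-sib filtering at $r \ge 0.5$, cross-locality kin edges at $r \ge 0.35$ |
| Connectivity | divMigrate-style directional relative migration from pooled allele frequencies ($G_{ST}$ + Jost's $D$), $I$, $E$, $R_{I/E}$ summaries, Mann–Whitney cluster comparison |
| Surfaces | isolation-by-distance residual resistance mapping with per-cell resampling significance; kriged moving-window rarefied-$H_o$ surface correlated with geoprofile hit scores |

The methods vignette (`vignettes/invasion-reconstruction.Rmd`) explains
every model, prior, and numerical choice.

## Worked example

The numbered drivers under `analysis/` run the whole reconstruction on
a simulated two-origin river invasion (four staggered sources, a
barrier at x = 8 km, clutch-structured sampling of 96 individuals at
400 SNPs):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_geoprofile.R
Rscript analysis/03_occupancy.R
Rscript analysis/04_popgen.R
Rscript analysis/05_connectivity.R
Rscript analysis/06_surfaces.R
```

Output of the profiling and structure stages on this synthetic valley:

```
geoprofile: modal source count 5 ; sigma 1.65 km [1.48, 1.83]; R-hat 1.0027
posterior over source count:
    4     5     6     7     8     9
0.016 0.460 0.386 0.117 0.018 0.002
```

Four sources were simulated; the posterior concentrates on 4–7 with its
mode at 5 — the honest answer for a 13-year-old invasion whose clouds
have begun to merge, and the reason the full posterior is always
reported alongside the mode. The occupancy stage prints the cumulative
extent per side of the barrier (west 90.4 km², east 37.1 km² in 2009),
and the structure stage recovers the two founder origins exactly:

```
AMOVA: Phi_ST = 0.472 (p = 0.000999)
IBD (all localities): Mantel r = 0.712, p = 0.001
level-1 clusters: K = 2   (localities 1-4 vs 5-8)
```

Tables and ESRI ASCII surfaces land under `results/`.

A 28-locality reference table of published per-locality diversity
statistics for the motivating study system is packaged as
`table1_fixture()` (mean $H_o$ 0.216, $F_{IS}$ from −0.300 to 0.119).

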