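# countrysideSAR

Projecting short-term species extinctions under land-use change with
species-area relationship (SAR) models, for macroecologists and
conservation modellers who need extinction projections that (a) credit
species persisting in human-modified habitat and (b) behave correctly
when the spatial grain of the analysis changes.

## The models

The classic power-law SAR predicts that converting an area *a* of a
landscape of native habitat of area *A* drives extinct

&nbsp;&nbsp;&nbsp;&nbsp;ε(a) = 1 − ((A − a)/A)^z,

treating converted land as completely hostile. The **countryside SAR**
weights each habitat's area by a species-group affinity *h*:

&nbsp;&nbsp;&nbsp;&nbsp;ε(a) = 1 − ((h₁(A − a) + h₂a) / (h₁A))^z,

so a fraction (h₂/h₁)^z of species persists even under full conversion.
With z = 1 and h₂ = 1 − σ this collapses to the **linear model**
ε = aσ/A, the naive proportional extrapolation of plot-scale field
results. Affinities are derived from plot-scale sensitivities
σ = 1 − S(modified)/S(native) through h = (1 − σ)^(1/z).

The package couples these models with a lattice landscape simulator
(controlled native cover and fragmentation), a nested sampling-window
analysis of how the projected extinction fraction depends on sampling
grain, and tools for summarising sensitivity databases (group means,
three-way ANOVA with η² effect sizes, affinity tables).

## Worked example

```r
library(countrysideSAR)

# 90% habitat loss at z = 0.2 under the classic SAR
classic_extinction(0.9, 1, z = 0.2)
#> [1] 0.3690427        # only ~37% of species lost despite 90% conversion

# plot-scale sensitivity 0.6 (permanent crops) -> countryside affinity
affinity_from_sensitivity(0.6, z = 0.2)
#> [1] 0.01024          # the h2 ~ 0.01 used below

cfg <- scaling_config(side = 64, native_fraction = 0.10, z = 0.2,
                      h2 = 0.01, n_replicates = 100, base_seed = 1)
curve <- run_scaling_experiment(cfg)
subset(curve, model == "countryside")
#>        model omega window_area mean_epsilon sd_epsilon n_windows
#>  countryside     1           1    0.5416448 0.18064619    409600
#>  countryside     2           4    0.4704691 0.18305110    102400
#>  countryside     4          16    0.3923275 0.11377573     25600
#>  countryside     8          64    0.3645880 0.04719029      6400
#>  countryside    16         256    0.3594419 0.02191499      1600
#>  countryside    32        1024    0.3582711 0.01001865       400
#>  countryside    64        4096    0.3579597 0.00000000       100
```

At the single-cell grain the countryside projection (0.542 = converted
fraction × sensitivity) matches plot-scale field studies exactly; at the
whole-landscape grain it falls to 0.358, because the extinction fraction
is convex in the converted fraction for z < 1. The classic SAR instead
starts at 0.90 (the converted fraction) at grain 1, and the linear
model's mean is flat across grains — linear extrapolation of plot results
overestimates large-scale extinctions. `variance_decay_summary(curve)`
summarises how the window-to-window spread shrinks with grain.

Sensitivity databases (CSV of native/modified richness comparisons
labelled by taxon, region and land-use class):

```r
db <- generate_sensitivity_db(sensitivity_design(n_per_cell = 73, seed = 11))
three_way_anova(db)   # F, p, eta^2 per effect (Type II by default)
#>   effect   df  sum_sq f_value  p_value  eta_sq
#> land_use    4 32.5835 133.011 8.57e-97 0.26810   # dominant land-use effect
#>    taxon    1  0.0853   1.392 2.38e-01 0.00070   # null taxon effect
#>    ...
affinity_table(db, z = 0.2, keys = "land_use")[, c(1, 2, 3, 8)]
#>         land_use   n mean_sigma affinity
#>     annual_crops 292      0.437   0.0566
#>   managed_forest 292      0.143   0.4612
#>  permanent_crops 292      0.598   0.0104
#>         pastures 292      0.310   0.1561
#>            urban 292      0.365   0.1031
```

A command-line front end for both workflows is installed at
`system.file("scripts/countryside_sar.R", package = "countrysideSAR")`
(subcommands `scaling` and `sensitivity`).

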