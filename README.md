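# prevcommon

Unsupervised species commonness classification and prevalence priors from
occurrence records.

## What it does and for whom

Bayesian ecological niche models (ENMs) multiply their likelihood by a
prior *prevalence* probability — the expected proportion of surveyed sites
where the species is present. Before a target area has been surveyed, this
prior is usually elicited from experts, which is slow and subjective.
`prevcommon` is for ecological modellers who instead want a reproducible,
data-driven prior over many species at once, computed from occurrence
records collected in analogous areas (other wetlands, other surveys, other
data collections).

The package classifies each species into **rare**, **fairly common** or
**very common** and maps the classes to prevalence probabilities
**0.2 / 0.5 / 0.8** (an optional 0.05-step gradient from 0.2 to 0.8 gives
finer granularity).

## The method

For each species six aggregative features are computed from its records
over a set of area polygons ("datasets"), a grid resolution (default
0.01°), and a time frame with a one-year unit:

- *A* = Σ over occupied datasets of (individuals / records) — abundance per record;
- *IntraDs* = total records / number of datasets;
- *InterDs* = occupied datasets / number of datasets;
- *E* = mean over occupied datasets of (occupied cells / polygon cells);
- *F* = mean over occupied datasets of (years with records / years in frame);
- *HF* = as *F*, counting years with at least *Thr* (default 5) records.

The z-scored feature matrix is modelled three ways, with no labels:

1. **Multi K-means** — a K-means sweep over K ∈ [3, n/2] selecting K\* by a
   chi-squared test of cluster-size uniformity (smallest K not rejected at
   α = 0.05; empty/sparse configurations excluded);
2. **X-means-style sweep** — the same sweep selecting K\* by minimum
   spherical-Gaussian BIC;
3. **Variational autoencoder** — a small VAE (architecture found by a
   growing search, latent dimension swept 1–6) scoring each species by
   reconstruction log-probability; scores are cut into quantile groups.

Each cluster/group centroid is labelled per feature against the
25th/75th percentiles across all species (H/M/L); a strict H majority
makes the cluster "very common", a strict L majority "rare", anything
else "fairly common" — species inherit their group's class. A per-species
majority **ensemble** of the three models (no majority → fairly common)
gives the final class and prevalence. Agreement against reference labels
(accuracy, Cohen's kappa, confusion matrices, binary very-common vs
less-common merge) and leave-one-out feature sensitivity complete the
toolkit, along with a synthetic occurrence generator with planted
commonness tiers for end-to-end validation.

See the methods vignette (`vignettes/commonness-methodology.Rmd`) for the
model details, parameter defaults and design rationale.

## Worked example

Simulate the default synthetic study (150 species in three planted tiers
across 20 wetland-like polygons over a decade), run the full pipeline, and
compare against the planted truth:

```r
library(prevcommon)

g   <- generate_occurrences(sim_config(seed = 42L))
ref <- setNames(g$truth$tier, g$truth$species)
run <- run_pipeline(g$records, g$cfg,
                    species_list = g$truth$species, reference = ref)
print(run)
#> Commonness run: 150 species, 85343 records over 20 datasets
#>   K* (Multi K-means) = 3; K* (X-means) = 18; VAE widths (2,2) latent 5
#> Ensemble
#> fairly_common          rare   very_common
#>            70            40            40
#>   MultiKMeans  3-class acc 1.000 kappa 1.000 | binary acc 1.000 kappa 1.000
#>   XMeans       3-class acc 0.867 kappa 0.800 | binary acc 0.867 kappa 0.706
#>   VAE          3-class acc 0.333 kappa 0.000 | binary acc 0.600 kappa 0.000
#>   Ensemble     3-class acc 0.867 kappa 0.800 | binary acc 0.867 kappa 0.706

head(run$table[, c("species", "A", "InterDs", "F",
                   "EnsembleClass", "Prevalence")], 4)
#>             species        A InterDs   F EnsembleClass Prevalence
#> 1 very_common_sp001 74.27505    0.75 0.9 fairly_common        0.5
#> 2 very_common_sp002 93.44516    0.95 0.9   very_common        0.8
#> 3 very_common_sp003 96.23373    0.95 0.9   very_common        0.8
#> 4 very_common_sp004 85.05786    0.85 0.9 fairly_common        0.5
```

Reading the output: the uniformity-selected clustering recovers the three
planted tiers exactly; the BIC sweep fragments the feature space into 18
clusters and demotes some lower-range very-common species to fairly
common (their centroids tie on high/medium feature counts); the VAE's
reconstruction scores separate tiers only weakly on this simulation, so
its quantile groups classify conservatively. The ensemble's `Prevalence`
column is the prior to hand to an ENM.

Real data enter through `read_occurrences()` (canonical or Darwin-Core
CSV headers), `read_areas()` (GeoJSON or WKT polygons) and
`study_config()`. A thin command-line wrapper over the same functions is
in `inst/cli/prevcommon.R` (`simulate`, `run`, `evaluate` subcommands).

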