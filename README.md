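# reefgrid

Spatial interpolation of benthic percent cover by ordinary kriging and
inverse distance weighting, with a simulation framework for studying how
photo-transect sampling density drives interpolation accuracy.

## The problem

Turbid-water patch reefs cannot be mapped by remote sensing, so the
distribution and abundance of their habitat-forming organisms (HFO — hard
corals, octocorals, macroalgae, sponges, zoantharians) must be interpolated
from *in situ* photo-quadrat samples collected along transects. Two
interpolators dominate practice:

- **Inverse distance weighting (IDW)** — deterministic weights
  `ẑ(x₀) = Σ dᵢ⁻ᵖ zᵢ / Σ dᵢ⁻ᵖ` over the neighbours inside a searching
  window, with power `p ∈ {1, 2, 3}`.
- **Ordinary kriging (OK)** — best linear unbiased prediction under a
  semivariogram `γ(h)` estimated from the data (Matheron estimator,
  weighted-least-squares fit of nugget `c₀`, partial sill `c`, range `a`
  for spherical/exponential/gaussian families), solving
  `Σⱼ λⱼ γ(xᵢ, xⱼ) + μ = γ(xᵢ, x₀)` for all neighbours `i`, `Σ λⱼ = 1`.

Which one to trust — and how far apart quadrats may be — depends on the
spatial structure and skewness of each taxon's cover. `reefgrid` implements
both interpolators from first principles behind a common elliptical
searching window, scores them by leave-one-out cross-validation (mean
absolute error `ME = mean |ẑᵢ − zᵢ|` and `r²`, the squared Pearson
correlation of predicted against measured), and synthesises per-taxon
prediction rasters into presence/absence layers and a 0-to-5 HFO richness
map at 5 m resolution.

Because ground truth is never available for a real reef, the package also
ships a synthetic-data module: Gaussian random fields (exact dense Cholesky
or circulant-embedding FFT) with per-taxon variograms, pushed through a
monotone zero-inflating transform with a saturation plateau to emulate
patchy, strongly skewed cover distributions, sampled along a 15-transect ×
200 m design with quadrats every 5 m, and degraded by binomial point-count
observation noise. Thinning the 5 m base samples by factors 2 and 4
emulates 10 m and 20 m sampling (50% and 75% fewer quadrats).

## Worked example

The package bundles a fully synthetic example survey (580 quadrats on 15
transects; see `tools/make_fixture.R` — it is generated by the package's
own simulator, not field data):

```r
library(reefgrid)
samples <- read_samples(system.file("extdata", "synthetic_reef_cover.csv",
                                    package = "reefgrid"))
samples
#> reef_samples: 580 points on 15 transects, 5 taxa (macroalgae, octocorals,
#>               sponges, zoantharians, millepora)

fit <- reef_interp(octocorals ~ 1, samples, method = "OK", max_lag = 100)
summary(fit)
#> reef_interp: OK of 'octocorals' on 580 samples
#>   OK spherical(41,564,48.4), window 193.482x193.482 m
#> Leave-one-out cross-validation:
#> cv_report [octocorals, OK spherical(41,564,48.4), window 193.482x193.482 m]:
#>   580/580 predicted (0 NODATA)
#>   ME = 9.278, r2 = 0.7009
```

The variography fitted a spherical model (nugget 41, partial sill 564,
range 48 m, cover² units): octocoral patches decorrelate within ~50 m, and
roughly 7% of the variance is quadrat-scale noise. The LOO `r² = 0.70`
says 5 m sampling captures most of the spatial signal; `ME = 9.3`
percent-cover points is the typical prediction error. The full protocol —
best IDW power vs best OK family, at 5/10/20 m sampling distances:

```r
cmp <- compare_methods(samples, taxa = c("octocorals", "sponges"))
cmp[, c("taxon", "factor", "method", "candidate", "ME", "r2")]
#>         taxon factor method   candidate    ME      r2
#> 1  octocorals      1    IDW         p=3  9.23 0.70263
#> 2  octocorals      1     OK   spherical  9.28 0.70014
#> 3     sponges      1    IDW         p=3  4.34 0.34625
#> 4     sponges      1     OK exponential  4.49 0.34874
#> 5  octocorals      2    IDW         p=3 11.69 0.50488
#> 6  octocorals      2     OK   spherical 11.50 0.51897
#> ...
#> 11    sponges      4    IDW         p=1  6.43 0.00380
#> 12    sponges      4     OK   spherical  6.42 0.00118
```

Accuracy degrades monotonically as sampling coarsens (factor 1 → 4 is
5 m → 20 m), and collapses entirely for the sparse, high-CV sponges at
20 m — their ~25 m patches slip between quadrats. Grid maps, presence
layers and the richness synthesis:

```r
rasters <- lapply(sample_taxa(samples), function(tx) {
  f <- reef_interp(as.formula(paste(tx, "~ 1")), samples,
                   method = "IDW", power = 3)
  predict(f, reef_grid())
})
write_asc(rasters[[2]], "octocorals.asc")  # ESRI ASCII grid, NODATA -9999
rich <- richness_map(lapply(rasters, to_presence, threshold = 0))
```

An end-to-end run (simulate → sample → compare → map → richness, with a
reproducible JSON manifest) is one call: `run_pipeline(pipeline_config())`.

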