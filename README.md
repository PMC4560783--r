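# ChromDyn

Chromatin locus diffusion and continuous-photobleaching analysis for live-cell
single-particle tracking (SPT) of nuclear loci — telomeres, centromeres and
tagged gene loci — together with the simulation machinery needed to validate
every estimator on ground-truth data.

## The scientific problem

Genomic loci in interphase nuclei do not diffuse freely. Their time-averaged
mean square displacement over a lag τ,

    MSD(τ) = ⟨r²(τ)⟩ = D_α · τ^α,

typically grows sublinearly (anomalous subdiffusion, α < 1), consistent with
fractional Brownian motion (FBM, Hurst index H = α/2) in the visco-elastic
nucleoplasm; α = 1 is normal (Brownian) diffusion with
D = D_α / (2d) in d dimensions. Note that the units of D_α
(μm² s^−α) depend on α, so diffusion coefficients are only comparable between
processes with the same exponent.

Single trajectories of live-cell SPT are far too short (≈ 50–100 frames) to
fit α reliably one locus at a time. ChromDyn therefore implements an ensemble
procedure based on the **mean logarithmic square displacement (MLSD)**:

1. per-locus time-averaged MSDs on a common lag grid;
2. subtraction of the static localization-error term 2·d·ρ², with ρ the
   per-axis precision measured on fixed cells;
3. power-law fits of the arithmetic ensemble-mean MSD (exponent α_MSD) and of
   the geometric-mean "average particle" MSD (exponent α_MLSD). For per-locus
   exponents α_i ~ Normal(ᾱ, σ_α²) the geometric mean estimates ᾱ unbiased
   by the spread, while the arithmetic mean is dominated by large-α loci;
4. the pointwise difference of local log–log slopes,
   ε(τ) = s_MSD(τ) − s_MLSD(τ) = σ_α² · ln τ, regressed on ln τ, yields the
   population variance σ_α² of the exponent;
5. D_α is the prefactor of the average-particle curve.

Around this core the package provides:

* an exact-covariance FBM simulator (circulant embedding) plus a population
  generator with per-locus exponents, localization noise, nuclear drift and
  in-plane rotation, and ground-truth manifests;
* rigid-motion correction: per-frame centre-of-mass subtraction and the
  closed-form 2D Procrustes rotation, including correction of a sparse locus
  (e.g. a gene locus) by co-observed reference loci (telomeres);
* convex-hull geometry: territories scanned by single loci (hull volume over
  a time window) and internal/peripheral classification (a locus is
  peripheral at t if it lies on the hull of all loci; loci that never touch
  the hull are internal);
* continuous-photobleaching (CP) analysis: a two-population
  reaction–diffusion–bleaching solver (bound pool bleaches fast, free pool
  is replenished by diffusion and bleaches slowly), trace smoothing, bleach
  onset detection, the I(t) = a·e^(−bt) + c·t + d fit and the free fraction
  d/(a+d).

## Worked example

Two synthetic nuclei at the imaging cadence of a volumetric time-lapse
(100 frames every 18.5 s, 20 nm localization noise): a wild-type-like
subdiffusive population (ᾱ = 0.6, σ_α = 0.1) and a faster normal-diffusion
population (ᾱ = 1.0, σ_α = 0.2).

```r
library(ChromDyn)

wt <- PopulationPreset(name = "lamin_wt", alphaMean = 0.6, alphaSd = 0.1,
                       dAlpha = 5e-4, nLoci = 200, nFrames = 100,
                       dt = 18.5, rho = 0.02, seed = 7)
ko <- PopulationPreset(name = "lamin_null", alphaMean = 1.0, alphaSd = 0.2,
                       dAlpha = 1e-3, nLoci = 200, nFrames = 100,
                       dt = 18.5, rho = 0.02, seed = 8)
res <- runPipeline(list(wt = wt, ko = ko), window = c(7, Inf))

res$reports$wt$estimate
#> EnsembleDiffusionEstimate (200 loci):
#>   alpha_MSD  = 0.660
#>   alpha_MLSD = 0.604
#>   mean alpha = 0.604, sd alpha = 0.110
#>   D_alpha    = 0.000337 um^2 s^-alpha, rho = 0.02 um
res$reports$wt$classification
#> [1] "subdiffusive"
res$reports$ko$estimate
#> EnsembleDiffusionEstimate (200 loci):
#>   alpha_MSD  = 1.219
#>   alpha_MLSD = 0.981
#>   mean alpha = 0.981, sd alpha = 0.236
#>   D_alpha    = 0.000689 um^2 s^-alpha, rho = 0.02 um
res$reports$ko$classification
#> [1] "normal"
```

The recovered mean exponents (0.604 and 0.981) match the generating values
(0.6 and 1.0); α_MSD exceeds α_MLSD in both conditions because loci with
large exponents dominate the arithmetic mean — the gap is exactly what the
ε-fit converts into σ_α. A per-locus exponent comparison between the
conditions:

```r
compareConditions(res$reports$wt, res$reports$ko)
#>      mean_a   mean_b difference  conf_low  conf_high         t       df  p_value
#> 1 0.6044855 0.981391 -0.3769055 -0.418193 -0.3356179 -17.95665 336.6938 4.77e-51
```

and the scanned territories grow with the faster, normal motion
(mean hull volume 0.010 μm³ vs 1.4 μm³ over the full 31 min here; at
matched D_α and a 15 min window the contrast is milder but in the same
direction).

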