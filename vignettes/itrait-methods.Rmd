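---
title: "Methods: from multi-optical scans to drought genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-optical scans to drought genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(itrait)
```

This vignette records the models, conventions and design choices behind
`itrait`, in the spirit of a statistical-methods appendix: what each stage
assumes, which knobs matter, and what the synthetic-data tests do and do
not demonstrate about real platform data.

## The phenotyping model

A scanned plant yields three kinds of raw data: a stack of 20 side-view RGB
images (one per 18° of rotation), a 250-band hyperspectral reflectance cube,
and a 360-projection X-ray sinogram of a stem cross-section. Each is
condensed into a fixed registry of i-traits:

* **RGB (67 traits).** Segmentation uses the excess-green index
  `2G − R − B` with an Otsu cut, a 3×3 morphological opening, and
  largest-component selection; geometric traits are measured on the view
  with the widest silhouette (ties break to the lowest view index, making
  extraction invariant to view order). The registry is 15
  geometry/architecture traits (TPA, height, width, convex-hull area,
  solidity, perimeter, compactness `4πA/P²`, skeleton length via
  Zhang–Suen thinning, a stem-width estimate, ...), 12 color summaries
  (mean/SD of R, G, B, hue, saturation, value over plant pixels), and 40
  hue-histogram bin fractions. Convex hulls are taken over pixel *corners*
  so that a filled rectangle has solidity exactly 1; the perimeter is the
  count of foreground pixel edges facing background. Only the total count
  is fixed at 67; the individual geometric definitions are this package's
  own, chosen to be deterministic and analytically checkable on phantoms.
* **HSI (2000 traits).** Per band `b`, total reflectance `T_b` (sum over
  plant pixels) and average reflectance `A_b` (mean), expanded to eight
  families {`T`, `A`, `lgT`, `lgA`, `dT`, `dA`, `ddT`, `ddA`}: base-10
  logs (missing-coded when the argument is nonpositive rather than
  clipped, to avoid fabricating values) and first/second finite
  differences over band index (central in the interior, one-sided at the
  ends). 2000/250 = 8 forces exactly eight families; this set is the
  symmetric completion of the named traits (`dT233`, `ddT200`, `lgA15`,
  `A248`). Derivatives are taken per band index; since the wavelength grid
  is equally spaced this is proportional to per-nm derivatives. The grid is
  calibrated linearly through band 15 = 434 nm and band 233 = 959 nm,
  which places band 136 at 725 nm and band 200 at 880 nm.
* **CT (100 traits).** Reconstruction is classical filtered
  back-projection: ramp (Ram-Lak) filtering in the frequency domain (Hann
  apodization optional) and linear-interpolation back-projection, with the
  angular quadrature halved for full-turn acquisitions since each line is
  measured twice. The trait names of the form `hollow_area_700` are read as
  *intensity thresholds* on the reconstructed slice: ten culm measures
  (hollow/material/total area, Feret diameter, mean wall thickness over 360
  rays, perimeter, hollow fraction, eccentricity, mean material intensity,
  hollow-centroid offset) at ten thresholds 100..1000 give exactly the
  100-trait registry. This threshold-ladder reading is the only one we
  found consistent with both the trait names and the printed count; it is a
  documented stand-in, like the RGB registry.

Assembled over treatments (WW, DS, and the per-accession DS/WW ratio) and
the design's time points (10 RGB, 4 HSI, 3 CT), one accession carries
67×10×3 + 2000×4×3 + 100×3×3 = 26,910 trait columns. Ratio columns are
missing-coded when the WW denominator is numerically zero.

## Drought-trait selection

Four filters run in a fixed order, and the final keep flag is their pure
conjunction (the report retains every stage's statistic, so decisions are
auditable):

1. **3σ outlier removal.** Single pass, with mean and SD computed from the
   original column — not iterated — discarding ~0.27% of normal data
   (the 99.7% coverage rule).
2. **Welch t-test** of DS vs WW accession means at α = 0.05. The
   unequal-variance form is the safer default when only "independent
   samples" is assumed; the verdict propagates to the trait's WW, DS and
   ratio columns, since a ratio trait is informative exactly when its
   parent contrast is.
3. **MLP importance.** A single-hidden-layer perceptron (64 units, weight
   decay) classifies WW vs DS rows per modality × time block; traits are
   scored by permutation importance normalized so the best trait scores
   100%, averaged over 5 seeded repeats, and dropped below 50%. Blockwise
   fitting keeps the network conditioning tractable; a near-chance
   classifier is flagged `low_separation` rather than silently trusted.
4. **Heritability.** One-way random-effects REML (`lme4`), accession as the
   random effect, `H² = σ²G/(σ²G + σ²e/r)`, ANOVA method-of-moments as
   fallback with negative components truncated at zero. H² is computed per
   treatment view; a WW/DS pair passes if either condition reaches the 0.2
   cutoff (the combination rule is not dictated by the selection procedure
   itself; requiring both would conflate heritability with
   stress-responsiveness). Ratio columns are judged on their own values.

## Association

Kinship is the VanRaden centered cross-product; structure covariates are
the first 3 genotype PCs. The mixed model `y = Qα + xβ + u + ε`,
`u ~ N(0, σ²g K)`, is solved by spectral decomposition of K — exact REML
for a single random effect — and the variance components estimated on the
no-SNP model are reused for every SNP test (uncompressed P3D). Replicates
are averaged per accession beforehand; the mean is the least-assumption
combination. Each SNP gets a GLS Wald t-test (df = n − q − 1), PVE is
`β²·Var(x)/Var(y)·100`, and the threshold is `1/n` markers before display
rounding. Significant SNPs are merged into QTLs by transitive closure of
the ≤100-kb adjacency per chromosome, each cluster reported as
[min − 100 kb, max + 100 kb] floored at 1. Candidate genes require a
significant SNP inside the 1-based inclusive gene span. eQTLs are scanned
per gene and condition with the same model; the most significant SNP
within the gene span ± 10 kb (window boundaries inclusive) makes the eQTL
local, otherwise distant — the "20-kb region" phrasing and the "10-kb
upstream and downstream" phrasing agree under this reading — and
significance in both vs one watering condition makes it static vs dynamic.

## Prediction

RR-BLUP estimates λ = σ²e/σ²u by REML on the eigenbasis of ZZ' and solves
the ridge system; with λ fixed it reproduces the dense closed-form ridge
solution to machine precision, which the tests assert. Bayes A is a Gibbs
sampler with per-marker scaled-inv-χ² variances (defaults df 5, scale
calibrated so markers explain about half the phenotypic variance a priori,
3000 iterations / 1000 burn-in / thin 5 — desk-scale BGLR-like settings);
in the large-df limit with the scale pinned to RR-BLUP's σ²u its
predictions converge to RR-BLUP's, a useful two-solver cross-check. The
candidate-vs-random evaluation repeats 50/50 train/test splits, draws
size-matched random SNP sets from the non-candidate pool each repeat, and
compares accuracy distributions with a one-sided Welch test. Stepwise
marker selection is forward entry at α = 0.05 with backward elimination at
α = 0.10 (the classical stepwise convention); exactly collinear candidates
are screened out by a residual-tolerance check. The four spectral indexes
use standard remote-sensing windows — green peak 500–590 nm, red valley
620–700 nm, red edge 680–760 nm — since the index names fix the features
but not the formulas; computed on average reflectance they are invariant
to plant size.

## The synthetic-data module

The generators define the conditions every test runs under:

* **Genotypes**: binomial sampling per SNP, allele frequencies uniform on
  [MAF_min, 1 − MAF_min], resampled until the *realized* MAF clears the
  floor (0.05 by default, matching the panel admissibility rule); optional
  k-subpopulation Beta-distributed divergence (F-model) gives the Q+K
  machinery real structure to absorb.
* **Trait panels**: value = causal-SNP effects + polygenic deviation +
  replicate noise, with the genetic values rescaled so their realized
  variance is exactly σ²G and σ²e solved from
  `H² = σ²G/(σ²G + σ²e/r)` — the identity holds to 1e-12 by construction,
  so heritability recovery is a genuine estimator test, not a tautology.
  The polygenic part defaults to an infinitesimal sum over all SNPs (borne
  by the kinship matrix, the appropriate null for mixed-model calibration);
  an iid accession-level variant is available. DS values are shifted by a
  treatment effect plus optional genotype-dependent drought effects so
  ratio traits carry real signal. Default H² = 0.4 and r = 2 reflect the
  panel median heritability and the two-replicate design this pipeline
  targets. Noise is Gaussian by default; a rescaled t(3) option exercises
  the 3σ filter.
* **Image phantoms**: a deterministic silhouette (stem rectangle + six
  thick leaf arcs) rasterized with one corrective pass so the realized
  pixel count lands within 2% of the requested area — area, height and
  width therefore have analytic ground truth. The leaf spectrum is a
  smooth curve with a green peak at 550 nm, a chlorophyll-scaled red
  valley at 670 nm, a logistic red edge onto the NIR plateau, and a water
  dip centered at 980 nm so that its depth controls the *sign and size* of
  the reflectance derivative at 959 nm (band 233). The CT phantom is an
  annulus forward-projected with a discrete Radon transform; the
  ground-truth slice is returned beside the sinogram so round-trip error is
  measurable.
* **Expression panels**: baseline + planted eQTL effects + noise, with
  local/distant geometry enforced at planting time against the 10-kb rule
  and dynamic eQTLs active only under DS.

What phantom-based tests show: that the extractors measure what they claim
on known geometry, that the reconstruction/segmentation chain is accurate
to stated tolerances, and that selection/association/prediction recover
planted architecture. What they do not show: robustness to real-world
nuisance — overlapping leaves, specular highlights, illumination drift,
beam hardening, heteroscedastic sensor noise — none of which the phantoms
emulate, deliberately (see Non-goals below).

## Numerical choices and degenerate inputs

* Segmentation never crashes on blank input: degenerate contrast returns
  an empty mask with a warning; empty plants zero-code geometry and
  missing-code color.
* FBP uses zero-padded FFT filtering (padding to the next power of two
  above twice the detector count) and clamps out-of-range detector samples
  to zero; reconstruction amplitude was verified on disk phantoms against
  the analytic value rather than tuned.
* The P3D REML optimizes log δ on [−12, 12] with eigenvalues floored at
  1e-10; SNPs with zero variance among phenotyped lines are skipped and
  listed, p-values are floored at the smallest positive double.
* The Bayes A sampler keeps a running residual vector, giving O(nm) cost
  per sweep; chains are reproducible given the seed, and the residual
  variance chain is exposed for stationarity checks.
* `H² = 1` panels (σ²e = 0) and `H² = 0` panels (no genetic variance) are
  both legal and exercised in tests.

## Problem sizes used in the tests

The test-suite and acceptance-script sizes are chosen to exercise the
study's design scales while staying desk-fast: heritability recovery on
368-line, 2-replicate panels over 50 simulations; mixed-model calibration
on 20 pooled null scans of 2000 SNPs × 200 lines and power on 50 scans of
5000 SNPs × 368 lines with a planted 20%-PVE SNP; the merging oracle on
1000 random SNP configurations; prediction checks on 120-line panels. The
population-scale catalogue numbers of a real campaign (thousands of
significant SNPs and candidate genes) require the real panel and images
and are out of scope here.

## Known limitations

* The 67-RGB and 100-CT registries match the published cardinalities and
  named members, but the remaining member definitions are this package's
  own documented stand-ins.
* The t-test stage applies no multiple-testing correction, by design
  (matching the procedure it implements); interpret the per-stage p-values
  accordingly.
* The MLP stage is stochastic even at fixed seeds across BLAS variants;
  only its contract (separators score 100%, the cut is on mean normalized
  importance) is asserted, not exact importances.
* eQTL records are per gene (top SNP per condition), not per LD-resolved
  regulatory interval; dense local LD can make a distant signal shadow a
  local one.
* The CLI-free interface is deliberate: the exported functions and this
  vignette are the interface, and `scripts/acceptance.R` is the runnable
  end-to-end example.
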