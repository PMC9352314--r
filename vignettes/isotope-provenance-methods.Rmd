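---
title: "Methods: fatty-acid isotope provenance assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatty-acid isotope provenance assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `isocompass`: the
models, the assumptions behind them, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## 1. From raw peaks to fatty-acid δ values

GC-IRMS reports per-peak δ values on an instrument scale. Two corrections
put them on the international scales (VPDB for ¹³C, VSMOW for ²H) as
free-fatty-acid values.

**Scale normalization.** `fit_normalization()` fits an ordinary
least-squares line mapping measured values of the certified FAME standards
(USGS70: δ¹³C −30.53‰, δ²H −183.9‰; USGS71: −10.5‰, −4.9‰; USGS72: −1.54‰,
+348.3‰) to their accepted values. At least two distinct standards are
required; three give a residual per standard that serves as a QC check. If
a `run_index` is supplied, a linear drift term is estimated jointly
(`lm(measured ~ accepted + run_index)`) and removed before the
normalization line is fitted. The drift model is linear in run order and
fitted per analytical sequence; amplitude (linearity) correction is
assumed to have been applied upstream unless such columns are provided.
Re-applying a normalization to already-calibrated records is an error by
design — double calibration is a silent corruption we refuse to allow.

**Methylation correction.** Derivatization adds a methyl group from
methanol (1 carbon, 3 hydrogens), so the measured FAME mixes the fatty
acid's atoms with methanol's. `methylation_correct()` inverts the linear
mass balance on the δ scale,

δ_FA = (n · δ_FAME − n_Me · δ_MeOH) / (n − n_Me),

with n the total count of the element's atoms in the FAME molecule
(carbons + 1 for ¹³C; 2c − 2d + 2 hydrogens for ²H, since the carboxyl
hydrogen is replaced by the methyl group) and n_Me = 1 or 3. Working on
the δ scale rather than atom-fraction space introduces errors well below
0.1‰ at natural abundance, which is standard field practice. The balance
is exactly invertible: `fame_from_fa()` is the inverse, and the test suite
checks round-trip conservation to 1e-9‰. The methanol δ values have **no
default** — they differ between laboratories and silently assuming them
would bias every corrected value, so the pipeline refuses to run without
them. The same logic applies to the brain-only fatty acid "HTA": its
structure is not standardized, so `register_hta()` must be called before
HTA peaks can be corrected; until then parsing yields NA atom counts and
correction raises an informative error. Acyl hydrogen is treated as
non-exchangeable; no H₃⁺-factor or memory-effect corrections are applied.

## 2. Composites and the core feature panel

The bulk-lipid proxy δ_FAbulk is the mass-fraction-weighted mean over
*all* identified peaks of a sample, computed separately per isotope
because the ²H peak set is typically smaller than the ¹³C set (poorer
detection limits for H₂). A panel-restricted variant is available via the
`panel` argument of `bulk_delta()` for sensitivity analysis.

The feature matrix uses the 11-FA core panel (14:0, 16:0, 16:1, 18:0,
18:1, LIN, ALA, ARA, EPA, DPA, DHA) × 2 isotopes = 22 features, the set
measured in every sample and tissue; brain comparisons may add HTA (24
features). Missing data are handled by complete-case deletion per
analysis, never imputation — this mirrors the varying per-tissue n in real
CSIA datasets, where a sample missing one panel feature is dropped from
multivariate analyses but still contributes to composites.

## 3. Site repeatability

`site_repeatability()` fits `y ~ covariates + (1 | site)` by REML (lme4)
and reports the adjusted repeatability R = σ²_site / (σ²_site + σ²_res):
the share of variance between sites after the fixed-effect group means of
taxon, tissue and/or year have been removed. "Controlling for" is thus
implemented as fixed-effect adjustment inside the mixed model; the
alternative two-stage estimator (residualize on covariates, then one-way
ANOVA moment estimator with the unbalanced-design n₀) is exported as
`site_repeatability_anova()` and the two are required by the test suite to
agree within 0.02 on balanced designs. Year enters as a fixed covariate by
default whenever both years are present; covariates with a single observed
level are dropped automatically, and a covariate confounded 1:1 with site
is rejected with an explicit error because R would not be identifiable.
Negative REML variance components are floored at zero.

The confidence interval is a parametric bootstrap: responses are
resimulated from the fitted model (`simulate.merMod`), the model refitted,
R recomputed; the percentile interval over `n_boot` (1000 by convention)
replicates is returned. The seed is mandatory — an unseeded bootstrap is
not reproducible and we treat that as an error, not a warning. R is
invariant under adding a constant to y and under positive rescaling, which
also makes it immune to affine calibration error.

## 4. Multivariate structure

`canonical_correlation()` computes canonical correlations between the
centered δ¹³C and δ²H blocks via SVD of the whitened cross-covariance
S_xx^{−1/2} S_xy S_yy^{−1/2}. Whitening uses a symmetric eigen inverse
square root with relative tolerance 1e-10; rank-deficient blocks are
truncated to their numerical rank with a warning, and n ≤ p + q triggers
an inflation warning. Dimension tests use Wilks' Λ_k = Π_{i≥k}(1 − r_i²)
with Rao's F approximation; for p = q = 1 this reduces exactly to the
ordinary correlation F test (verified in the tests), and sample sizes too
small for positive denominator degrees of freedom raise an error rather
than returning nonsense.

Variance attribution uses Type II sums of squares on additive models
(`drop1`-style: RSS(all other terms) − RSS(full)). The original analysis
convention mixes Type II and Type III depending on interaction
significance; we standardize on Type II and expose Type III (with
sum-to-zero contrasts) behind `type = "III"` only, because the attribution
tables are qualitative (which factor dominates) and Type III results
depend on a contrast-coding commitment that is rarely stated. Holm
adjustment is step-down `p.adjust`; Šidák is single-step 1 − (1 − p)^m.
Marginal means and Šidák-adjusted pairwise contrasts are delegated to
emmeans on a balanced reference grid.

## 5. Discriminant site assignment

`fit_lda()` stores class centroids ("grand means"), the pooled
within-class covariance S_w (denominator n − k), equal priors by default
(sites are compared, not prevalences; empirical priors are a flag), and
canonical axes as eigenvectors of S_w^{−1}B with per-axis proportion of
trace. Numerical choices:

* Ridge regularization ε = 1e-6 · tr(S_w)/p is added only when the
  condition number of S_w exceeds 1e8, or forcibly (with a warning) when
  p ≥ n; every application is logged via a message.
* Prediction is the maximal Gaussian discriminant score, equivalent under
  equal priors to the nearest-Mahalanobis-centroid rule; the test suite
  holds the implementation to exact label agreement with a brute-force
  oracle over 100 random instances, and to agreement with an independent
  reference implementation.
* Exact score ties are broken lexicographically by site id and flagged —
  never at random, so runs are reproducible.

Cross-validation follows the bootstrap convention: each of `n_boot` (999)
replicates resamples training rows with replacement *within class*, fits,
and evaluates on the out-of-bag rows; accuracy aggregates over all OOB
predictions. OOB evaluation is pessimistic for very small classes (each
replicate drops ~37% of a class); `loo_cv_accuracy()` provides the
deterministic leave-one-out alternative and is the appropriate within-year
baseline when classes hold only a handful of fish. Resubstitution accuracy
is always reported alongside, and the tests check the optimism inequality
(CV ≤ resubstitution on average).

Site pooling is suggestion-only: `suggest_site_pools()` proposes
single-linkage groups of sites that are close in *both* centroid
Mahalanobis distance and geographic distance, but `pool_sites()` only ever
applies a user-supplied map. The multi-tissue consensus rule scores a fish
site-specific when ≥ 3 of its (up to 4) tissues are assigned correctly;
with fewer than 3 tissues available, all must be correct.

Cross-year transfer (`cross_year_predict()`) freezes the training-year
model — centroids plus pooled covariance, no test-year refitting — and
scores the test year both exactly (confusion-matrix trace over total) and
with a distance tolerance: a prediction within `tolerance_km` (default
1 km) of the true site per the supplied site-distance matrix counts as
tolerant-correct. The distance matrix may be Euclidean from coordinates or
supplied directly (stream distances are allowed; symmetry and a zero
diagonal are enforced, the triangle inequality deliberately is not).

## 6. What the synthetic generator emulates — and what it does not

`simulate_csia()` draws, for every fish × tissue × FA × isotope,

δ = μ_FA,iso + altitude term + site effect + tissue offset + taxon offset
+ year shock + residual,

then pushes the free-acid values through the generative FAME mass balance
and the inverse of a configurable instrument calibration, so the emitted
peak table is on the raw scale and every pipeline stage (including
calibration fitting from emitted standards) is exercised against stored
truth. Key structural choices, mirroring the study system the package was
designed around (a sub-alpine 15-site stream network, three taxa, four
tissues, two years):

* **Altitude gradient in ¹³C only** (default −5‰ per km over 525–1070 m
  a.s.l.): δ¹³C gets lighter upstream; δ²H carries no altitude trend.
* **Equicorrelated site effects**: one latent draw per (site, isotope)
  propagates to FAs with correlation 0.7 for ¹³C and 0.3 for ²H — the
  simplest mechanism making δ¹³C strongly inter-FA-correlated and δ²H only
  weakly so. Site-effect SDs default to 1.5‰ (¹³C) and 5‰ (²H) against
  residual SDs of 0.8‰ and 8‰.
* **Close tributary pairs**: sites 4/5 and 10/11 sit < 1 km apart with
  site effects correlated at 0.8, emulating shared water sources and
  giving the distance-tolerant scoring and pooling suggestions something
  real to detect.
* **Year drift as independent per-(site, FA) shocks** (SD 1.2‰ for ¹³C,
  6‰ for ²H), mirroring patchy rather than global between-year change.
  The configuration deliberately uses two per-isotope drift SDs: the two
  delta scales differ by an order of magnitude and a single value cannot
  serve both.
* **Mass fractions** are Dirichlet draws around a realistic FA profile
  (concentration 200).

Defaults were chosen once so that default simulations land in the
qualitative regime the method is known to occupy — multivariate CSIA
classification far above the 2-feature bulk classifier, cross-year
transfer substantially degraded relative to within-year performance —
and are configuration, not claims about any real dataset.

Not emulated: mechanistic isotope fractionation (bioconversion kinetics,
trophic discrimination), hydrological isoscapes, spatial autocorrelation
of site effects beyond the two twin pairs (so tolerant accuracy rarely
exceeds exact accuracy in simulations, unlike in real stream networks
where neighboring sites are systematically confusable), heteroscedastic
residuals, and peak-detection dropout (every simulated sample carries the
full panel for both isotopes). Passing tests on simulated data therefore
demonstrate the *statistical machinery* — calibration algebra, variance
partitioning, classifier behaviour, seeding and determinism — not the
field-level validity of any particular assignment.

## 7. Problem sizes and reproducibility

The test suite and the acceptance script use: a "tiny" fixture (3 sites ×
6 fish, muscle only) for smoke tests; a "paper_shape" fixture (15 sites,
159 first-year fish across three taxa plus 49 second-year bullheads at 9
sites, four tissues) for regime checks; 200 simulated datasets per
generating ratio (15 sites × 10 fish) for repeatability recovery; 999
bootstrap replicates for classification CV and 1000 for repeatability CIs
in production use (reduced in unit tests). Every stochastic stage takes an
explicit seed, and `run_pipeline()` writes a manifest (config hash,
versions, seeds, row counts, warnings) so that two runs with the same
configuration are byte-identical — a property the test suite asserts.

## 8. Known limitations

* The repeatability model supports a single random site effect; nested or
  crossed random structures (e.g. fish within site) are out of scope.
* Quadratic or flexible discriminant analysis is not provided; the pooled
  covariance assumption is the point of comparison the canonical variate
  framework requires.
* The generator's taxon and tissue offsets are constant across FAs by
  default; per-FA offset tables are accepted but no default structure is
  shipped.
* Published reference tables bundled under `inst/extdata/` are summary
  values transcribed for worked examples; the underlying per-sample field
  data are not public, so headline field-study accuracies are not
  recomputable from raw data and are not claimed by this package.
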