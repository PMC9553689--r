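---
title: "Quantifying seed and nut nutrition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seed and nut nutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrispec)
```

nutrispec implements a complete desk-scale version of a multi-instrument
nutritional survey of seeds and nuts: near-infrared (NIR) calibration of the
five proximate nutrients, ^1^H-NMR fatty-acid class profiling, proximate
formulas, and linear chromatographic quantification, tied together by
replicate statistics and a report assembler. This vignette explains the models
behind each stage, the parameters that matter, and the choices made where the
design was genuinely open.

## The NIR calibration model

A ground sample's NIR spectrum between 900 and 1700 nm is dominated by
overtone and combination bands of C–H, O–H and N–H bonds, so it carries a
(nearly) linear signature of the sample's oil, moisture, ash, protein and
carbohydrate content. The calibration model is therefore linear in the
centered spectrum,

$$\hat{y} = (\mathbf{x} - \bar{\mathbf{x}})^\top \mathbf{b} + \bar{y},$$

with the coefficient vector $\mathbf{b}$ estimated either by partial least
squares (PLS) or principal component regression (PCR). Both are implemented
in the package:

* `fit_pls()` runs the sequential NIPALS algorithm for a single response:
  each latent variable's weight vector is the normalized covariance
  $X^\top y$, scores are $X w$, and both $X$ and $y$ are deflated by the
  rank-one score/loading product before the next component. The returned
  coefficients $\mathbf{b} = W (P^\top W)^{-1} q$ reproduce the
  latent-variable prediction exactly, and after $k$ components the residual
  $X$ is orthogonal to every extracted weight vector — both properties are
  tested.
* `fit_pcr()` regresses the centered response on the scores of the leading
  principal components of the centered spectra, with a deterministic sign
  convention (largest-magnitude loading element positive).

Only centering is applied to $X$ and $y$. Standard normal variate (SNV)
pretreatment already puts every scan on a common scale, and autoscaling
wavelengths would inflate noise-only channels; the response is centered but
not scaled so that all error metrics stay in nutrient percentage points.

With the number of components equal to the predictor rank, both estimators
collapse to ordinary least squares; the test suite verifies this equivalence
against a closed-form solve to 10^-8^ on small instances, which is the
strongest available independent oracle for the implementation.

### Pretreatment

`savitzky_golay()` performs local polynomial least-squares smoothing (and
derivatives) with position-dependent weights. Points within half a window of
the spectrum ends are handled by refitting the polynomial on the truncated
window rather than by padding — no data are fabricated beyond the measured
range. Defaults are window 11 and polynomial order 2, a mild smoother for a
115-point grid; the derivative option divides by the 7 nm grid step so first
derivatives are in absorbance/nm. `snv()` centers and scales each scan using
the sample standard deviation (denominator $n-1$, the dominant chemometrics
convention; the choice is documented because tests assert exact values). The
default chain is smoothing followed by SNV; on this generator's data the two
orders are nearly equivalent, and the chain is configurable in `pretreat()`.

### Validation metrics and RPD

`validate()` reports the full error suite. For a residual vector $r$ on $n$
samples:

* RMSE-type quantities use divisor $n$: $\mathrm{RMSE} = \sqrt{\sum r_i^2/n}$;
* SE-type quantities are bias-corrected: the spread of residuals about their
  own mean with divisor $n-1$. The two definitions differ only by the mean
  bias and the divisor, which is why published tables list both with similar
  values;
* R² values are squared Pearson correlations between observed and predicted;
* RPD is the standard deviation of the *prediction set's reference values*
  divided by SEP. It holds by construction in every report, and the bundled
  reference metrics are internally consistent with this definition: the two
  oil models' SEP × RPD products imply holdout standard deviations of 22.77
  and 22.80, agreeing to 0.14 %.

The data are split once into a random holdout prediction set (default 20
samples — the survey's design) and a calibration set; RMSECV/SECV come from
10-fold cross-validation (or leave-one-out) inside the calibration set. Which
subset a published cross-validation column was computed on is generally not
recoverable from a finished table, so both schemes are selectable and both
sets of statistics are always reported.

`classify_rpd()` bands RPD values as excellent (≥ 3), very reliable (2–3),
limited (1.5–2) and unreliable (< 1.5). Published bandings sometimes overlap
as printed (e.g. "2–3 very reliable" alongside "2.5–5 limited"); the package
uses non-overlapping defaults and leaves the thresholds configurable rather
than resolving the contradiction silently.

The number of latent variables is rarely stated in published calibrations;
`select_components()` chooses it by minimizing RMSECV, breaking ties toward
the smaller model.

## The synthetic-data generator

No raw spectra accompany the reference dataset, so the generator emulates the
study conditions:

* **Compositions.** `generate_compositions()` draws oil, moisture, ash and
  protein uniformly within ranges spanning the reference samples' observed
  extremes (oil 0.2–61 %, moisture 3–14.5 %, ash 1.7–5.2 %, protein
  15.5–48 %) and closes every row with carbohydrate-by-difference, rejecting
  draws whose closure term leaves its own range. Every composition sums to
  exactly 100 %.
* **Spectra.** Each scan is a Beer–Lambert-style linear mixture of five
  pure-component spectra, one per nutrient, built from Gaussian bands
  centered at the wavelengths where each nutrient's calibration regression
  coefficients peak (oil 929/1039/1208/1386/1700 nm, moisture
  977/1107/1338/1473 nm, ash 1149/1305/1411/1494 nm, protein
  1153/1308/1411/1494/1673 nm, carbohydrate 929/1007/1211/1442/1584/1692 nm).
  Widths default to a 25 nm sigma and amplitudes to 1: broad, heavily
  overlapping bands, with protein and ash nearly collinear — deliberately
  reproducing the conditioning that makes full-spectrum multivariate
  calibration the method of choice. The grid is 900–1700 nm at the 7 nm
  instrument bandwidth (115 points).
* **Artefacts.** Per-scan linear baseline drift, a multiplicative scatter
  factor and white noise, i.e. exactly the structure SNV and smoothing are
  designed to remove. The generator's default is noise-free; the noisy study
  condition used in the analysis scripts and acceptance run is baseline slope
  sd 10^-5^ AU/nm, offset sd 0.02 AU, scatter sd 5 % and additive sd 0.002 AU,
  chosen once as typical magnitudes for a diffuse-reflectance instrument of
  this class.

One modelling consequence deserves emphasis: because compositions close to
100 %, the five mixing fractions are linearly dependent, and the centered
spectra span a **four**-dimensional space. Four latent variables therefore
recover noise-free compositions to machine precision, and requesting a fifth
is a rank-deficiency error by design. The tests and the acceptance run use
$k = 4$ for exact-recovery checks.

What the generator does *not* emulate: wavelength-dependent scatter
(multiplicative effects are a single factor per scan), detector nonlinearity,
temperature-induced band shifts, and any nonlinearity of real
constituent–absorbance relationships. Passing the recovery tests shows the
estimators are correct for the linear model they assume, not that a real
instrument would achieve these error levels.

## Fatty-acid classes from NMR integrals

For an oil's ^1^H spectrum, five integrals suffice to quantify fatty-acid
classes, because the proton stoichiometry per acyl chain is fixed: every
chain has one terminal methyl (3H) and one α-carbonyl methylene (2H); every
unsaturated chain has four allylic protons; ω3 chains' methyl resonance is
shifted by the nearby double bond; and each double-bond-interruption
contributes diagnostically to the polyunsaturation region. With integrals
A (non-ω3 methyl), B (ω3 methyl), C (allylic), D (α-carbonyl methylene),
E (polyunsaturation-diagnostic):

$$\omega_3 = 100\frac{B}{A+B},\qquad
\omega_6 = 100\left(\frac{E}{D} - \frac{2B}{A+B}\right),$$
$$\omega_9 = 100\left(\frac{C}{2D} - \frac{E}{D} + \frac{B}{A+B}\right),\qquad
\mathrm{SFA} = 100\left(1 - \frac{C}{2D}\right).$$

The four classes sum to 100 *identically* — the terms telescope — and
PUFA = ω3 + ω6. These identities, scale invariance under rescaling all
integrals, and an exact round trip with the generator's inverse map
(`integrals_from_profile()`) are tested over a thousand random profiles. On
the six bundled reference profiles the equations reproduce every published
class value and the three printed ω6:ω3 ratios (0.767, 1.804, 4.443).

Whether region E is best described as the olefinic or the bis-allylic region
is ambiguous in the surrounding literature; the implementation fixes only the
algebra above, which is the unique parse under which the published class rows
sum to 100 and PUFA additivity holds, and leaves the spectroscopic assignment
open. Negative intermediate values (possible with noisy integrals) clamp to
zero with a warning rather than erroring, so batch runs survive; the ω6:ω3
ratio is reported as `NA` when ω3 is zero or undetected, never as infinity.
"nd" cells in the bundled tables load as `NA` and are excluded from means,
never imputed as zero.

## Proximate formulas

`nitrogen_percent()` implements the Kjeldahl back-titration formula
$(\mathrm{mL_{sample}} - \mathrm{mL_{blank}}) \times N \times 14.007 \times
100 / \mathrm{mg_{sample}}$. The conversion to protein
(`protein_percent()`) defaults to a factor of 1.0 — the convention under
which the bundled reference protein values were produced — with the
conventional 6.25 available; the choice is explicit because the two differ
by a factor large enough to matter nutritionally. Carbohydrate is defined by
difference, which guarantees the five-fraction closure to exactly 100; a
budget that overshoots (negative carbohydrate) is flagged with a warning
rather than an error so that replicate batches keep processing.
`mass_fraction_percent()` covers the gravimetric fractions (residue mode for
ash and oil, loss mode for moisture) and is invariant to the mass unit.

## Chromatographic quantification

Sugars (HPLC-ELSD, eight-analyte panel) and resveratrol (LC-MS/MS) are
quantified by linear calibration: `fit_calibration()` fits unweighted
ordinary least squares of response on concentration over the standard series
(100–1200 ppm for sugars). ELSD response is in truth slightly power-law; the
linear model is used deliberately because the reference analyses report a
single linear R², and a log-log option is provided but off by default.
Weighted regression is omitted for the same reason.

`assign_peaks()` matches peaks to the expected retention times (xylose 9.34
through maltose 21.65 min; resveratrol 3.050 min) with a configurable
half-window, default 0.15 min. The default is set below half the closest
library spacing (sorbitol and galactose are 0.85 min apart), and a tolerance
that would make windows overlap is rejected when the assignment is
configured, not discovered per sample. One analyte is never assigned to two
peaks; the nearest peak wins. `quantify_sample()` back-calculates extract
ppm, flags values outside the fitted standard range as extrapolated, reports
negative back-calculations as zero with a warning, and converts to the
reporting bases: mg/100 g flour for sugars (1 g sample in 10 mL water) and
µg/100 g oil for resveratrol. Extraction recovery is assumed complete, as no
recovery factor accompanies the reference values.

## Replicate statistics

Replicates (18 per sample in the reference design) are summarized as mean ±
sample sd. Across-sample testing is classical one-way ANOVA
(`anova_oneway()`, equal-variance), with pairwise significance at α = 0.05
via Tukey's HSD by default; unadjusted pairwise t tests are available because
published significance narratives rarely name their post-hoc procedure, and
the two options bracket the reasonable range. `build_report()` assembles the
mean ± sd blocks with significance marks and `nd` cells.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full synthetic pipeline at
the survey's scale — 140 samples, 115 wavelengths, a 20-sample holdout,
10-fold CV — which completes in seconds; the ANOVA type-I simulation uses
2000 null draws of three six-replicate groups, enough to resolve the 5 %
rate to about ±1 %. Degenerate inputs are errors where they signal a broken
pipeline (constant scan in SNV, rank-exceeding component counts, zero
calibration slope, mismatched wavelength grids) and warnings where a batch
should survive one bad record (negative carbohydrate, negative
back-calculated concentration, clamped class percentages). All random steps
take explicit integer seeds; nothing depends on hidden global state beyond
the seed passed in.

## Known limitations

* The NIR stage is validated against the linear mixture model it assumes;
  real spectra add nonlinearities the generator does not produce, so the
  error levels achieved here are upper bounds on realism, not forecasts.
* NMR and GC-FID fatty-acid figures are *not* asserted to agree numerically
  with each other — on real data the two methods correlate strongly but
  imperfectly; the package only checks rank-order sanity where both derive
  from the same synthetic truth.
* The chromatographic stage starts from peak tables; peak detection and
  integration from raw traces, and MS/MS spectral matching, are out of scope
  (precursor and fragment masses are carried as identity metadata only).
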