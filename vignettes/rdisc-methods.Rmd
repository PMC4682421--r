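---
title: "Methods: quality control, discretization and classification of single-cell Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control, discretization and classification of single-cell Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdisc)
```

# The problem

A single-cell Raman spectrum records inelastic (Stokes) photon scattering
across typically 1,000–2,048 wavenumber channels. The vibrational bands in
it are a phenotype fingerprint, but the raw trace mixes three components of
very different magnitude: the Raman bands themselves, an intense smooth
autofluorescence baseline that can dwarf them, and broadband instrument
noise. `rdisc` first removes the latter two (quality control), then reduces
the spectrum to a short list of representative peaks (discretization), so
that storage, comparison and classification operate on ~10–20 numbers per
cell instead of thousands.

# Quality control

The chain is fixed: **denoise → baseline → normalize**. Each stage is also
exported on its own.

## Wavelet shrinkage denoising

The intensity trace is decomposed with an orthogonal discrete wavelet
transform (default: order-4 Daubechies filters, 3 decomposition levels) and
the detail coefficients are soft-thresholded at the universal threshold

$$t = \hat\sigma \sqrt{2 \ln n}, \qquad
  \hat\sigma = \mathrm{median}(|d_1|) / 0.6745,$$

where $d_1$ is the finest detail band. The signal is reconstructed from the
adjusted coefficients. Boundaries are handled by mirror extension to a
power-of-two length (continuous at both ends of the periodic extension) and
the result is truncated back to the input length; the transform is exactly
orthogonal, so reconstruction without thresholding is exact to rounding.

Two choices deserve comment:

* **All detail levels are thresholded by default** (`shrink_levels =
  1:wavelet_levels`). The universal threshold with a MAD-estimated $\sigma$
  is conservative, and noise energy that survives in the mid bands
  (levels 2–3) produces smooth bumps a few channels wide that the
  downstream peak gates would have to reject one by one. Thresholding every
  band is the standard form of this estimator; restricting shrinkage to the
  finest band remains available through `qc_config()`.
* **Depth 3 by default.** Deeper decompositions remove more noise but start
  to distort band shapes of FWHM 10–30 cm⁻¹; three levels leave bands of
  that width untouched on a ~1.4 cm⁻¹ channel grid.

The denoiser is a near-fixed point on its own output: a second application
changes the trace by well under 10 % of the first application's change
(asserted in the tests).

## Piecewise baseline correction

Troughs are channels that are the *strict* minimum of the window
$[i - w, i + w]$ (default half-width $w = 25$ channels), with the first and
last channels always added so the baseline covers the whole grid. Between
adjacent anchors a low-order curve is fitted — by default the straight line
through the two anchor intensities, so every trough is interpolated
exactly; `baseline_order = 2` substitutes a quadratic through three
consecutive anchors.

On a smooth denoised trace the strict-minimum rule can leave hundreds of
channels between troughs (a monotone slope of the fluorescence background
has no interior window minimum at all), and a chord across such a span cuts
through or sails under the curved background. `estimate_baseline()`
therefore refines the anchor set: any segment whose signal dips below its
chord by more than `anchor_tol` (default $10^{-3}$ of the intensity range)
is split at the deepest such channel, recursively. The refined baseline
tracks the lower envelope of the signal; since peaks are always above the
local background, refinement anchors never land on a peak, and the supplied
troughs remain exact interpolation points. What the refinement cannot fix
is a *concave* background stretch without troughs — there the baseline
remains a chord below the background and leaves a broad positive residual;
such residuals are wide and flat, which is exactly what the downstream
curvature gate rejects.

Corrected intensities are floored at zero by default (`clip_negative`):
physical intensities are non-negative, and the floor prevents downstream
stages from chasing negative noise excursions.

## Normalization

Min–max scaling maps every intensity by
$y_i \leftarrow (y_i - \min Y) / (\max Y - \min Y)$, giving min 0 and max 1
exactly. A spectrum whose range is zero up to floating-point rounding
(relative range $\le 10^{-12}$) is rejected as degenerate rather than
normalized into amplified rounding noise.

Normalization makes all downstream thresholds relative to the strongest
band. The flip side is a genuine domain restriction: a trace containing *no*
band at all is rescaled so that its residual noise spans $[0, 1]$, and no
fixed curvature or intensity threshold can then tell noise from signal.
The pipeline assumes at least one real band; the tests exercise the
near-worst case of a single band over default background and noise.

# Discretization

A channel $i$ of a quality-controlled spectrum becomes a representative
peak iff **all three** gates hold (they are applied as a conjunction):

1. **Local maximum**: $p_i > \max(p_{i-M}, \dots, p_{i+M})$, strict, with
   the window truncated at the boundaries. Default $M = 20$ channels. The
   strictness implies flat plateaus produce no candidates, and of two bands
   closer than $M$ channels only the taller survives.
2. **Sharpness**: the geometric curvature
   $\kappa = |f''| / (1 + f'^2)^{3/2}$, with derivatives from central
   finite differences *on the channel grid* (unit spacing), must exceed
   $\lambda$. Channel-grid spacing gives $\lambda$ a grid-independent
   meaning; users who want physical cm⁻¹ curvature can rescale by the
   squared channel spacing. The first and last channels have no central
   difference and can never pass this gate.
3. **Noise floor**: $p_i$ must exceed the noise level — the mean of the
   window (width $M$) with the smallest mean among the quiescent windows,
   "quiescent" meaning variance at most the median of all window
   variances. The median rule is parameter-free and selects genuinely flat
   regions.

## Calibrating the sharpness threshold λ

$\lambda$ is the one parameter without a natural closed form; it was
calibrated once on the simulator's study conditions and fixed at
$\lambda = 3 \times 10^{-3}$. The calibration target is separation of two
populations on the ~1.4 cm⁻¹ grid of a 2,048-channel spectrum:

* the weakest marker band of interest (relative height 0.3 after
  normalization, FWHM 30 cm⁻¹) has apex curvature
  $\kappa \approx 2h/\gamma^2 \approx 5 \times 10^{-3}$;
* residual background bumps (imperfect baseline segments, surviving
  smoothed noise) measure up to $\approx 4 \times 10^{-3}$ at the extreme
  tail, with the bulk far lower, and broad flat humps (width
  ≥ 200 cm⁻¹) sit near $10^{-5}$.

$3 \times 10^{-3}$ splits the two with margin on both sides; on 100
simulated spectra it yields ~98 % recovery of planted bands and ~0.3
spurious peaks per spectrum, with a median of 10–12 representative peaks.
Raising $\lambda$ trades recall of weak broad bands for fewer spurious
peaks monotonically (peak count is non-increasing in both $\lambda$ and
$M$, asserted as a property test).

# Similarity of discrete spectra

Peaks of two spectra are matched one-to-one with tolerance
$\delta = 10\,\mathrm{cm}^{-1}$. Among all feasible matchings the
implementation maximizes the pair count and, among those, minimizes the
total position distance. Because both peak lists are sorted and the
tolerance is an interval constraint, an optimal matching can always be
uncrossed, so a dynamic program over the two sorted lists finds it exactly
(verified against exhaustive search on small instances); argument order is
canonicalized so the result is symmetric.

The scores are

$$s_1 = \frac{|\text{matched}|}{n_a + n_b - |\text{matched}|}, \qquad
  s_2 = \mathrm{cor}(v_a, v_b), \qquad
  s = \sqrt{s_1}\, s_2,$$

with $v_a, v_b$ the matched-pair intensities. $s_2$ is defined as 0 when
fewer than two pairs exist or either intensity vector is constant — the
correlation is undefined there, and 0 (no evidence of correlation) extends
the no-common-peaks convention. The square root in $s$ deliberately softens
the position term so that two spectra sharing most bands but differing in a
few class-specific ones are separated mainly by the intensity pattern.

# Classification protocol

Both classifiers run over either representation:

* **k-NN** (default $k = 1$): similarity is Pearson correlation of
  intensity vectors on a common grid (full spectra; spectra on different
  grids are linearly interpolated), or the combined score $s$ (discrete).
  Similarity ties break by earlier reference order, vote ties by the
  nearest neighbour's label — both deterministic.
* **LDA**: multi-class Fisher discriminant with the pooled within-class
  covariance regularized as $\Sigma + \text{ridge} \cdot I$ (default
  $10^{-3}$), equal priors by default. The ridge keeps the fit defined
  when dimensions exceed samples, as they do for full spectra. For the
  discrete representation the fixed feature dimension comes from a **peak
  vocabulary**: all training peak positions pooled and single-linkage
  merged at $\delta$, each spectrum projected to the intensity of its peak
  nearest each vocabulary slot (0 if none within $\delta$). The vocabulary
  is fitted on the training side of each split only.

Evaluation repeats a stratified random 60/40 split 10 times (stratification
keeps small classes present in training; the protocol would otherwise
occasionally drop a rare class entirely) and reports per-repeat accuracies
and their mean. All randomness flows from one integer seed; a fixed seed
reproduces the report bit for bit. Full-spectrum classification operates on
quality-controlled spectra — the raw traces are dominated by the random
fluorescence background, which correlation similarity would measure instead
of the bands.

# What the simulator emulates — and what it does not

`default_templates()` builds class templates on a 400–3,200 cm⁻¹ grid
(2,048 channels by default): six marker bands shared by all classes (common
biomolecule bands) plus 3–8 class-unique bands at least 25 cm⁻¹ from any
other class's unique bands, Lorentzian line shapes with FWHM 10–30 cm⁻¹ and
relative heights 0.3–1. Within a class, bands are at least 65 cm⁻¹ apart so
that two planted bands never compete inside one ±M detection window — the
generator is designed to test the pipeline, not the inherent ambiguity of
overlapping bands. Each simulated cell adds Gaussian position jitter
(1.5 cm⁻¹), lognormal height variation (CV 0.15), a smooth background of
2–3 wide Gaussians scaled to twice the tallest band (fluorescence dominates
Raman signal in real cells), and additive Gaussian noise
($\sigma = 0.02$, i.e. SNR 15 for the weakest band), floored at zero.

Real spectra differ in ways the simulator does not model: overlapping and
shouldered bands, cosmic-ray spikes, detector response curves, heteroscedastic
(shot) noise, and baselines with sharp edges. Passing the synthetic
acceptance checks therefore demonstrates the pipeline's internal
consistency and its behaviour under the stated noise/background model, not
instrument-grade performance.

# Numerical choices and degenerate inputs

* Text I/O uses `%.17g`, so both file formats round-trip doubles exactly;
  duplicate shift values are an error (silent averaging would hide
  acquisition faults), and every malformed line is reported with its line
  number.
* Strict inequalities in both window scans mean ties produce *no*
  candidate/trough rather than an arbitrary one.
* Window variance uses the unbiased estimator; the eligibility rule
  (≤ median) is unaffected by the choice of denominator.
* `match_peaks` tie-breaks (equal count and equal total distance) are made
  order-independent by canonicalizing the argument order.
* LDA prediction ties go to the first class in sorted label order;
  a singular scatter with `ridge = 0` raises an error advising a positive
  ridge rather than returning pseudo-inverse results.
* Constant spectra: accepted by the denoiser (identity), rejected by
  normalization (degenerate range), with the failing stage named in the
  error.

# Problem sizes

The test suite and the acceptance script run entirely on simulated data:
100 spectra of 2,048 channels for the condensation and recovery checks, 200
spectra (5 classes × 40) for the classification protocol, 200 random
instances of length ≤ 512 per brute-force oracle comparison, and ≤ 8 peaks
per side for exhaustive matching enumeration. These sizes were chosen so
the full suite exercises every claim at the scale of a realistic single-cell
study while remaining quick enough to run on every change.

# Known limitations

* After min–max normalization there is no absolute intensity scale; a
  spectrum with no real band at all is outside the method's domain (its
  noise is rescaled to full range and discretization will report noise
  bumps as peaks).
* The λ default is calibrated for ~1.4 cm⁻¹ channel spacing; markedly
  different grids need a rescaled `lambda_min` (quadratic in the spacing
  ratio).
* Concave background stretches without troughs are corrected only up to a
  broad flat residual (rejected later by the curvature gate, but it can
  bias peak intensities near such regions by a few percent).
* The noise-floor gate is weak by construction (the quietest window's mean
  is near zero after a good baseline correction); the curvature gate does
  most of the spurious-peak rejection.
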