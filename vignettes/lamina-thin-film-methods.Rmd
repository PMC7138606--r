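---
title: "Thin-film optics of butterfly scale laminae: models, processing, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-film optics of butterfly scale laminae: models, processing, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalefilm)
```

## The physical picture

The lower lamina of a typical butterfly wing scale is a continuous sheet of
chitin some 90–260 nm thick, bounded by air on both sides. At these
thicknesses it acts as a dielectric thin film: light reflected from its two
surfaces interferes, and the reflected spectrum — hence the perceived
structural color — is set almost entirely by the optical thickness
$nT/\lambda$. As $T$ increases, the reflected color traverses the
characteristic thin-film sequence (Newton's series): gold, then
magenta/copper, then indigo and blue, then green. `scalefilm` packages the
quantitative machinery around that observation: a forward reflectance model,
inverse thickness estimation from measured spectra, the spectral-processing
chain used on microspectrophotometry data, corrections for helium-ion
microscopy (HIM) cross-section metrology, hierarchical statistics for nested
thickness data, and a synthetic-data generator that stands in for specimen
data.

## Forward model

A single lossless film of index $n = 1.56$ (chitin; treated as
nondispersive) in air. For each polarization the amplitude reflectance is
the two-interface Airy sum

$$r = \frac{r_1 + r_2 e^{i\phi}}{1 + r_1 r_2 e^{i\phi}},
\qquad \phi = \frac{4\pi n T \cos\theta_t}{\lambda},$$

with $r_1, r_2$ the Fresnel amplitudes at the air→film and film→air
interfaces and $\theta_t$ the refracted angle. Unpolarized reflectance is
the arithmetic mean of the s and p power reflectances (the measurement used
an unpolarized halogen source; no polarization handling is stated for it,
so the mean is our declared choice). The implementation is validated in the
test suite against an independently coded transfer-matrix oracle to 1e-8.

Two consequences worth knowing:

* the peak reflectance of an ideal chitin film in air is
  $((n^2-1)/(n^2+1))^2 \approx 17.4\%$ — thin films are a real but dim
  color source ("around 20 %" is the right mental number);
* $R(\lambda, T) = R(c\lambda, cT)$ at normal incidence, which is why
  thickness sets the hue.

**Cone averaging.** Spectra are measured through an objective with
numerical aperture 0.5, an inverted illumination cone with maximal
half-angle $\arcsin(0.5) = 30°$. The model averages $R(\lambda,\theta)$
over $\theta \in [0°, 30°]$ weighted by the circular annulus factor
$2\pi\theta$ and normalized by the cumulative circular area — the weighting
is deliberately the literal $\theta$ weight of the source procedure, not
the solid-angle $\sin\theta$ weight; a `weight = "solid_angle"` option
exists but is off by default so that defaults reproduce the published
model. Discretization uses 31 equally spaced angles with trapezoid end
correction; doubling the angle count moves the result by well under 1e-4.
Averaging over angle blue-shifts and slightly smooths the spectrum; it
never shifts the dominant peak to longer wavelengths.

**Roughness.** An uneven lamina is modelled as an ensemble of ideal films
with Gaussian-distributed thickness (mean = measured mean, SD = sample SD),
truncated at $T > 0$, 400 draws by default, seeded for reproducibility.
Averaging over the ensemble damps the spectral oscillation, as expected
from phase averaging.

**Pigment.** The observed reflectance of a pigmented scale is modelled as
double-pass Beer–Lambert attenuation,
$R_{obs} = R_{lamina}\,10^{-2A(\lambda)}$: light crosses the pigmented
upper structure before and after reflecting off the lamina. The source
observations state a threshold behavior (≤ 0.2 AU does not cancel
structural color) but no functional form; the double-pass form is our
recorded modelling decision and is tested only for the qualitative masking
property, plus the exact arithmetic that a uniform absorber scales the
spectrum without moving its centroid.

## Spectral processing

Raw reflectance spectra are processed in the narrative order of the source
protocol, recorded here as a single pipeline because no single order is
stated there:

1. local-regression smoothing — tricube-weighted local linear fit
   (`stats::lowess`, zero robustness iterations) with span 0.3 as a
   fraction of points;
2. clamp negative values to zero;
3. subtract the per-spectrum minimum;
4. divide by the white-reference correction factor 2.5 (specular scale
   measured against a diffuse BaSO₄ standard that the scale does not fill).

Whether the division by 2.5 happened before or after minimum subtraction is
not explicit in the protocol; since the two operations commute up to a
constant factor of the subtracted minimum and all downstream thickness
inference is amplitude-invariant, we fixed the order above once. Exact
replication of the cited processing routine's internals is not claimed;
tests use smooth synthetic inputs where any reasonable local-regression
smoother agrees (and a linear ramp, on which local-linear smoothing is
exact, isolates the chain arithmetic).

Absorbance is $A = -\log_{10}(\text{sample}/\text{reference})$ from
transmitted-light counts of index-matched scales; $1 - 10^{-A}$ is the
fraction of light not transmitted (0.2 AU ≈ 37 %).

## Inverse thickness estimation

The proposal that structural variation "could be surveyed from reflectance
spectra" is realized as `fit_thickness()`. No fitting objective is stated
in the source; ours is a declared choice validated by round-trip recovery:

* **objective** — least squares between *shape-normalized* spectra (each
  divided by its own mean). Rationale: the thickness signal lives in the
  positions of the interference extrema, not in absolute amplitude, so
  calibration factors (the 2.5 divisor, integration time) cancel.
* **search** — the objective is multimodal in $T$ (adjacent Newton phases
  produce locally similar spectra), so we never run a single local
  optimizer: an exhaustive grid over 50–350 nm (1 nm default) is followed
  by golden-section refinement around the best grid point, and all local
  minima are reported as ranked candidates.
* **calibration offset** — measured spectra sit 40–80 nm red of the
  ideal-film model for every specimen; aligning them would need either
  $n \approx 1.75$ or thicknesses 20–25 nm above the measured means. We do
  not guess the cause; `calibration_offset_nm` adds a constant to the
  *reported* thickness (never to the objective) so a survey can be anchored
  to HIM measurements if desired. Default 0.

## HIM metrology

Point thickness measures are rescaled for working-distance variation,
$T_{correct} = T_{raw} \, d / 9058\,\mu m$, and carry a worst-case tilt
bound $T(1-\cos t)$: with the inflection-point criterion limiting tilt to
5°, underestimation is below 1 nm for any lamina up to 260 nm. Group
summaries report mean ± SD pooled over point measures — whether published
±SD values pool points or scales is not stated; we pool points and leave
variance partitioning to the hierarchical model.

## Hierarchical statistics

Thickness data are nested: multiple point measures per scale, multiple
scales per individual, few individuals per group. The source analysis used
a Type III nested ANOVA via lme4 with Satterthwaite degrees of freedom;
that machinery is explicitly out of scope here and replaced by a declared
procedure:

* **variance components** by REML (lme4) on
  `value ~ group + (1|individual) + (1|scale)`;
* **significance** by permutation, reassigning whole *individuals* to
  groups — the exchangeable unit — so all within-individual correlation is
  preserved. The statistic is the one-way F on per-individual means.

This choice is assumption-light and testable: the suite verifies type-I
calibration (rejection rate within [0.02, 0.09] at α = 0.05 over 100 null
simulations) and null-uniformity of p-values. It has one honest cost,
acknowledged rather than hidden: with $g$ individuals per group in a
two-group design there are only $\binom{2g}{g}$ reassignments, so the
p-value has a floor of $2/\binom{2g}{g}$ — with 3 individuals per group
that floor is 0.1, and p-values like the parametric 0.00157 reported for
the minimal published design are unreachable *by construction*. Simulation
tests and the `repro` pipeline therefore use 6 individuals per group, where
the floor is ≈ 0.002; with 3 individuals per group the test is still valid
but can at best flag the observed arrangement as the most extreme one.

Post-hoc pairwise comparisons use per-individual means with pooled
within-group variance and a studentized-range (Tukey HSD) family-wise
adjustment; adjusted p is monotone in and never below the raw pairwise p.
The Mann–Whitney U test (used for absorbance contrasts) enumerates all
$\binom{n+m}{n}$ assignments exactly for $n+m \le 12$ (midranks for ties)
and otherwise uses the normal approximation with tie and continuity
correction.

**Color grouping.** "Largest natural breaks" on two metrics — mean
thickness and weighted average reflected wavelength — is formalized as:
sort each metric, cut at its $k-1$ largest gaps ($k = 5$), and declare the
metrics in agreement when the two partitions coincide; on disagreement both
partitions are returned with a conflict flag. This 1-D gap rule is one
reading of an informal procedure; 2-D clustering was deliberately not used
because the source language treats the metrics separately and reports their
agreement.

## Colorimetry

`render_color()` integrates a spectrum against the CIE 1931 2° observer
under D65 and converts to sRGB. No colorimetry package is available in the
target environment and tabulated observer data cannot be shipped as binary
data, so the observer is the published multi-lobe piecewise-Gaussian
analytic fit (Wyman, Sloan & Shirley 2013; ~1 % accurate) and D65 is the
standard 10 nm table inlined as source. Tristimulus values are normalized
to the *computed* illuminant white before the sRGB matrix, so a flat
spectrum maps to exact neutral regardless of the observer approximation.
These choices are modern defaults — the source states none — and all color
assertions in the tests are qualitative (hue families and their order), for
which ~1 % observer error is immaterial. The hue sweep 90 → 260 nm
reproduces Newton's series: gold → red/magenta → indigo/blue → green.

## Synthetic data: the stated world

The generator emulates the statistical structure the analysis assumes, not
any real specimen:

* **thickness tables** — treatment mean + Gaussian individual effect +
  scale effect + point noise, truncated positive. Defaults: means as
  printed for the focal comparisons (e.g. 187 nm blue vs 107 nm brown cover
  scales); components 5/5/14 nm (pooling to ≈ 16 nm, inside the printed
  12–24 nm SD range); 3 individuals × 5 scales × 10 points, matching the
  published sampling ("minimum 12 measures from 3 scales"; 20–60 measures
  per individual). Working distances are drawn near the 9058 µm reference
  (SD 300 µm, our choice of a plausible instrument spread) and the
  *inverse* correction produces `raw_nm`, so metrology round-trips exactly.
* **spectra** — forward-model spectra at given thicknesses, optional
  parametric Gaussian-band pigment filters (brown/neutral broad absorber,
  yellow short-pass, red mid-band — shape stand-ins, not chemistry),
  optional slow sinusoidal baseline drift, plus additive Gaussian noise
  (default SD 0.01 reflectance units, typical of processed spectra).

What a green test establishes: the pipeline's internal consistency —
generation → processing → inverse fit recovers generating parameters at
realistic noise. What it does not establish: agreement with real scales,
which show the 40–80 nm model offset, film curvature, possible
birefringence and non-uniform composition; none of these are simulated.

## Numerical choices and limitations

* Angular discretization 31 points, trapezoid-corrected; stable to < 1e-4
  under doubling.
* Golden-section refinement tolerance 1e-3 nm; grid step is the accuracy
  contract (±1 nm at the default).
* Truncated-Gaussian draws are redrawn rather than clipped, preserving the
  mean for the SDs used here.
* Degenerate inputs error early: flat spectra (thickness unidentifiable),
  inverted bounds, all-zero spectra for the centroid, single-individual
  groups (fixed effect confounded with the random effect).
* Out of scope by design: multilayer stacks, absorbing films, ridge and
  crossrib diffraction, refractive-index fitting, dispersion, phylogenetic
  comparative methods.
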