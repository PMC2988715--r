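---
title: "Models and methods behind pentachroma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pentachroma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentachroma)
```

This vignette explains the models the package implements, the assumptions
they rest on, the tunable parameters and their defaults, and the design
choices made where the methodology left genuine freedom. It also describes
what the synthetic-cohort generator does and does not emulate, and hence
what a passing test suite does and does not show about real recordings.

## Spectral data model

All wavelength-indexed quantities travel as a `spectrum`: a strictly
increasing wavelength grid (nm) with one value per wavelength. Two grids
are used throughout. Template and quantum-catch computations run on a 1 nm
grid from 300 to 800 nm, which keeps template shapes smooth and matches the
300–800 nm integration bounds of the quantum-catch relation. Sensitivity
curves live on the measurement grid of the ERG protocol, 320–700 nm in
20 nm steps. The two grids are deliberately not reconciled: sensitivity is
only defined where it was measured, while catches integrate over the full
pigment support. All integrals use the trapezoid rule; all resampling is
linear interpolation and never extrapolates.

## Naka-Rushton analysis of response-intensity curves

At each test wavelength, b-wave amplitude versus stimulus irradiance is
fitted with the hyperbolic Naka-Rushton function with unit slope,
`R(I) = Rmax·I/(I + K)`. The fit is unweighted least squares. Because
`Rmax` enters linearly, the joint optimum is found by profiling: for any
half-saturation level the best `Rmax` is closed-form, and the profiled
residual sum of squares is minimized over `LogK` by golden-section search,
bounded at the tested irradiance range ± 2 log units. This is
deterministic and cannot fail to converge the way a general nonlinear
optimizer can; a fit is still flagged non-converged when the optimum pins
to a bound or `Rmax` collapses to zero.

Below 360 nm and above 600 nm the protocol often cannot reach the response
asymptote. The asymptote is considered unreached when the fitted `Rmax`
exceeds the largest observed response by more than 25% — a numerical rule
chosen here, since "reached" is otherwise undefined — in which case the
curve is refitted with `Rmax` fixed to the nearest interior wavelength's
value. Sensitivity is `1/K`; curves are reported as log10 relative
sensitivity with maximum exactly 0, and transformed to min-max scaled
linear relative sensitivity before any template fitting.

## Visual-pigment templates and chromophore mixtures

Absorbance templates are the standard vitamin-A1/A2 rhodopsin nomograms:
a log-inverse-polynomial alpha band plus a Gaussian UV beta band, with all
shape coefficients functions of the peak wavelength. The A1 alpha band uses
A = 69.7, B = 28, b = 0.922, C = −14.9, c = 1.104, D = 0.674 and
`a(λmax) = 0.8795 + 0.0459·exp(−(λmax−300)²/11940)`; the A2 alpha band uses
`A(λmax) = 62.7 + 1.834·exp((λmax−625)/54.2)`, B = 20.85, b = 0.9101,
C = −10.37, c = 1.1123, D = 0.5343 and
`a(λmax) = 0.875 + 0.0268·exp((λmax−665)/40.7)`. Both beta bands have
amplitude 0.26. Every template is renormalized to peak 1 after every
transformation; relative-sensitivity fitting requires a common scale and
the renormalization supplies it.

The six cone classes carry fixed A1 anchors: SWS1 368, SWS2b 423, SWS2a
456, RH2b 484, RH2a 523 and LWS 560 nm. The two RH2a paralogs (519 and
528 nm) are pooled at their 523 nm average; the source material also
mentions using a 532 nm spectrum for this pooled class, an internal
inconsistency we resolve in favor of the stated 523 nm average.

A retina with A2 proportion `a` carries the mixture
`A(a) = (1−a)·A1(λmax,A1) + a·A2(λmax,A2)`. The full-A2 peak is given by a
monotone quadratic shift relation anchored exactly at the two published
pairs (RH2a 523 → 560, LWS 560 → 626 nm) with zero shift below its vertex
near 413 nm, reflecting that short-wavelength pigments barely shift. The
effective peak of a mixture is read off the curve (argmax on the 1 nm
grid), not interpolated analytically; for SWS1 and SWS2b, whose shift is
essentially zero, this argmax can drift a few nm with `a` because the A2
band shape is broader — the monotone-shift property is only meaningful for
classes with a real shift. Published per-individual fitted peaks at A2 = 0
(e.g. 374 nm for SWS1 against the 368 nm anchor) are not exactly
reproducible from the mixture model; the package reports mixture-model
effective peaks and treats the anchors as fixed.

Lens transmission is a single multiplicative ocular-media correction
followed by renormalization. A synthetic logistic UV cutoff with half
transmission at 350 nm (`synthetic_lens()`) stands in where no measured
curve is supplied; it is labelled synthetic because it is not a measured
lens spectrum.

## Identifying functional cone mechanisms

Identification uses sensitivity curves from (usually three) background
conditions: spectrally flat control, long-wavelength isolation (LW), and
intense or dim short-wavelength isolation (SW, Dim-SW). An isolation
condition is named for the mechanisms it spares: its background light
adapts the complementary mechanisms. Operationally the LW background is
short-pass-shaped light and the SW/Dim-SW backgrounds are long-pass-shaped
light; the control carries equal total photon flux, and Dim-SW carries a
tenth of the SW flux.

Peak candidates are the strict local maxima (plateaus resolve to the
shorter wavelength) of the condition-averaged log curve, whose per-point
noise is reduced by the square root of the number of conditions;
wavelengths where at least two single conditions show coincident local
maxima are added as candidates when averaging happens to blur a notch.
Acceptance applies two criteria. First, the candidate must appear under at
least two conditions, where "appears" tolerates 0.1 log10 units of notch
fill so that measurement noise does not delete an otherwise clear peak;
spectral regions sloping monotonically away never appear. Second, in the
UV range (≤ 400 nm) the amplitude must track the adaptation: larger under
the background giving the SWS1 mechanism its smallest catch share than
under the background giving it the largest. A UV bump that instead shrinks
is the beta band of mid/long-wavelength cones, not a UV cone. Outside the
UV range the tracking direction is not diagnostic — spectrally adjacent
mechanisms respond almost identically to the background tilts — so
presence under two conditions governs. Backgrounds are ranked by catch
*share* (catch divided by the background's mean drive across mechanisms)
so that a dim variant of a condition does not masquerade as the sparing
background merely by being dim.

The retinal A2 proportion comes from the long-wavelength limb of the
averaged curve (the points from the longest accepted peak outward), where
the chromophore shift is largest and opponent interactions are absent.
RH2a and LWS mixtures are fitted with free A2 proportion and free
magnitude. Model selection between the two pigments uses the linear-scale
fit; the A2 proportion of the winner is then refined on the log scale,
which weights the far tail where the candidates differ most and localizes
the shift much more precisely. A high-A2 RH2a and a low-A2 LWS have nearly
coincident peaks, so when the two limb fits are within 0.02 R² of each
other the decision falls to which hypothesis places the whole template set
(one shared A2 proportion per individual) closest to the remaining
observed peaks; a clearer limb verdict is final.

Each accepted peak is then assigned a pigment class. Candidates are the
classes whose effective peak (at the individual's A2 proportion,
lens-corrected) lies within 40 nm; a magnitude coefficient is fitted over
a local ±40 nm window and the assignment maximizing total fit R² under a
one-class-per-peak constraint is found by exact search. Fit quality rather
than raw peak distance adjudicates because opponent interactions narrow
sensitivity peaks and displace them from the template peak — which is also
why R² well below 1 is expected and observed even for noise-free data.

The resulting pigment set is matched against the packaged subset
catalogue. Subset labels in the catalogue are species-scoped: the same
pigment set carries different labels in different species, one label
denotes different sets across species, and two labels within one species
share a set and differ only in fitted peak wavelengths. Matching therefore
prefers rows of the individual's species and, among those, the nearest
peak-wavelength constellation; where a set is inherently ambiguous within
a species, label-level recovery cannot be guaranteed and set-level
identity is the meaningful outcome.

## The opponency (multiple-cone mechanism) model

Between two sensitivity notches — strict local minima of the linear
relative curve, plus the curve ends — sensitivity is modelled as a signed
weighted template sum `S(λ) = Σ k_i·A_i(λ)`, positive weights excitatory
and negative weights inhibitory (opponent). For each segment every
combination of one to three of the individual's pigments is fitted by
unconstrained linear least squares under every background. Selection
follows three rules: combinations whose weight signs differ across
backgrounds are discarded; among the survivors the smallest combination
whose mean R² is within a parsimony margin (default 0.02, a numerical
choice — "minimum possible number of cones" needs a quantitative rule) of
the best is taken; ties resolve to the best mean R². The dominant cone of
a segment is the one contributing most at the segment's sensitivity peak,
and always carries a positive weight in a sane fit. Both per-segment and
concatenated (stitched) R² are reported, since a single whole-curve R² is
otherwise ambiguous. With at most six candidate pigments the search is
exhaustive (41 combinations per segment) and bit-for-bit reproducible.

## Quantum catch and expression

Quantum catch is the 300–800 nm trapezoidal integral of absorbance times
photon irradiance. Irradiance inputs are assumed to be photon (quantal)
spectra; an explicit energy-to-photon converter exists but is never
applied implicitly. For reflectance-based conspicuousness the irradiance
is replaced by sidewelling irradiance times pattern reflectance, with the
LWS template built at A2 = 0.5 by convention.

Relative opsin expression treats the amplification efficiency `E` as a
fraction, so the base `1 + E` lies in [1, 2]; percent-style efficiencies
are rejected with an explanatory error rather than silently rescaled.
Expression fractions are `(1+E_g)^(−Cq_g)` normalized over the genes of an
individual. Technical replicates are averaged on load and no-template /
no-RT control rows are excluded with a logged count. Sex differences use
pooled-variance t-tests per gene (a Welch option exists), preceded by
Kolmogorov-Smirnov normality and Cochran's C homogeneity reports, at the
Bonferroni-corrected α = 0.05/6 = 0.0083 for six genes. Cochran's C uses
the standard F-based bound with the average group size.

Cohort tallies report one decimal (table convention) or integer percent
(prose convention); the exact ratios are always available. The Fisher test
for pigment presence across the three species enumerates all 2×3 tables
with the observed margins and sums the probabilities of tables no more
probable than the observed one — the common two-tailed definition; an
independent implementation (the network algorithm in `stats`) serves as an
oracle in the tests, never as the implementation.

## What the synthetic generator emulates

`simulate_cohort()` draws individuals per species and sex with the
published group sizes and per-group subset frequencies, A2 proportions
uniform on 0–0.65 (the published per-individual range), and opponent
weights uniform on 0.3–0.6 — a magnitude that produces notch depths
comparable to published curves. A sensitivity curve is built segment-wise:
boundaries at the midpoints between adjacent effective peaks, each
segment carrying its cone's absorbance minus the weighted absorbances of
its spectral neighbors, normalized to peak 1 within the segment — the
same piecewise signed-sum structure the opponency model fits.

Chromatic adaptation is modelled divisively with a saturating Weber gain,
`g = ((Q0 + Q)/(Q0 + Q_control))^(−w)`, with exponent `w = 0.25` and a
dark-light constant `Q0` of 0.2 times the mean control catch. The
functional form and both constants are this package's own modelling
choice: the methodology describes adaptation operationally, not
mathematically. The constants were chosen so that, as in the published
curves, every sensitivity peak remains visible under every background
while its amplitude tracks the adaptation, and so that the dim and intense
short-wavelength conditions differ (a pure power law of the catch ratio
makes them identical after normalization, and strong exponents erase
adjacent peaks on a 20 nm grid entirely).

Opponent weights are rejection-sampled per individual so that every
functional cone manifests a peak resolvable on the measurement grid under
the control and at least one isolation background — the defining property
of a functional mechanism in this protocol; if the configured weight range
admits no such structure for a subset's spectral packing, stronger and
then weaker ranges are tried. Measurement noise is multiplicative
log-normal on sensitivity with σ the standard deviation of the natural
log (≈ fractional noise, default 0.05). RI records invert the
Naka-Rushton analysis exactly: eight irradiance levels spanning
`LogK ± 2`, per-individual `Rmax` uniform on 60–140 µV, Gaussian response
noise (default 2 µV). qPCR records invert the expression relation with
efficiencies uniform on 0.85–1.0 and Gaussian Cq noise (default 0.15
cycles), with a built-in preset in which *M. auratus* sexes differ in
RH2b/RH2a expression and *P. taeniolatus* sexes are matched.

The generator does **not** emulate raw voltage traces, eye optics,
photopigment bleaching, underwater radiative transfer, or any biological
source of curve asymmetry beyond linear opponency. Passing recovery tests
therefore show that the analysis chain is internally consistent and
correctly inverts data of the assumed structure at realistic noise — not
that it would be equally reliable on recordings violating those
assumptions (e.g. nonlinear adaptation or non-template-shaped absorbance).

Recovery is validated on two designs: the full cohort emulation above, and
a calibration grid with one individual per catalogue subset row at A2
pinned to 0, 25 and 50%. On the grid, noise-free recovery of the
generating pigment set is complete and recovery at σ = 0.05 exceeds 90%.
On the cohort design with continuous A2, occasional failures remain in the
spectrally degenerate zone where a high-A2 RH2a and a low-A2 LWS are
nearly indistinguishable — a genuine identifiability limit, not a
numerical artifact.

## Problem sizes and determinism

The shipped tests run cohorts of 34–42 individuals, 200-replicate power
simulations for the qPCR sex tests, and 500-replicate noise studies for
the Naka-Rushton stage; these sizes give stable statistics for every
stochastic claim while keeping the whole suite fast. All generators are
byte-deterministic under a fixed seed; all fits are deterministic by
construction (profiled 1-D optimization, exact linear algebra, exhaustive
combination search).

## Known limitations

- Identification operates on the 20 nm measurement grid; pigments whose
  effective peaks fall within about one grid step are resolvable only
  through their opponency structure, and at high noise their recovery
  degrades first.
- The A2 proportion estimated from the long-wavelength limb carries a
  small positive bias when the limb is contaminated by opponent
  subtraction near the peak; the log-scale refinement reduces but does
  not eliminate it.
- Subset labels 9/10 (and 2/4 across species) of the published catalogue
  are not functions of the pigment set alone; label-level agreement is
  not a well-defined target for those rows.
- The Fisher enumeration is exponential in the table margins and intended
  for the small cohort tables of this design (it completes in well under
  a second there).
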