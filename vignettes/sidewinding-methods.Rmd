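---
title: "Extracting and modeling sidewinding kinematics: methods and design choices"
author: "sidewindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and modeling sidewinding kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sidewinding is the asymmetrical gait of several desert vipers: sections of
the body rest in static contact with the sand while the sections between them
are lifted up and forward to the next contact patch, so the animal travels
obliquely to its own body axis. `sidewindr` implements a complete analysis
chain for intraspecific studies of this gait:

1. extraction of whole-animal and waveform kinematics from digitized 3-D
   marker trajectories (10 dorsal markers, high-speed video),
2. allometric scaling statistics (outlier screening, AICc-ranked ANCOVA model
   search, reduced-major-axis slopes with isometry tests), and
3. observed-variable path analysis linking morphology, kinematics and speed
   by maximum likelihood on covariance matrices.

Because raw field data of this kind are rarely deposited, the package also
contains a first-class synthetic-data module that generates marker
trajectories and morphometric tables with known ground truth, so every stage
of the chain is testable end to end.

# Smoothing and differentiation

Digitized coordinates are smoothed with a Savitzky–Golay (local polynomial)
filter with uniform weights: displacement with 3 passes, and the velocities
and accelerations obtained by first- and second-order central differences
with a single pass, all with polynomial order 4 and a span of 143 frames at
the 250 Hz effective frame rate. To remove edge effects, 150 leading and 100
trailing frames are dropped from every series. All of these are configuration
parameters (`smoothing_config()`) with the defaults above.

Filter edge treatment before trimming is a polynomial fit on the truncated
end windows (the `signal::sgolayfilt` convention); since the edges are
discarded anyway, this choice is immaterial.

**Design bandwidth.** An order-4, span-143 filter passes a sinusoid
essentially unchanged below about 1 Hz (gain 0.997 at 1.0 Hz), attenuates
visibly by 1.8 Hz (gain 0.93) and strongly above 2 Hz. Any pipeline built on
these settings is therefore only faithful for cycle frequencies up to roughly
1–1.5 Hz. The synthetic study conditions use 0.5–1.0 Hz, which is realistic
for routine (non-escape) sidewinding and lies inside that bandwidth; the
recovery tests show what the pipeline can do *within* its design band and say
nothing about faster locomotion.

# Kinematic variables

* **Centroid speed and acceleration.** The centroid of all 10 markers stands
  in for the center of mass; velocity and acceleration come from first- and
  second-order central differences of the smoothed centroid displacement,
  and mean/peak values of their norms summarize the trial.
* **Marker peak speed and height lifted.** Peak speed is averaged over
  markers 3–7 and height lifted over markers 2–8, the bands that are
  consistently closest to the trial mean when per-marker values are replaced
  by z-scores (head and tail markers are contaminated by non-locomotor
  behavior). `zscore_select()` re-derives such bands from data: it returns
  the contiguous band minimizing mean |z|, with ties going to the longest
  band. The height baseline is each marker's own trial minimum z, because an
  absolute substrate height is not observable in general recordings.
* **Waveform geometry.** Markers 4–9 are used. When the planar angle formed
  at a marker by its two neighbours reaches a temporal local minimum, that
  marker sits at a wave extremum (crest or trough); the extremum kind comes
  from the sign of the planar cross product of the neighbouring segments.
  Events of the same physical extremum are chained across markers (the wave
  travels head to tail, so passage times increase with marker index by well
  under one period) and linearly interpolated in time, yielding each
  extremum's position at every frame it spans. At each frame, two same-kind
  extrema with the opposite extremum between them define a triangle:
  wavelength is the distance between the same-kind pair, the skew angle is
  the signed angle between the triangle's median and the perpendicular of
  the pair line (positive = tilted head-wards), and the peak-to-peak
  amplitude is the median length times the cosine of the skew. Trial values
  average over all triangles and frames. Frequency is the reciprocal of the
  median of all pooled periods between same-kind events at a marker —
  the median makes the estimate robust to an occasional spurious event.

Three numerical choices deserve comment:

* **Angle-minimum prominence.** Noise creates shallow spurious minima in the
  angle series; minima must have at least 5° prominence (configurable).
* **Event-time refinement.** On a skewed wave the angle minimum is
  systematically offset from the true apex passage: at the minimum, the body
  tangent parallels the (tilted) neighbour chord rather than the wave axis,
  which biases the skew angle away from zero by 1.5–3°. Because steady-state
  sidewinding is a shape-invariant traveling wave, a marker sits exactly on
  an apex when its lateral excursion — detrended by the whole-animal lateral
  drift, whose rate equals the centroid's because the axial advance is
  orthogonal to the lateral axis — is locally extremal. `refine_extrema()`
  relocates each event to that nearby lateral extremum. The refinement was
  validated against the analytic extremum paths of the generator.
* **Track extension.** A marker band spanning less than one full body
  wavelength never observes two same-kind extrema simultaneously. Under the
  steady-state assumption extremum paths are linear in time, so each track
  is extended by its least-squares line up to 0.75 periods beyond its
  observed span (configurable). This is the same steady-state assumption
  that underlies the triangle geometry itself.

**Body axis versus travel direction.** Crest/trough ordering and the skew
sign need a head-wards direction. The net centroid displacement (travel
direction) could serve, but the marker indexing already provides the body
axis directly (marker 1 is the head), so the implementation uses the
head-to-tail polyline direction instead; both choices are invariant under
planar rigid motions. What no planar information can provide is the gait's
handedness: mirror-image trials produce identical marker geometry with
opposite cross-product signs, so the raw skew sign is only consistent within
a handedness class. Trials must be annotated left/right (as scored from
video), and `apply_handedness_sign()` negates left-handed trials so that
positive skew always means a head-wards tilt.

Trials too short for a complete extremum triangle report `NA` for the wave
variables — missing, never fabricated.

# The synthetic-data generator

`generate_trajectory()` produces an exactly shape-invariant traveling wave
with static ground contact:

* The planar template is one straight **contact flank** per cycle (the track
  segment, a fraction `contact_frac` = 0.7 of the trough-to-crest flank,
  traversed during the contact fraction `duty` of the cycle) joined to a
  single **cubic Bézier swing** that carries the body over the crest, past
  the trough and into the next contact segment with continuous direction and
  speed. Both true lateral extrema lie inside the smooth swing; a
  fixed-point iteration adjusts the underlying corner geometry so the
  template's true extrema reproduce the requested wavelength, peak-to-peak
  amplitude and skew exactly (to 1e-6).
* The whole pattern translates at the constant velocity that cancels the
  contact-flank pattern speed, so contact-phase markers are *exactly*
  stationary, a `duty` fraction of markers is static at every instant, and
  every marker advances by exactly one stride along the travel axis (+y)
  per cycle. Stride — and hence mean speed = frequency × stride — is
  therefore a *derived* quantity, fixed by wavelength, amplitude, skew, duty
  and the contact fraction, not an independent dial.
* Vertical lift is `H sin²(π τ)` across the swing phase and zero during
  contact (C¹ at lift-off); handedness mirrors x; i.i.d. Gaussian noise
  (default SD 0.1 cm, the scale of careful 3-D digitization error) is added
  last; everything is reproducible from the seed.

Default geometry: 10 markers (head, neck, six evenly spaced trunk markers,
cloaca, tail tip) on a body that carries about 1.7 wave arc lengths, matching
real sidewinders; wavelength ≈ 0.35 SVL, amplitude ≈ 0.25 SVL, lift ≈
amplitude/8 in the study simulator.

What the generator does *not* emulate: turning and acceleration phases,
within-trial parameter drift, digitization dropouts, marker occlusion and
non-locomotor head/tail behavior. Passing recovery tests therefore
demonstrate correctness of the extraction pipeline under its stated
steady-state assumptions, not robustness to every pathology of real video.

`generate_morphometrics()` draws log-normal SVL and power-law traits
(`trait = a·SVL^b·10^ε`, isometric exponents by default: 1 for linear
measurements, 3 for mass) with optional log-scale sex and age offsets, and
discrete meristic counts (female-biased ventrals, male-biased subcaudals)
that do not scale with SVL. `simulate_study()` ties both together: one
representative trial per kinematics individual, wavelength reflecting
relative body width (stouter snakes form looser curves), frequency varying
widely and independently of size, skew positively correlated with frequency,
and contact duty varying between individuals so that speed keeps unexplained
variance beyond the wave-geometry predictors, as real locomotor data do.

# Scaling statistics

Morphometric traits are log10-transformed. Outliers are screened per age
group from standardized residuals of log trait on log SVL + sex; a point is
flagged when |z| > 3 **and** it is separated from the next-most-extreme value
by more than 1 SD. The published rule reads "and/or"; the conjunction is the
conservative reading and the default, with `rule = "or"` available. The
screen is applied once, before all further analyses of that trait.

`ancova_search()` fits the full factorial model
(SVL + sex + age + all interactions) and every marginality-respecting
submodel — the full lattice rather than one stepwise path, which is cheap at
this scale and independent of path order — ranks them by
AICc = AIC + 2k(k+1)/(n−k−1), and reports Type III tests (sum-to-zero
contrasts, which Type III requires to be meaningful) for the selection. For
kinematic variables, body temperature enters as an additive covariate only
(no interactions). Two selection rules are provided: the default picks the
lowest AICc; `richer_within_2` picks, among models within 2 AICc units of
the best, the one with the most predictors — useful when the goal is a more
granular view of group-specific scaling, at the price of admitting weakly
supported terms. AICc-family selection is deliberately liberal (a spurious
one-parameter term lands within 2 AICc units with substantial probability),
so recovery guarantees are stated in terms of *detection*: effects of at
least two residual SDs are contained in the selected model essentially
always, while occasional extra terms are expected behavior, not a defect.

Scaling itself uses reduced-major-axis (standardized major axis) regression,
appropriate because both axes carry error: slope = sign(r)·sd(y)/sd(x), CI
from B = t²(1−r²)/(n−2) as slope·(√(B+1) ± √B), with OLS slopes reported
alongside. A trait is isometric when the expected exponent (1 for linear
traits, 3 for mass) lies inside the RMA slope's 95% CI; otherwise positive or
negative allometry by the side of the interval. Samples are split into the
groups suggested by each trait's best ANCOVA model before slope fitting.
Scale counts are excluded from scaling by default (configuration, not code):
dorsal row counts barely vary, and ventral counts violate variance
homogeneity and do not scale with SVL.

# Path analysis

Variables entering the path analysis are residuals from OLS regressions on
log SVL (plus sex and/or age when the variable's best ANCOVA model retained
them); skew angle is signed and therefore not log-transformed. Pearson
correlations among residuals are reported with pairwise-complete tests.

`fit_path_model()` minimizes the maximum-likelihood discrepancy
F = log|Σ(θ)| + tr(S Σ⁻¹) − log|S| − p over the free paths, residual
covariances and variances, with Σ(θ) = (I−A)⁻¹ S_res (I−A)⁻ᵀ implied by the
acyclic path structure. χ² = (n−1)F at the optimum; df = p(p+1)/2 − free
parameters; standard errors from the inverse observed information; RMSEA =
√(max(χ²−df,0)/(df(n−1))); per-path likelihood-ratio tests refit with the
path fixed to zero. Optimization is BFGS from sample-moment starts with 10
seeded jittered restarts; non-convergence is flagged, never papered over.
The default input is the correlation matrix of residuals, so coefficients
are standardized and squared coefficients read as variance explained;
covariance-matrix fitting gives the unstandardized solution, and the two are
equivalent up to scaling (tested). n is the number of complete-case
individuals for the model's variable set.

The default seven-variable model — sample size limits models to seven
variables — sends frequency, wavelength, amplitude and skew to mean centroid
speed, body width at 50% SVL to wavelength, and includes height lifted as a
correlate. Free covariances: all exogenous pairs, plus the wavelength
residual with each exogenous non-parent. That parameterization has 26 free
parameters against 28 moments: df = 2. The final outcome's residual covaries
with nothing; mediator residuals covary with exogenous non-parents only.

The candidate menu (`sidewinding_path_menu()`) is a documented
reconstruction: all models share the frequency/wavelength/amplitude → speed
core; morphological subsets of {tail length → frequency, ventral count →
wavelength, mass → wavelength, width50 → wavelength} of sizes 1–3, never mass
and width50 together (redundant stoutness measures); the seven-variable cap
is filled with skew and/or height (both for one-trait subsets, one or the
other for two-trait subsets, neither for three-trait subsets), giving
4 + 10 + 2 = 16 candidates. `model_menu_search()` rejects candidates with
significant lack of fit (p < 0.05), ranks survivors by RMSEA and breaks ties
by AICc = χ² + 2k + 2k(k+1)/(n−k−1). When any surviving model has n ≤ k+1
the AICc correction is undefined, so the tie-break falls back to AIC —
at n = 26 with ~25-parameter models this is the usual case, and it is the
main caveat in comparing richly parameterized models on small samples.

# Problem sizes used in validation

The bundled tests validate parameter recovery on a 36-trial grid (cycle
frequencies 0.5–1.0 Hz, wavelengths 18/24 cm, amplitude-to-wavelength ratios
0.5–0.7, skews −5° to 20°, lift = amplitude/8, noise 0.1 cm, both
handednesses), statistical recovery on 100-replicate simulations (ANCOVA
detection at n = 200, RMA CI coverage of a true slope 1.2 at n = 500,
path-parameter coverage within 3 SEs at n = 2000), and the analysis scripts
run a 74-individual, 26-trial study. These sizes were chosen to mirror a
realistic single-species field study while keeping the whole suite quick to
run.

# Known limitations

* The waveform method assumes steady, roughly straight sidewinding with one
  dominant mode; turning or accelerating trials must be truncated or
  discarded upstream.
* With 10 markers no midline spline is attempted; all waveform quantities
  come from the extremum geometry.
* Measurements degrade predictably outside the smoothing filter's design
  band (above ~1.5 Hz at 250 Hz with span 143): peak-to-peak amplitude and
  height lifted attenuate first.
* Handedness cannot be inferred from marker coordinates and must be
  annotated.
* Path models are observed-variable only: no latent variables, no multi-group
  fitting, complete cases only.
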