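# sidewindr

Tools for studying how body size and shape relate to sidewinding locomotion
in snakes. Sidewinding is the asymmetrical gait of desert vipers such as the
sidewinder rattlesnake: body sections rest in static contact with the sand
while the sections between them are lifted up and forward, so the animal
travels obliquely to its own body axis. `sidewindr` takes digitized 3-D
marker trajectories (10 dorsal markers tracked on high-speed video) and a
morphometrics table, and answers three questions a locomotor-scaling study
asks:

1. **What are the kinematics of each trial?** Whole-animal (marker centroid)
   mean/peak speed and acceleration; per-marker peak speed (markers 3–7) and
   height lifted (markers 2–8); and the body-wave geometry — cycle frequency,
   wavelength λ, peak-to-peak amplitude A and signed skew angle φ — from the
   times and places at which markers pass the wave's crests and troughs.
   Displacement is smoothed with a 3-pass order-4 Savitzky–Golay filter
   (span 143 frames at 250 Hz), velocity and acceleration come from central
   differences with a single smoothing pass, and 150 + 100 edge frames are
   trimmed. The wave triangle of two same-kind extrema and the opposite
   extremum between them gives λ = |P₁P₂|, skew = signed angle between the
   triangle's median and the perpendicular of P₁P₂ (positive = head-wards),
   and A = |median|·cos(φ); frequency is the reciprocal of the median
   inter-extremum period.
2. **How do traits scale with body size?** Outlier screening on standardized
   residuals, an AICc-ranked ANCOVA model search over SVL × sex × age (body
   temperature as an additive covariate for kinematics), and reduced-major-
   axis regression, slope = sign(r)·sd(y)/sd(x) with CI slope·(√(B+1) ± √B),
   B = t²(1−r²)/(n−2), tested against isometric expectations (1 for linear
   traits, 3 for mass).
3. **What drives speed?** Observed-variable path analysis of size-corrected
   residuals by maximum likelihood on the covariance (default: correlation)
   matrix: χ² = (n−1)·F lack-of-fit, RMSEA = √(max(χ²−df,0)/(df(n−1))),
   per-path likelihood-ratio tests, and a 16-model candidate menu compared by
   RMSEA with AICc tie-breaks. The default seven-variable model sends
   frequency, wavelength, amplitude and skew to mean centroid speed and body
   width (50% SVL) to wavelength, with height lifted as a correlate (df = 2).

Because raw data of this kind are rarely deposited, the package includes a
first-class synthetic-data module: an exactly shape-invariant traveling-wave
generator with static ground contact, configurable wave parameters, vertical
lift, handedness and noise, plus a log-normal allometric morphometrics
generator — every stage of the pipeline is validated against known ground
truth. See the methods vignette
(`vignettes/sidewinding-methods.Rmd`) for the model details and design
decisions.

## Worked example

The `analysis/` scripts run a complete study on simulated data: 74
individuals measured, 26 with one representative sidewinding trial each.

```sh
Rscript analysis/01_simulate.R            # writes results/fixtures/
Rscript analysis/02_extract_kinematics.R  # results/trial_kinematics.csv
Rscript analysis/03_scaling.R             # scaling tables
Rscript analysis/04_path_analysis.R       # correlations + path models
```

Output of the last stage (seed 20160701):

```
default model: chi2 = 0.285, df = 2, p = 0.867, RMSEA = 0.000 (n = 26)
  frequency -> speed      0.861 +/- 0.048  (LRT chi2 = 65.38, p = 6.17e-16)
  -> frequency explains 74% of speed variance (squared coefficient)
  wavelength -> speed     0.051 +/- 0.041  (LRT chi2 = 1.46, p = 0.227)
  amplitude -> speed      0.326 +/- 0.041  (LRT chi2 = 31.34, p = 2.16e-08)
  skew -> speed           0.046 +/- 0.049  (LRT chi2 = 0.89, p = 0.346)
  width50 -> wavelength   0.908 +/- 0.084  (LRT chi2 = 43.52, p = 4.19e-11)
```

Read: the hypothesized model is consistent with the simulated data (no
lack of fit, RMSEA 0); snakes in this synthetic population modulate speed
mainly through cycle frequency (the standardized coefficient 0.861 squares
to 74% of speed variance), stouter snakes form longer waves
(width50 → wavelength 0.908), and skew angle has no direct effect on speed —
the same qualitative structure the extraction and modeling chain is designed
to detect in real trials. The scaling stage (`03_scaling.R`) prints RMA
slopes per trait with isometry verdicts; with the default isometric
generator all linear traits come out isometric (slope CI covering 1) and
mass isometric against its expectation of 3.

The same functions work interactively:

```r
library(sidewindr)
w  <- wave_params(frequency_hz = 0.8, wavelength_cm = 20, amplitude_cm = 14,
                  skew_deg = 12, lift_height_cm = 1.75, duty = 0.5)
gt <- trial_ground_truth(w, n_frames = 1800, noise_sd_cm = 0.1, seed = 1)
tr <- generate_trajectory(gt)
k  <- smooth_trial(tr)
extract_trial_kinematics(k)
#   centroid_mean_speed ~ gt$centroid_speed_cm_s, frequency_hz ~ 0.8,
#   wavelength_cm ~ 20, amplitude_cm ~ 14, skew_deg ~ 12 ...
```

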