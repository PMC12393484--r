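---
title: "Models and methods: brightness mapping, single-molecule tracking, and nuclear texture phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tfquant implements three quantitative single-cell imaging analyses that are
routinely combined to characterise how a transcription factor behaves in the
nucleus — how much it self-associates (Number & Brightness), how it moves and
binds chromatin (single-molecule tracking), and how cell populations shift
their nuclear phenotype under perturbation (texture-based profiling). Each
analysis ships with a simulator that generates inputs with known ground
truth, so every stage can be verified by parameter recovery against
closed-form expectations.

## Number & Brightness (N&B)

For each pixel of a fluctuation image series $F(t)$ the first two temporal
moments give the *apparent brightness*

$$B = \frac{\sigma^2}{\langle F \rangle},$$

which on a photon-counting detector equals $\varepsilon + 1$ for mobile
particles of molecular brightness $\varepsilon$ (detected counts per molecule
per dwell time); the $+1$ is the shot-noise contribution. Because
$\varepsilon$ scales linearly with stoichiometry, a monomer calibration
($\varepsilon = \mathrm{median}(B) - 1$ over a monomer-control acquisition)
extrapolates the expected brightness of dimers ($2\varepsilon + 1$) and
tetramers ($4\varepsilon + 1$), and *brightness cursors* — intervals on the
B axis — assign each pixel an oligomeric class.

Design choices where the procedure is conventionally underdetermined:

* **Variance convention.** Unbiased ($n-1$) temporal variance; at 100 frames
  the difference from the population variance is far below recovery
  tolerance.
* **Cursor bounds.** Only the class *levels* are fixed by the calibration;
  the interval widths are set at the arithmetic midpoints between adjacent
  levels (maximum-margin partition), with the monomer interval opening at
  $B_1 - \varepsilon/2$ and everything below it treated as background and
  excluded from the monomer/dimer/oligomer renormalization. The oligomer
  reference level is the tetramer ($s = 4$).
* **Calibration statistic.** The median, robust against bright aggregates.
  A caveat documented here because it matters at low signal: the per-pixel
  sampling distribution of $B$ at 100 frames is right-skewed, so its median
  sits 2–3% below its mean; converting $B - 1$ to $\varepsilon$ amplifies
  that offset by $1/\varepsilon$. For dim calibrations
  ($\varepsilon \approx 0.2$) this is a systematic $\sim\!10\text{–}15\%$
  underestimate; at $\varepsilon \ge 0.5$ it is below 5%. Calibration
  acquisitions should therefore use constructs bright enough that
  $\varepsilon \gtrsim 0.5$, or longer series.

### Detrending

Slow drift from cell movement or photobleaching inflates the temporal
variance and biases $B$ upward. `detrend_stack()` subtracts a centered
boxcar moving average (default window: 10 frames, 10% of a 100-frame
acquisition; edge frames use truncated windows) and adds the pixel's global
mean back. Subtracting a $w$-frame local mean also removes $1/w$ of the
genuine fluctuation variance — a 10% brightness deflation at $w = 10$ that
would swamp the quantity being estimated — so the deviations are rescaled by
$\sqrt{w_t/(w_t - 1)}$, which restores the white-noise variance exactly, and
the trace is re-centred so the first moment is preserved to machine
precision.

The bleaching model in the simulator follows the physics that makes this
detrend work: bleaching removes fluorophores, so the ramp multiplies the
*occupancy* mean, leaving per-molecule brightness intact. The local
variance/mean ratio then stays $1 + s\varepsilon$ at every frame and only
the slow mean drift — which the moving average removes — contaminates the
pooled moments. (Scaling the detected counts themselves would deflate
brightness multiplicatively, and no moving-average procedure could undo it.)
The drift bias on a raw, undetrended stack grows with the mean count rate;
the detrending-rescue check uses a bright acquisition (50 monomers per focal
volume, 30% bleach) where the raw calibration is biased by $\sim\!40\%$ and
the detrended one recovers $\varepsilon$ to within a few percent.

### Simulator

`simulate_ffs_stack()` draws, per pixel and frame, species occupancies from
Poisson laws and detected counts from Poisson laws with mean
(occupancy $\times\, s \varepsilon$) — a compound process whose
variance/mean ratio is exactly $1 + s\varepsilon$. Defaults mirror a typical
fluctuation acquisition: 100 frames of $256 \times 256$ pixels, 41 nm
pixels, 12.5 µs dwell. Frames are treated as independent samples; raster-
scan temporal correlation inside a frame, detector excess noise and optics
(PSF) are deliberately not modelled, so the simulators validate the moment
arithmetic, not image formation.

## Single-molecule tracking (SMT)

Two acquisition presets are built in: *fast* (20 ms frames, maximum
expected $D = 3\,\mu m^2/s$, detection box 7 px) for displacement and bound-
fraction analysis, and *slow* (500 ms frames, $D_{max} = 0.33\,\mu m^2/s$,
box 9 px) for residence times. Both allow a one-frame blinking gap, at most
3 linking competitors, and exclude cells with fewer than 500 trajectories.

* **Detection** is a local-maximum detector with intensity-weighted centroid
  refinement inside the box — a deliberately simple stand-in for
  hypothesis-test detectors, exposing an intensity threshold rather than a
  localization p-value (documented as non-equivalent).
* **Linking** is deterministic cost minimisation: candidate pairs within the
  gating radius $r(g) = \sqrt{4 D_{max}\, \Delta t\, (g+1)}$ (gap
  $g \le$ blink allowance) are accepted greedily in order of squared
  displacement, each detection considering only its 3 nearest candidate
  tracks. Every localization ends up in exactly one trajectory. A
  consequence of this hard gate worth knowing: a Brownian molecule at
  diffusion coefficient $D$ exceeds $r(0)$ on a fraction
  $e^{-D_{max}/D}$ of its steps, i.e. $\sim\!5\%$ at $D = D_{max}/3$ —
  track fragmentation at that loss rate is expected behaviour, not a linking
  defect. The linking-oracle check therefore runs at $D = D_{max}/6$
  (0.5 µm²/s under the fast preset), where the gate is essentially never
  binding and the measured loss isolates assignment and gap-bridging
  quality ($>99\%$ of links recovered at $\le 5$ molecules/frame with 10%
  blinking).
* **Diffusion coefficients** come from the time-averaged MSD at lags 1–4
  frames (gap-aware), fitted by least squares with a free intercept that
  absorbs the localization-error offset $4\sigma_{loc}^2$ (through-origin
  fit available). Non-positive slopes are floored at $10^{-4}\,\mu m^2/s$ so
  $\log_{10} D$ is defined; floored tracks always count as confined. Short
  tracks make the per-track estimate noisy and its median sits
  $\sim\!10\%$ below truth at 20-frame tracks — well inside the 15%
  recovery band the checks use, but worth remembering when comparing
  absolute values across studies.
* **Mobility threshold.** The confined/non-confined boundary is the minimum
  of the Gaussian-kernel density (Silverman bandwidth) between the two
  highest modes of the control condition's $\log_{10} D$ profile — an
  operationalisation of "inflection point on the diffusion profile". If the
  profile is unimodal the boundary falls back to the decision point of a
  two-component Gaussian mixture. The same threshold is reused for all
  conditions.
* **Residence times** (slow preset) are trajectory lifetimes in frames
  $\times\,\Delta t$. They are fitted with a two-exponential mixture —
  short component: target search; long component: stable, regulation-
  associated binding — by maximum likelihood with right-censoring. Because
  observed durations are whole frames, the default likelihood is
  *interval-censored*: an uncensored $k$-frame dwell contributes
  $P((k-1)\Delta t < T \le k\Delta t)$ and an event surviving into the last
  observable frame contributes $P(T > (k-1)\Delta t)$. Fitting the
  continuous density to 0.5 s-discretized 1 s dwells would by itself bias
  the short time scale by $\sim\!25\%$; the interval likelihood removes
  that bias exactly. Optimisation is multi-start (5 seeded initialisations
  on log/logit scales); a fitted time-scale ratio under 2 triggers a
  degeneracy warning. Photobleaching correction
  $1/\tau_{corr} = 1/\tau - k_{bleach}$ is opt-in with a user-supplied rate.

The track simulator assigns each molecule one diffusive population (no
within-track state switching — the underlying switching kinetics are not
identifiable from the data these analyses consume), staggers appearances
uniformly over the acquisition so the per-frame density is controllable,
adds per-axis Gaussian localization error, and drops interior frames with
at most one consecutive miss, matching the one-frame gap allowance.

## Texture-based population phenotyping

Per-cell feature vectors are computed from single-nucleus crops and masks:
13 gray-level co-occurrence (Haralick) features on 64-level quantized
masked intensities, accumulated as symmetrized co-occurrence matrices over
the four directions at pair distances {1, 2, 4, 8} px and averaged over
directions, plus the mean, SD, skewness and kurtosis of the masked
intensity — 56 features per channel. The co-occurrence computation is
implemented in the package so the direction averaging is exact: features
are invariant under 90° rotations to machine precision, and constant crops
produce defined (zero-variance) values. Quantization is per crop on the
masked intensity range, making features invariant to affine intensity
rescaling.

The pipeline then follows the standard population-profiling recipe:

1. **Z-score** each feature across all cells (zero-variance features are
   dropped with a warning; parameters are stored for reuse on held-out
   data).
2. **Condense**: within each condition, a seeded permutation partitions
   cells into disjoint pools of exactly $n$ (default 60); the pool mean is
   one population-level *center*; remainder cells are discarded.
3. **Classify**: PCA (4 components) fitted on training centers, a linear
   SVM (unit cost) on the component scores, stratified 80/20 split.
   Accuracy and a row-normalized confusion matrix (% per true condition)
   are computed on the test set and averaged over 20 seeded splits by
   default — a single split reproduces the literal procedure but with a
   20%-test-set variance that the averaging tames.
4. **Distances**: pairwise Euclidean distances between centers; the
   condition-level matrix averages cross-condition pair distances, and
   within-condition mean pair distance measures dispersion.
5. **Discriminant scatter**: for 2-D visualisation the centers are projected
   onto the first two linear discriminant factors computed with a
   ridge-regularized within-class covariance (axis signs fixed by making
   the largest-magnitude loading positive). The SVM carries the accuracy
   numbers; the discriminant projection only draws the map.
6. **Bootstrap condensation**: for each candidate pool size and iteration,
   80% of each condition's cells are resampled *with replacement*, the
   resample is partitioned into pools (the partition-of-the-resample
   choice), and one PCA + SVM split records its accuracy. The optimal
   condensation number is the smallest candidate reaching ≥95% accuracy in
   ≥95% of iterations; with no qualifier the report says so. Because large
   pool sizes can leave very few centers, the bootstrap's internal
   classifier allows a single test center per condition, whereas the
   exported `fit_classify()` requires two and errors otherwise, naming the
   condition.

The feature-table simulator draws per-condition multivariate Gaussians
whose means are shifted by `effect_size` SD units along a fixed seeded
random unit direction per condition; in high dimension those directions are
near-orthogonal, so the pairwise separation is $\approx$
`effect_size`$\times\sqrt{2}$. The nuclei simulator fills elliptical masks
with smoothed Gaussian random fields whose correlation length is the
condition's texture scale — enough structure to drive the co-occurrence
features apart, with no claim to model chromatin itself.

## Numerical conventions

* Every stochastic function takes an explicit `seed`; `NULL` uses the
  session RNG, any integer gives bit-reproducible output and never touches
  the caller's RNG state. Internal sub-seeds are derived deterministically.
* Degenerate inputs fail loudly: single-frame stacks, empty masks,
  calibration without fluctuation signal, constant diffusion profiles,
  all-equal dwell tables, all-constant feature tables.
* Stacks round-trip losslessly through 16-bit grayscale TIFF with a JSON
  metadata sidecar; tables are schema-validated CSV (missing columns,
  non-numeric cells and duplicate keys are named errors).

## Problem sizes used by the built-in checks

The test-suite and the acceptance script run the full pipelines at sizes a
desk check can afford while keeping the statistics meaningful: brightness
recovery on $128 \times 128 \times 100$ stacks (and 500 frames for cursor
classification), 1,500–5,000 simulated tracks for linking and diffusion
recovery, 2,000 censored dwells for the residence fit, 500–600 cells per
condition for the phenotyping pipeline, and 200 bootstrap iterations over
candidate pool sizes {5, 10, 20, 40, 60}.

## Limitations

* The simulators validate the estimators, not image formation: no PSF,
  no raster-scan correlation, no detector excess noise, no 3-D diffusion.
* The linking stage is a deterministic gate-and-assign tracker; it does not
  reproduce probabilistic multi-hypothesis scoring, and its hard gate
  truncates the fastest molecules (see above).
* Mobility analysis offers no within-track state switching; molecules are
  summarised by one diffusion coefficient each.
* The texture feature list reproduces the published lineage of the
  profiling method at the level of the stated pipeline (Haralick family +
  intensity moments); it does not claim bit-level equality with any
  specific implementation's feature values.
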