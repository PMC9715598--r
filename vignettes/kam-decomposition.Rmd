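---
title: "Decomposing the knee adduction moment from the ground reaction vector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the knee adduction moment from the ground reaction vector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(kamdecomp)
```

## The model and its assumptions

The external knee adduction moment (KAM) is the frontal-plane moment about
the knee joint centre that tends to rotate the tibia into varus; it is the
standard surrogate for medial-compartment knee loading. The ground
reaction vector (GRV) estimate of the KAM keeps only the ground reaction
force terms:

$$\mathrm{KAM} = \mathrm{GRF}_{ML}\,\mathrm{KJC}_V +
  \mathrm{GRF}_V\,(\mathrm{COP}_{ML} - \mathrm{KJC}_{ML}),$$

with the vertical ($V$) and mediolateral ($ML$) components taken in the
global frame and the moment about the anteroposterior (walking-direction)
axis at the knee joint centre (KJC). Inserting the ankle joint centre
(AJC) and rotating the COP offset into a foot-fixed frame (FF) whose
anteroposterior axis is the foot axis splits this into four moments:

* **M1** $= \mathrm{GRF}_{ML}\,\mathrm{KJC}_V$ — the mediolateral shear
  force acting over knee height;
* **M2** $= \mathrm{GRF}_V\,(\mathrm{AJC}_{ML} - \mathrm{KJC}_{ML})$ —
  the vertical force acting over the frontal-plane knee–ankle offset,
  i.e. tibia varus inclination;
* **M3** $= \mathrm{GRF}_V\,\mathrm{COP}^{FF}_{ML}\cos(\mathrm{FPA})$ —
  the vertical force acting over the medial offset of the COP from the
  foot axis;
* **M4** $= \mathrm{GRF}_V\,\mathrm{COP}^{FF}_{AP}\sin(-\mathrm{FPA})$ —
  the vertical force acting over the part of the COP's global medial
  offset created by the foot progression angle (FPA) and the COP's
  anterior position.

Because the foot-frame rotation is exact
($\mathrm{COP}_{ML}-\mathrm{AJC}_{ML} =
\mathrm{COP}^{FF}_{ML}\cos\mathrm{FPA} +
\mathrm{COP}^{FF}_{AP}\sin(-\mathrm{FPA})$), the four components sum to
the GRV moment identically; the package's tests hold this to
$10^{-9}$ N·m on randomized geometry, and the total is invariant to where
the foot frame splits M3 from M4.

A per-limb *medial-positive* sign convention makes every equation
side-agnostic: mediolateral quantities are measured toward the body
midline of the limb under study, so knee adduction is positive, a
laterally placed COP makes M3 negative, and toe-out (positive FPA) with an
anterior COP makes M4 negative, for the left and right leg alike. A trial
mirrored through the sagittal plane with the side flag flipped produces an
identical decomposition.

Assumptions inherited from the GRV simplification: segment inertial and
gravitational terms are neglected (they live in the inverse-dynamics
reference, below); the moment axis is the global walking direction, not an
anatomical knee axis; the lab origin lies on the ground plane so vertical
coordinates are heights; and the KAM alone is analysed — the knee flexion
moment is out of scope.

### Lever arms: coordinates versus angles

M1's lever arm can be written as knee height
($\mathrm{KJC}_V$) or as $L_{shank}\cos(\mathrm{SPTA}) + $ ankle height;
M2's as the knee–ankle ML offset or as $L_{shank}\sin(\mathrm{FPTA})$. In
3D no pair of independent planar angles makes both angle forms exact
simultaneously, so the package computes two conventions
(`tibia_angles()`): *projection* angles (planar projections from vertical,
the values reported to users) and *consistency* angles (solved so the
angle lever arms reproduce the coordinates). `decompose_trial()` defaults
to coordinate lever arms, which guarantee the exact sum. Angle mode
defaults to the consistency convention — evaluating the angle forms with
projection angles is still available explicitly, but its error grows with
combined sagittal/frontal shank inclination (several percent of peak KAM
at sagittal inclinations past ~15°), which is why it is not the default.

## The processing pipeline

`decompose_trial()` runs: stance detection → optional filtering →
per-sample limb-frame geometry → per-sample decomposition →
normalisation → stance-time normalisation.

* **Filtering** (`lowpass_filter()`): 4th-order Butterworth at 8 Hz,
  applied forward and backward so the double pass is zero-phase and does
  not shift peak timing. The cutoff is left at its nominal value rather
  than corrected for the second pass. The implementation seeds each pass
  with steady-state initial conditions and reflect-pads the series, so a
  constant signal is reproduced to better than $10^{-9}$ — important on
  short stance records where default zero initial conditions leave
  visible end transients.
* **Stance detection** (`detect_stance()`): the longest contiguous run of
  vertical GRF at or above 20 N (a conventional force-plate contact
  threshold), at least 3 samples long, with half-open `[start, end)`
  indexing. Detection runs on the *raw* force, not the filtered one:
  zero-phase smoothing spreads the contact transient backward in time and
  would move the detected contact by several samples.
* **FPA at midstance**: the foot progression angle is a per-step foot
  placement angle, so it is evaluated once, at the sample at 50% of
  stance, and applied to the whole stance.
* **Time normalisation** (`time_normalize()`): linear interpolation onto
  101 stations (every 1% of stance), endpoints preserved; affine profiles
  are reproduced exactly.
* **Normalisation**: moments are divided by body weight × height and
  multiplied by 100 (%Bw·Ht).

Degenerate inputs are rejected with typed errors rather than coerced: a
foot axis with no ground projection, a shank shorter than 5 cm, a missing
CSV column, non-monotonic time, a COP off the ground plane while the foot
is loaded, stance segments shorter than 2 samples.

## The inverse-dynamics reference

`newton_euler_kam()` computes the reference KAM by a bottom-up two-segment
Newton–Euler recursion in the frontal plane: ankle moment from GRF at the
COP plus foot gravity and translational inertia, then knee moment adding
the shank's gravitational, translational and rotational terms;
accelerations come from central finite differences (one-sided at the
boundaries), and the result is reported as the *external* moment so that
with massless segments it reduces exactly to the GRV estimate (the test
suite holds this to $10^{-6}$ N·m on a quasi-static simulated stance). The
foot's own rotational inertia about the anteroposterior axis is neglected:
a flat foot barely rotates in the frontal plane during stance and its
frontal radius of gyration is small. A prescribed frontal-plane pendulum
(shank swinging about a fixed knee under zero GRF) matches the closed-form
torque $I\ddot\theta + mgd\sin\theta$ within 1% at 100 Hz, which exercises
both the angular-inertia and gravity terms.

Segment parameters come from published anthropometric tables
(`anthropometrics()`): de Leva's adjusted Zatsiorsky–Seluyanov values
(default) or Dempster's cadaver values. The choice changes only the ID
reference, never the decomposition, and is exposed because the underlying
gait-model literature does not fix it. Radii of gyration are scaled by the
measured joint-to-joint distances of the trial.

## Agreement statistics

`extract_features()` returns the three standard KAM descriptors: first
peak (maximum over stations at ≤ 50% of stance — the station exactly at
50% belongs to the first half, a deterministic tie rule), second peak
(maximum over the remainder), and angular impulse (trapezoidal time
integral of the full *signed* profile; abduction excursions subtract, and
a positive-part-only option exists).

`cmc_inter_protocol()` implements the inter-protocol coefficient of
multiple correlation over $G$ cycles × $P$ protocols × $F$ stations:

$$\mathrm{CMC} = \sqrt{1 -
  \frac{\sum_{g,p,f}(Y_{gpf}-\bar Y_{gf})^2 / (GF(P-1))}
       {\sum_{g,p,f}(Y_{gpf}-\bar Y_{g})^2 / (G(PF-1))}},$$

where $\bar Y_{gf}$ is the across-protocol mean at cycle $g$, station $f$
and $\bar Y_g$ the grand mean of cycle $g$ — so between-cycle variability
does not inflate the agreement. When the within-cycle mean square exceeds
the total, or the profiles are flat, the statistic is undefined and
reported as `NA`, never clamped to zero. The sum-of-squares structure and
degrees of freedom above are this package's fixed documented choice.

`bland_altman()` reports bias (mean difference), precision (SD of
differences, $n-1$), limits of agreement bias ± 1.96·precision (normal
quantile), and $t$-based confidence intervals
($t\,\sigma/\sqrt n$ for the bias, $t\,\sigma\sqrt{3/n}$ for each limit).
When features are compared across repeated cycles, each cycle contributes
one pair (features are averaged per cycle before differencing).

## The synthetic gait generator

`simulate_trial()` builds a single-stance trial from closed-form
ingredients and, in parallel, evaluates the four component moments
analytically from the same noise-free limb-frame coordinates — so the
full lab-frame pipeline (3D reconstruction, limb frames, FPA, foot-frame
rotation) can be checked against known ground truth. Defaults, chosen
once to be physiologically plausible for a healthy adult:

* vertical GRF: two Gaussian bumps at 25%/75% of stance (amplitudes
  1.20/1.13 ×Bw before windowing, widths 0.18 of stance) under a C²
  smootherstep envelope (edge 0.28 of stance) with a 14% *contact floor*,
  so the force steps to ≈ 45 N at touch-down and lift-off — emulating the
  fast heel-strike transient and making 20 N contact detection decisive
  even with several newtons of force noise, while keeping the rest of the
  signal smooth enough that the 8 Hz zero-phase filter is essentially
  transparent;
* mediolateral GRF: a medially directed bump of 0.04 ×Bw peaking at 30%
  of stance;
* geometry: shank length 0.246 × height, ankle height 0.08 m, frontal
  tibia angle 4° varus, sagittal tibia sweep −15°→+20°, FPA 5° toe-out;
* COP: monotone eased travel from 0.05 m behind to 0.10 m in front of the
  ankle along the foot axis, with an early-stance medial offset decaying
  toward toe-off;
* speeds: stance durations 0.75/0.60/0.50 s for slow/self-selected/fast,
  with a knee-centre oscillation (8 mm base amplitude, 2 cycles per
  stance, velocity-free endpoints) scaled ×0.5/×1/×2 so segment
  accelerations — and hence the ID-vs-GRV gap — grow with speed;
* sampling: 100 Hz kinematics, subject 77.3 kg / 1.775 m.

`scenario_preset()` shifts this base geometry into three conditions:
`varus_oa` (FPA +6.5°, frontal tibia angle +4.1°, heavier subject,
COP medial offset reduced to a quarter), `braced_healthy` (FPA −3.9°,
frontal tibia angle −1.1°), and `healthy` itself. The deltas are the
magnitudes reported for varus-OA patients and for a valgus-pushing
ankle–foot orthosis in the clinical gait literature; the absolute base
values and the COP/ML-force profiles are this package's own plausible
placeholders, since no distributions are published for them.

All randomness flows from one explicit seed per configuration
(`simulate_batch()` derives per-cycle seeds deterministically from a
master seed), so every collection is bit-reproducible.

### What the generator does and does not emulate

It reproduces the geometric and kinetic structure the decomposition
consumes: double-bump loading, heel-to-toe COP progression at a
configurable FPA, tibia inclinations, speed-scaled segment accelerations,
and additive Gaussian sensor noise on markers and forces. It does **not**
emulate soft-tissue artifact, marker occlusion, force-plate crosstalk or
targeting, double support on two plates, muscle action, or inter-subject
variability in profile *shapes*. Passing the recovery tests therefore
shows the pipeline's algebra, frames and normalisation are correct and
noise-robust under idealised conditions — not that the model is accurate
on any particular laboratory's real recordings.

With its defaults the healthy preset yields a first-peak-dominant KAM
whose late-stance maximum sits just after midstance rather than forming a
pronounced separate bump; configurations with a larger frontal tibia
angle and smaller toe-out (e.g. `fpta = 6, fpa = 2`) produce the classic
two-peaked shape, and the test suite uses such a configuration where a
strictly interior second peak matters.

## Numerical choices and problem sizes

* Exact-sum and cross-product checks run on 1,000 randomized
  configurations at $10^{-9}$ N·m; sign-semantics grids use 144 points
  per component.
* Noise-free pipeline recovery is asserted to $10^{-6}$ %Bw·Ht with the
  filter disabled: an 8 Hz filter is only approximately transparent even
  to band-limited signals, and the noise-free path needs no denoising.
  Noisy recovery (2 mm marker noise, 5 N force noise, 10 cycles) is
  asserted as RMS profile distance per component below 2% of peak KAM
  with the filtered pipeline — RMS is the metric used for waveform
  recovery throughout, since a max-over-stations criterion is bounded
  from below by the averaged sensor-noise floor itself (about 1.5% per
  station for these settings) regardless of pipeline quality.
* Validation batches use 10 cycles × 3 speeds; CMC against ID exceeds
  0.98 on quasi-static batches and the first-peak |bias| grows
  monotonically with the speed regime, mirroring the expected behaviour
  of a GRV estimate as accelerations grow.
* The whole suite and the acceptance script each run in a few minutes on
  one CPU; simulation sizes (61–76 stance samples at 100 Hz, 10-cycle
  batches) were chosen as representative of single-lab gait sessions.

## Known limitations

* The moment axis is the global walking direction; laboratories that
  report the KAM about an anatomical knee axis will see small systematic
  differences at large external rotations.
* The inverse-dynamics reference is planar (frontal-plane) and
  two-segment; it is a reference for the KAM only, not a general 3D joint
  moment solver.
* C3D ingestion is not implemented (`read_c3d()` raises a clear
  not-supported error); trials enter through the documented CSV + JSON
  format.
* The FPA uses the heel→toe landmark axis; skeletal foot axes derived
  from multi-marker models may differ by a constant offset.
* Walking direction is taken from trial metadata, not estimated from the
  trajectory.
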