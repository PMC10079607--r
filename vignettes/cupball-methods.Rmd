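---
title: "Models and metrics for cup-and-ball transport assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and metrics for cup-and-ball transport assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupball)
```

## The task and its model

Transporting a cup with a ball rolling inside is a compact physical proxy
for carrying a cup of sloshing coffee: the hand acts on the cup, the cup
acts on the ball, and the ball acts back. Because the instructed movement
runs along the line between a start and a target circle, the object reduces
to a cart on a line carrying a suspended pendulum with a single angular
degree of freedom. With cup position $X(t)$, ball angle $\theta$ (zero at
the downward vertical, counterclockwise positive), pendulum length $l$
equal to the cup's radius of curvature, ball mass $m_b$ and cup mass $m_c$:

$$(m_c + m_b)\ddot X = \underbrace{m_b l (\dot\theta^2 \sin\theta -
\ddot\theta \cos\theta)}_{F_{ball}} + F_{inter},$$

$$\ddot\theta = -\frac{\ddot X}{l}\cos\theta - \frac{g}{l}\sin\theta.$$

The second equation is all that is needed to predict the ball: the cup
trajectory is treated as *prescribed* (kinematic driving) and the pendulum
responds. No human-controller model is attempted; the first equation then
simply reads off the force the ball exerts on the cup and the idealized
interaction force. Defaults mirror the physical device: $l = 75$ mm,
$m_b = 67$ g, rim angle $55^\circ$ (deep cup) or $40^\circ$ (shallow cup).
The cup mass is irrelevant to the ball dynamics and enters only
$F_{inter}$; it is set to 0.1 kg and recorded as an assumption, since the
cup-handle assembly's true mass and its friction with the board are
unknown — $F_{inter}$ is an idealized frictionless quantity.

`simulate_trial()` integrates the pendulum with a fixed-step classical
4th-order Runge–Kutta scheme, default $dt = 10^{-3}$ s. The pendulum
period at $l = 75$ mm is $2\pi\sqrt{l/g} \approx 0.55$ s, so the default
step resolves it 550-fold; the test suite verifies the small-angle period
to better than 1% and total-energy conservation to below $10^{-6}$ J over
10 s, and cross-checks a driven trial against an adaptive high-accuracy
integration (`deSolve::lsoda`) to under $10^{-4}$ rad.

### Ball escape

The ball leaves the cup when its mechanical energy exceeds the escape
energy $E_{ESC} = m_b g l (1 - \cos\theta_{ESC})$. The simulator declares
escape at the first step where $E_{Total} > E_{ESC}$ — the same energy
criterion the risk metric is built on — and reports crossing of the rim
angle itself as a secondary flag. By default the trace is truncated at
escape (the trial is physically over); integration past escape is
available because the pendulum model formally extends there, and the
synthetic-trial generator uses it in the rare case an escape occurs within
the first few frames so that a recording always spans at least half a
second.

## The synthetic-trial generator

No recordings of the physical device are deposited anywhere, so the
package generates its own study conditions. `generate_synthetic_trial()`
emulates the device's camera output: the simulated 1-D trajectory is laid
onto the board between the start and target circle centres (diameter
14 cm, separation 52 cm), the ball centre is reconstructed as the cup
centre displaced by $l\sin\theta$ along the movement axis, i.i.d. Gaussian
tracking noise is added (default 0.5 mm, a typical sub-pixel centroid
jitter), positions are quantized to the camera's pixel grid (640 px across
the 91.4 cm board, about 1.43 mm/px), and frames are sampled at 80 Hz.

Drive profiles define what the "subject" does:

* the able-bodied surrogate is a minimum-jerk reach of 0.52 m (about 1.1 s
  per stroke), a short dwell, and a minimum-jerk return;
* the impaired surrogate (`impaired_drive()`) follows the
  submovement-decomposition picture of post-stroke reaching: with growing
  severity $s \in [0,1]$ each stroke fragments into $1 + \mathrm{Pois}(3s)$
  sequential minimum-jerk subreaches separated by brief pauses, stroke and
  dwell durations stretch by $1 + 0.6s$, and $\mathrm{Pois}(6s)$ small
  corrective submovements are superimposed. Fragment durations scale with
  the square root of their amplitude share, which keeps peak acceleration
  near that of the unfragmented stroke: impaired movement here is slower
  and fragmented, not more violent, consistent with the instruction to
  transport the ball without losing it.

`make_fixture_cohort()` assembles whole cohorts: able subjects at severity
zero, stroke surrogates tested on both sides with the contralesional hand
drawing severities from 0.5–0.85 and the ipsilesional from 0.15–0.4, under
all three difficulty conditions.

What the generator deliberately does **not** emulate: closed-loop
responses of the hand to ball forces (the drive is open-loop), camera
lens distortion and colour-detection failures, torso compensation, and
trial-to-trial learning. Tests passing on synthetic cohorts therefore
demonstrate that the *analysis pipeline* is correct and that the metrics
order graded impairment as expected — not that the specific clinical
effect sizes of any real cohort are reproduced.

## Preprocessing

Raw recordings are low-pass filtered at 12 Hz with an 8th-order
Butterworth filter. The filter is applied forward and backward
(zero-phase): metric timing — segment boundaries, the times of ball-angle
maxima — must not be lag-shifted, and the effective attenuation is the
squared single-pass magnitude. Ends are handled by odd reflection padding
so that constants and slow trends pass without edge transients.
Coordinates are then projected onto the movement axis (the unit vector
from start to target centre, origin at the start centre), and the ball
angle is recovered from the overhead geometry as
$\theta = \arcsin\!\big((p_{ball} - p_{cup})\cdot\hat u / l\big)$, clamped
to $[-1, 1]$ before the arcsine; displacements exceeding $l$ by more than
10% raise a tracking-glitch warning. Derivatives use central differences
(one-sided at the ends) *after* filtering, and the ball's angular velocity
differentiates the recovered angle rather than differencing raw ball
pixels. Non-uniform timestamps (dropped frames) are linearly resampled to
the nominal rate first, with a warning. Frame indices are 1-based and
segments inclusive, the natural convention in R; serialized outputs state
this.

The **active segment** runs from the first to the last frame where
$|\dot X|$ exceeds 5% of the trial's peak. Movement time, SPARC and
mutual information all use this window; the same threshold is applied to
the filtered velocity (the unfiltered alternative is strictly noisier and
the choice is recorded here because no published convention pins it down).
The rule is deliberately literal — a single suprathreshold frame is a
valid (flagged) one-frame segment — so a noise excursion in long
stationary padding can occasionally stretch the segment; the tests
therefore check the *median* stability of movement time under tracking
noise rather than a per-realization bound.

## The four metrics

**Movement time** is the span of the active segment.

**SPARC** (spectral arc length) measures smoothness as the negated arc
length of the DC-normalized magnitude spectrum $\hat V(\omega)$ of the
speed profile over $[0, \omega_c]$, with the frequency axis scaled by
$\omega_c$. The cutoff adapts to the signal: $\omega_c$ is the largest
frequency not exceeding $\omega_{cmax} = 20\pi$ rad/s beyond which
$\hat V$ stays below $\bar V = 0.05$ (the recommended parameters for this
metric). Amplitude invariance follows from the DC normalization and
duration invariance from the $\omega/\omega_c$ scaling. Two numerical
choices matter: the spectrum is zero-padded to at least $2^{16}$ points
(0.0012 Hz grid at 80 Hz) because the discrete arc length only converges
once the spectral ripples are resolved — at coarser grids slow trials are
spuriously "smoother" — and the arc length is summed on the computed grid,
which the tests pin against an independent trapezoid-rule oracle to
$10^{-6}$.

**Risk** converts the ball's energy margin into a spill score. With
$E_{Kinetic} = \tfrac12 m_b l^2 \dot\theta^2$,
$E_{Potential} = m_b g l (1-\cos\theta)$ and
$E_{MARGIN}(t) = E_{ESC} - E_{Total}(t)$,

$$Risk = 1 - \frac{1}{n}\frac{1}{E_{ESC}} \sum_{i=1}^{n} E_{MARGIN}(t_i)$$

over the $n$ interior local maxima of $|\theta|$ (strict neighbour
comparison; plateaus count once at their midpoint; maxima with prominence
under $0.5^\circ$ are discarded as sensor noise — the physical ball cannot
produce such micro-reversals, the tracking pipeline can). Risk is
evaluated over the full recorded trial, and it is *not* clamped to
$[0,1]$: values above 1 are physically meaningful records of an escape and
clamping would hide them. A trial whose $|\theta|$ is monotone has no
maxima and the metric is reported as undefined rather than zero.

**Mutual information** quantifies how predictable the ball is from the
cup. Since both trajectories are near-sinusoidal, each signal is
represented by its phase in normalized state space,
$\phi = \mathrm{atan2}\!\big(\dot s/(2\pi f),\, s - \bar s\big)$; the
four-quadrant form keeps phase defined on the full circle, where a
one-argument arctangent would collapse quadrants. The characteristic
frequencies $f_X, f_\theta$ are not pinned down by any convention, so they
are estimated per trial as the dominant non-DC spectral peak of the
centered signal on the active segment, with fallbacks when no peak clears
five times the median spectral magnitude: the pendulum's natural frequency
$\sqrt{g/l}/(2\pi) \approx 1.82$ Hz for the ball and one cycle per segment
for the cup; both frequencies are reported for audit. MI is then the
histogram estimate of $\iint P(\phi_{ball}, \phi_{cup}) \ln
\frac{P(\phi_{ball},\phi_{cup})}{P(\phi_{ball})P(\phi_{cup})}$ on a
$10\times10$ grid over $(-\pi,\pi]^2$ (bin count configurable; empty cells
contribute zero; natural log, so nats), over the whole active segment as
one distribution — out- and back-strokes are pooled rather than averaged
per phase, a choice flagged for sensitivity analysis. The estimator's
positive bias for independent inputs decays as $(b-1)^2/(2n)$; tests bound
single realizations with the exact null distribution
($2n\,\mathrm{MI} \sim \chi^2_{(b-1)^2}$).

## Consistency statistics

Within- versus between-subject consistency of each metric uses a linear
random-intercept model fitted by REML (`lme4`), with
$ICC = \sigma^2_u / (\sigma^2_u + \sigma^2_e)$. The *unconditional* ICC
fits intercept only; the *conditional* ICC adds hand group and difficulty
as reference-coded categorical fixed effects. REML rather than ML matches
standard ICC practice; negative moment estimates are handled by the REML
boundary ($\sigma^2_u = 0$ is returned, not errored). Unbalanced tables
(missing trials) are supported. On balanced one-way data the REML estimate
coincides with the closed-form ANOVA ICC(1,1) estimator, which the test
suite asserts to $10^{-6}$ and uses as the independent cross-check; the
parameter-recovery study (500 replicate cohorts of 6 subjects × 20 trials
per generating ICC in 0.1–0.9) recovers the generating ratio with median
error below 0.05. The report supports both poolings of the stroke
surrogates — both hands as one group, or hand as a covariate level —
since either reading is defensible.

## Problem sizes and degenerate inputs

The test suite and the acceptance script favour many small deterministic
problems: 10 s of free pendulum at $dt = 10^{-3}$ s for the physics
checks, 20 randomized profiles for each metric oracle, 50 paired seeds for
the impairment orderings, 2500 REML fits for the recovery grid, and a
6 + 6-subject cohort at 6 trials per condition for the end-to-end report.
These sizes make every check reproducible in minutes on one CPU while
keeping Monte-Carlo intervals comfortably inside the asserted tolerances.

Degenerate inputs fail loudly rather than silently: a trial with zero peak
velocity has no active segment (no-movement error); an all-zero speed
profile or zero spectral DC leaves SPARC undefined; a ball that never
oscillates leaves risk undefined; constant phases leave MI undefined; a
single subject or a constant response leaves the ICC undefined. The
no-ball condition reports risk and MI as *absent*, never as zero.

## Known limitations

* The drive is open-loop: no feedback from ball state to hand, so
  strategies like resonance exploitation or active damping are outside the
  generator's vocabulary (the analysis pipeline would measure them fine).
* $F_{inter}$ ignores friction between cup base and board and the unknown
  cup-assembly mass.
* Phase estimation assumes near-sinusoidal kinematics; strongly aperiodic
  trials fall back to default frequencies and their MI should be read with
  the reported $f_X, f_\theta$ in hand.
* The ICCs computed on synthetic cohorts describe the generator's
  heterogeneity, not any clinical population's.
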