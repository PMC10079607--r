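# cupball

Quantitative assessment of upper-extremity function from a functional
object-transport task: sliding a cup with a ball rolling inside from a
start circle to a target and back, recorded by an overhead camera. The
package is for movement scientists and rehabilitation researchers who want
theory-based, per-trial performance metrics for this task — and a fully
synthetic test bench for them — without any device hardware.

## What it computes

The cup-and-ball is modelled as a cart on a line carrying a suspended
pendulum (length `l` = the cup's radius of curvature, one angular degree
of freedom):

    (m_c + m_b) Ẍ = m_b l (θ̇² sinθ − θ̈ cosθ) + F_inter
    θ̈ = −(Ẍ/l) cosθ − (g/l) sinθ

From filtered, axis-projected kinematics (12 Hz 8th-order Butterworth,
zero-phase; movement axis = start→target line; active segment = where
|Ẋ| exceeds 5% of the trial peak) four per-trial metrics are produced:

| metric | meaning |
|---|---|
| movement time (s) | span of the active segment (extension + flexion) |
| SPARC (a.u., ≤ 0) | negated arc length of the normalized speed spectrum up to an adaptive cutoff (V̄ = 0.05, ω_cmax = 20π rad/s); more negative = less smooth |
| risk (–) | 1 − mean energy margin at ball-angle maxima / escape energy, with E_ESC = m_b g l (1 − cos θ_ESC); > 1 marks an escape |
| mutual information (nat) | histogram MI between cup and ball state-space phases on the active segment; higher = more predictable object interaction |

Within- vs between-subject consistency of each metric is quantified by
intraclass correlation coefficients from REML random-intercept models
(`lme4`), unconditional and conditional on hand group + difficulty.

A simulator (`simulate_trial`, classical RK4 on the driven pendulum) plus
a camera emulator (`generate_synthetic_trial`: 80 Hz, pixel quantization,
tracking noise) and an impairment-graded drive generator
(`impaired_drive`, fragmented strokes with corrective submovements) stand
in for the physical device's recordings.

## Worked example

```r
library(cupball)

sys <- condition_system("deep_ball")   # 55 deg rim, l = 75 mm, 67 g ball
rec <- generate_synthetic_trial(
  system = sys,
  drive = impaired_drive(0.6, seed = 42),  # moderately impaired surrogate
  seed = 43, condition = "deep_ball", subject = "PS01", hand = "contra"
)
m <- compute_metrics(preprocess_trial(rec))
m
#> <metric_set>
#>   movement time      : 3.300 s
#>   SPARC              : -3.863 a.u.
#>   risk               : 0.460
#>   mutual information : 0.245 nat
#>   segment            : [27, 291]
```

Reading: this surrogate took 3.3 s for the reach-and-return (an
unimpaired surrogate needs about 2.3 s), its fragmented velocity profile
lengthens the spectral arc to −3.86 (vs about −2.75 when smooth), the
ball's energy at its angle maxima consumed 46% of the escape threshold,
and the cup–ball phase coupling carries only 0.25 nat of information
(vs about 0.9 for smooth transport) — slower, less smooth, riskier, less
predictable.

Cohort-level use goes through `make_fixture_cohort()` →
`batch_compute()` → `icc_report()`, or the command-line interface
(`inst/cli/cupball.R`) with verbs `simulate`, `fixture-cohort`,
`compute`, `batch-compute`, `icc`.

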