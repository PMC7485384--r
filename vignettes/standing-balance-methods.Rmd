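---
title: "Reflex-based balance control in perturbed standing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflex-based balance control in perturbed standing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

standreflex simulates a person standing on a platform that translates
horizontally in random square pulses, and asks how much of the balance
response can be produced by delayed proprioceptive reflexes alone.  This
vignette documents the model, the controller, the identification procedure
and the design decisions behind them.

```{r setup}
library(standreflex)
```

## The plant

The body is a sagittal-plane rigid-body chain of seven segments: a trunk
segment that lumps torso, head and arms, plus thigh, shank and foot for each
leg, connected by revolute hip, knee and ankle joints.  The trunk is a
floating base, giving nine degrees of freedom; the controller is identical
in both legs, so effectively six coordinates describe the motion (trunk
position and pitch, hip, knee, ankle).  Joint angles are zero in upright
stance with flexion (ankle dorsiflexion) positive; x points toward the toes
and y up.

The model stands on a platform that is *kinematically* driven: its
trajectory is prescribed and the human cannot push it around, reflecting an
apparatus whose 1000 kg platform mass makes human-to-platform coupling
negligible.  The platform mass is therefore retained only as metadata.

Anthropometry defaults to an 80 kg, 1.80 m adult using standard body-segment
fractions (Winter's tables): segment masses 67.8% (trunk+head+arms), 10.0%
(thigh), 4.65% (shank) and 1.45% (foot) of body mass; lengths as fractions
of stature; inertias from standard radii of gyration.  Every entry of
`default_anthropometry()` can be overridden, because identification against
a specific participant requires matching stature and mass.

Foot-ground contact acts at a heel and a toe point per foot, with a
penetration spring-damper normal force (80 kN/m, damping proportional to
penetration) and regularized Coulomb friction (`mu` = 1,
tanh-regularization at 0.1 m/s).  These values give millimetre-scale static
penetration and settle to a vertical ground reaction within 2% of body
weight; they replace the contact solver of the original simulation engine,
which is not reproduced here.

Integration is fixed-step semi-implicit Euler at `dt` = 0.5 ms.  A fixed
step makes the reflex delay buffers exact (each delay is an integer number
of steps) and the scheme is symplectic, so the passive chain conserves
energy to well below 0.1% over a second.  The step size is bounded above by
the contact and friction stiffness acting on the light foot segment;
0.5 ms keeps those modes stable with margin.

## Muscles

Each leg is driven by the nine sagittal mono- and bi-articular muscles:
iliopsoas, gluteals, rectus femoris, biceps femoris long and short head,
vastus, gastrocnemius, soleus, tibialis anterior.  Muscles are four-element
Hill models: an active contractile element (CE) with a bell-shaped
force-length curve (width 0.56, residual 0.05) and a Hill force-velocity
curve (maximum shortening rate 12 optimal lengths per second, eccentric
plateau 1.5), a parallel elastic element engaging beyond the optimal length,
a small CE damping term, a series elastic element (SEE) that is quadratic in
strain with reference strain 0.04, and a buffer elastic element that stops
the CE from collapsing below 44% of its optimal length.  The CE velocity is
found at every step by solving the four-element force balance: on each
force-velocity branch the balance reduces to a quadratic, solved in closed
form (with a safeguarded Newton fallback); the accepted residual is below
10^-6 of the muscle's maximum isometric force.

Pennation is a scalar projection factor in the tradition of the
reflex-walking muscle models (not an angle): both the CE length and the CE-side forces project onto the
tendon line of action by this factor.

Two parameter groups deserve note:

* The rectus femoris and biceps femoris short head carry their published
  parameters (optimal CE lengths 8.1 cm and 12 cm, maximum isometric forces
  1200 N, tendon slack lengths 35 cm and 10 cm, pennation 0.5 and 0.7).
  The tibialis anterior maximum isometric force is 4000 N — deliberately
  high, because the single dorsiflexor otherwise cannot resist the platform
  pulses; its activation in stance stays low, so the realized force remains
  physiological.
* Attachment geometry (signed moment arms per spanned joint) is not fixed
  by published parameter tables; `default_muscles()` ships a documented default
  table adapted from the reflex-walking model family (hip arms 0.08–0.10 m,
  knee 0.05–0.06 m, ankle 0.04–0.05 m, constant over the small angular
  excursions of stance, with a cosine-shaped option available).  The
  musculotendon resting length at upright is `l_slack + pennation * l_opt`,
  so tendons start at slack in the reference posture.

Activation follows first-order excitation-contraction coupling with a 10 ms
rise and 40 ms fall time constant.

## The reflex controller

Each muscle's stimulation is the sum of three parts, clamped to
[0.001, 1]:

* a constant feedforward input `u0` — the baseline drive that maintains
  stance;
* force feedback (Golgi tendon organ pathway): gain times the time-delayed
  SEE force, normalized by `F_max`;
* length feedback (muscle spindle pathway): gain times the time-delayed CE
  length (normalized by `l_opt`) in excess of an offset, and zero below the
  offset.

Normalization is a deliberate reading: with feedback gains bounded at ±3
and length offsets bounded in [0.2, 1.1], the feedback laws only produce
stimulations of order one if force is expressed in units of `F_max` and CE
length in units of `l_opt`.

Delays are per muscle (35–100 ms, `delay_table()`), realized as exact
ring-buffer lags of the fixed-step simulation.  The controller at time t
sees only sensor samples from t − Δt and earlier.

### The dead zone

Feedback is gated by the whole-body centre of mass (COM): inside a dead
zone within the base of support no feedback is applied and the model stands
on feedforward drive and muscle viscoelasticity alone — an event-based,
intermittent control.  The zone is parameterized by distances `x_heel` and
`x_toe` measured inward from the heel and toe contact points (at most
10 cm), and transition fractions `z_heel`, `z_toe` in [0, 1] that define
linear ramps of width `z * x` outside the zone edges, smoothing the onset
of feedback.  Beyond the ramps the gate saturates: the gains act at -G on
the heel side and +G on the toe side — one gain magnitude per muscle and
modality, with the sign flipping across the zone.  The heel-side case distinctions of this gate admit more than one reading;
we implement the continuous piecewise-linear one (constant, ramp, zero,
ramp, constant) and test it against an independently coded oracle.

The gate uses the instantaneous COM by default ("real-time" COM
measurement); a configurable COM delay (20 or 100 ms, matching reported sensing
latencies of human COM estimation) is available through `controller_preset(com_delay = ...)`.  The COM position is
evaluated in the platform frame against the current heel and toe contact
positions, from which the dead-zone distances are measured inward.

## Episode protocol and objective

`run_episode()` reproduces the simulation protocol:

1. **Joint-angle control (0–1 s).**  A per-joint PD servo (gains 3000/3000/
   2000 N m/rad, damping 60/60/30 N m s/rad) holds a slightly flexed
   reference stance (hip 0.04 rad, knee 0.08 rad, ankle dorsiflexed to keep
   the feet flat, COM 5 cm ahead of the ankles) while the muscles, whose
   tendons start at slack, contract to their feedforward equilibrium.
   Muscle-only control from the first instant is very hard to stabilize;
   this phase exists for exactly that reason.
2. **Quiet stance (1–2 s).**  The PD servo is off; the reflex controller
   runs with the platform still.
3. **Perturbation (2–110 s).**  The platform follows the signal.

The episode stops early if the chest point (top of the trunk) drops below
0.7 m.  Identification scores an episode by effort — the time-averaged
summed squared activation over the 100-s evaluation horizon — under three
constraints: the model must survive the horizon, the chest must be above
1.3 m at its end, and the mean absolute ankle displacement relative to the
platform (measured from its position at perturbation onset) must stay below
0.05 m.  We evaluate the horizon from perturbation onset, i.e. simulation
time [2 s, 102 s]; the displacement constraint uses the absolute value,
since a signed mean could mask symmetric slipping.

## Perturbation signal

`generate_signal()` draws square pulses i.i.d. uniformly from amplitudes
{-5, -2.5, 0, 2.5, 5} cm and durations {0.25, 0.5, 0.75, 1.0, 1.25, 1.5} s
and concatenates them to the requested duration.  Neither the pulse distribution nor the amplitude semantics (absolute
position versus increment) is fixed by the protocol; we default to uniform draws interpreted as absolute platform
positions (which reproduces the bounded ±5 cm traces seen in the recorded
platform motion) and provide an incremental mode.  Pulse edges are
rate-limited at 1 m/s so the kinematically driven platform has finite
velocity.  Recorded traces can be loaded from two-column CSV and windowed
at arbitrary offsets.

## Identification: lexicographic PSO

Controller parameters are identified by global-best particle swarm
optimization with a lexicographic ordering: the total normalized constraint
violation is minimized first, and effort decides only among feasible
candidates.  Each candidate is evaluated by a single forward simulation of
the full episode (single shooting).  The decision vector holds `u0` per
muscle, the active feedback gains and length offsets of the architecture,
and the four dead-zone parameters: 40 parameters for the base
(force+length) architecture, 31 for length-only, 22 for force-only.

For the PSO hyperparameters we use the standard constriction-style values (inertia 0.72, cognitive = social = 1.49),
velocity clamped to 20% of each parameter's range, reflecting bounds, and a
warm start from a good initial guess — warm starting being standard practice for these high-dimensional,
simulation-in-the-loop searches.  Constraint violations are
normalized by their bounds before summing, so a second of missing duration
and a centimetre of missing chest height are commensurable.  Everything is
deterministic given the seed.

The shipped `calibrated_preset()` parameter sets were produced with this
machinery in stages: quiet-stance stabilization first, then optimization on
a generated 110-s perturbation signal, and finally a robustification stage
in which each candidate is scored on several independent signal
realizations (summed violations, mean effort).  The last stage matters: a
controller optimized against a single realization tends to overfit it — it
survives its training signal but falls under other draws from the same
pulse distribution — while the multi-signal optimum generalizes across
fresh realizations.  The published parameter values
(`controller_preset()`) are retained verbatim as the literature reference;
they were identified on a different physics engine and anthropometry and do
not stabilize this plant as-is, which is expected for reflex controllers,
whose gains are tuned to the loop they close.

## Evaluation

`compare_trajectories()` follows the comparison pipeline: experimental
angle/moment series are filtered with a zero-phase (forward-backward)
second-order Butterworth at 16 Hz, resampled onto the simulation time
points by linear interpolation, and correlated per signal (three joint
angles, three joint moments) with Pearson's r and a two-sided t-transform
p-value.  Zero-phase filtering is the biomechanics convention and avoids
introducing lag bias into r; we filter at the native rate before
resampling.  Simulated output is noise-free and is not filtered.  Simulated
moments are net muscle moments per joint averaged over the two legs.

## Synthetic pseudo-experiments

The real perturbed-standing recordings are external data; to keep every
pipeline stage testable offline, `pseudo_experiment()` runs a reference
episode and overlays band-limited measurement noise: white Gaussian noise
low-pass filtered at 5 Hz and rescaled to 0.6 deg SD on angles and 2 N m
SD on moments, written at 100 Hz in the evaluation CSV dialect.  The
magnitudes are calibrated to the model's signal content: joint-angle
excursions in perturbed stance have SDs of roughly 2-5 deg (smallest at
the ankle, which the dead zone and tendon stiffness hold nearly rigid),
so this noise leaves correlations in the strong-but-imperfect band
(r between 0.9 and 1) where the evaluation tests are sensitive — a
pipeline defect (lag, sign, scaling) pulls r far below it, while the true
sensor noise spectrum of any given apparatus remains a declared
assumption.  What passing those tests shows is that the
*evaluation machinery* is faithful — not that the model reproduces human
data, which requires the external dataset.

`discrimination_fixture()` generates pseudo-experiments from the
length-only and force-only architectures so tests can verify that the
comparison stage ranks each architecture highest against its own data —
the contrast between feedback modalities that the pipeline exists to resolve.

## Numerical and scale choices

* Episode step 0.5 ms; trajectory logging 100 Hz; muscle force-balance
  tolerance 10^-6 F_max with velocity clipped at the maximum
  contraction rate (clips are counted and reported).
* Degenerate inputs are rejected with named-field errors: non-positive
  segment masses/lengths, ill-ordered dead-zone edges, delays that are not
  integer multiples of the step, non-monotone signal time stamps.
* Test and example problem sizes are scaled for a single CPU: the packaged
  regression tests use 8–30 s episodes where full length is unnecessary,
  and the end-to-end identification check uses a 16-particle, 40-iteration
  swarm warm-started at the calibrated preset — large enough to exercise
  the lexicographic machinery, small enough to run routinely.  The
  calibration itself used larger swarms.

## Known limitations

* Sagittal plane only; no frontal-plane or 3D motion, no joint limits
  beyond the muscles' passive elements.
* Muscle spindles are pure delayed length feedback with an offset — no
  velocity term, by design (the simplest spindle model keeps the search
  space small); no short-range stiffness, so rapid stretch responses are
  softer than in real muscle; both exclusions are deliberate, isolating the contribution of the reflex
  loops themselves.
* The platform is position-driven; ground-reaction-based triggering of the
  intermittent controller is not modelled (the COM is its proxy).
* Anthropometry, muscle geometry and contact parameters are documented
  defaults, not participant-specific measurements; conclusions about a
  specific dataset require overriding them.
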