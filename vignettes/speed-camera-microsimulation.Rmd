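---
title: "Methods: highway microsimulation of speed enforcement cameras"
author: "secsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: highway microsimulation of speed enforcement cameras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secsim)
```

# The question and the modelling strategy

A fixed speed camera measures spot speed at one point; an average
(point-to-point) camera measures mean speed over a section; an in-vehicle
telematics device measures speed continuously. Their effect on *whole-trip*
speeding therefore differs far more than their effect at the camera pole.
`secsim` quantifies this with an agent-based microsimulation of a single
6 km, 3-lane highway without exits or obstacles, in which drivers differ
only in how they respond to enforcement, and summarises each simulated
scenario by the **ratio of unsafe driving (RUD)**: the percentage of total
vehicle-distance travelled strictly above the 90 km/h limit.

The package follows a simulate → regress → translate pipeline: a factorial
grid of scenarios is simulated, per-run RUD is regressed on the scenario
factors, and pooled mean-speed contrasts between camera layouts are
converted to crash relative risk with the power model.

# Driver population

Each driver carries a behavioural class, a desired free-flow speed (DFFS,
the speed chosen on an empty road) and a telematics flag.

* **Group A (law-abiding)** — DFFS at or below the limit; enforcement is
  irrelevant to them.
* **Group B (kangaroo)** — DFFS above the limit, but the target speed drops
  to the limit inside a fixed camera's 150 m upstream detection zone and
  everywhere inside a point-to-point section; outside, the DFFS resumes.
  This produces the V-shaped speed profile around cameras known as the
  distance halo effect.
* **Group C (consistent speeder)** — DFFS above the limit regardless of
  enforcement.

DFFS is sampled from per-group truncated normals (km/h): A — mean 84,
sd 4 on (0, 90]; B — mean 100, sd 6 on (90, 140]; C — mean 110, sd 8 on
(90, 160]. The locations and spreads are a design choice: the source data
for such distributions (driver-level GPS percentiles) is not publicly
printed, so we chose values that reproduce the defining structure — group A
strictly legal, B and C strictly violating, C fastest with the heaviest
tail — while keeping all four numbers per group configurable
(`default_dffs_params()`). Sampling is inverse-CDF on the normal quantile
function, with the open lower bound guarded against round-off.

Group counts use deterministic largest-remainder rounding (ties broken
A < B < C), so a scenario's nominal composition is exact and composition is
not an extra noise source. Telematics devices go to a uniformly random
subset of the B ∪ C pool of size `round(p/100 · |B ∪ C|)` — sampling
without replacement among violators only. The returned driver order is a
random permutation: arrivals cycle through the pool sequentially, and a
group-sorted pool would otherwise confound arrival time with behaviour.

**What the generator does not emulate.** Real DFFS distributions are
skewed, multi-modal and correlated with vehicle type, trip purpose, age and
time of day; real populations drift over days (the time halo effect). None
of that is modelled: a passing test suite shows the pipeline reproduces the
*mechanistic* consequences of the three-class behavioural model, not that
any particular road's drivers follow these distributions.

# Car-following and lane-change model

The simulator is a discrete-time (default `dt` = 1 s) safe-velocity model —
the classic Krauss formulation that ships as the default in mainstream
traffic microsimulators. Per step and vehicle:

1. target `v* = min(v_behavioural, v + a·dt, v_safe)` with
   `v_safe = −bτ + sqrt((bτ)² + v_leader² + 2·b·gap)`;
2. stochastic imperfection `v' = max(0, v* − σ·a·dt·U)`, `U ~ U(0,1)`;
3. position advance `x += v'·dt`; vehicles beyond the segment end leave.

Defaults (`sim_params()`): acceleration a = 2.6 m/s², deceleration
b = 4.5 m/s², reaction time τ = 1 s, imperfection σ = 0.5, vehicle length
5 m, minimum gap 2.5 m — the conventional passenger-car values. Gaps are
measured net of vehicle length and minimum gap, and the update runs
front-to-back per lane with the follower additionally hard-clamped behind
its leader's updated position, which makes the no-collision invariant exact
(the test suite asserts zero violations over randomised scenarios, plus
exact flow conservation: inserted = exited + on-road).

Deceleration into a camera zone is not rate-limited: the behavioural target
simply drops to the limit at zone entry, the simplest reading of "abrupt"
kangaroo braking. Point-to-point compliance for group B is an instantaneous
cap at the limit across the whole controlled section; this guarantees the
section-average constraint and is the conservative choice. The alternative
— speeding and then compensating to game the section average — would
need its own behavioural sub-model; the observation that group-B RUD under
average cameras remains clearly above zero in the source setting suggests
real drivers do partially game it, so our cap gives an upper bound on
point-to-point effectiveness for group B.

Lane changing is intentionally minimal: a vehicle held below 80 % of its
target moves left if the new leader leaves it strictly faster and the new
follower is not forced below its current speed; an unblocked vehicle
symmetrically returns right. Without any overtaking, one slow vehicle caps
an entire lane and demand effects degenerate; with this rule, faster
violators can clear slower law-abiding traffic at low densities but get
progressively trapped as demand rises — the mechanism behind the negative
demand–RUD association.

Arrivals are a Poisson process at the demand rate (total across lanes),
pre-generated from the scenario seed and handed to the kernel as per-step
counts. Each arrival takes the next driver from the (shuffled) pool, enters
at `min(DFFS, limit)` on the lane with the largest entry headway, and is
queued whenever the entry gap is below minimum gap + vehicle length.

# Randomness and the paired design

All randomness of a run derives from the scenario seed: the population
draw, the arrival process, and the imperfection noise.

Two deliberate choices make layout contrasts *paired* comparisons:

* `expand_seeds()` gives every scenario the same deterministically derived
  seed list (common random numbers), so for a given seed the population and
  arrival pattern are identical across camera layouts;
* the imperfection draw is a counter-based stream keyed on (seed, driver,
  step) rather than a shared sequential stream, so the noise a driver
  receives at a given time is also identical across layouts and cancels in
  contrasts.

Neither choice alters any marginal distribution; they only remove
between-layout noise from within-seed differences — the standard
variance-reduction design when simulation configurations are compared. The
FIX2-vs-FIX3 pooled-speed contrast is of the order of a few hundredths of a
km/h, which unpaired noise at desk-scale replication would swamp.

# Metrics

* `compute_rud()` — distance share strictly above the threshold
  (`exceeds 90 km/h`, so exactly 90 is safe); per-step distance is
  `speed · dt`, which matches the simulator's update exactly and is robust
  to exit truncation.
* `compute_group_rud()` — the same restricted per class; classes with zero
  distance are *absent*, not zero.
* `space_mean_speed()` — total distance over total time, the flow-weighted
  (harmonic) mean that the power model expects as "traffic speed". The
  arithmetic sample mean would overweight fast vehicles.
* `speed_profile()` — arithmetic mean speed per position bin (default
  100 m), used for the V-shape diagnostics.

The kernel accumulates the same per-step quantities while running, so batch
runs skip trajectory materialisation; a test asserts the two routes agree.

# Scenario design and inference

The full factorial design crosses camera layout (FIX1/FIX2/FIX3/P2P),
telematics 0–10 % (integer steps), group B 10–50 % (step 5), group C 1–5 %
(step 1) and demand 500–3500 VPH (step 500): 13,860 cells, 30 seeds,
415,800 runs. The telematics reading of "0 to 10 %" as eleven integer
levels is forced by the printed cell count (4·11·9·5·7 = 13,860).

The RUD regression (`fit_rud_regression()`) is plain OLS with classical
standard errors — per-run rows, no clustering — of RUD on layout indicators
(reference FIX1), demand/1000, the two group shares and the telematics
rate. Confidence intervals are coefficient ± 1.96 SE; p-values below 0.001
are reported as `<0.001`. Rank deficiency is detected up front and the
collinear columns are named.

The crash-risk translation (`build_crash_risk_table()`) classifies runs
into implementation cells — community behaviour (law-abiding / average /
law-avoiding / law-carefree, from the B and C shares), traffic (low
500–1500, moderate 2500–3500 VPH) and telematics (none 0–1 %, enforcement
8–10 %) — pools distance and time across runs and seeds per cell and
layout *before* dividing (one traffic-level speed per cell, which is what
the power model expects), and applies `RR = (v̄_alt/v̄_ref)^n`, n = 3.
Deliberate edge rulings: demand 2000 VPH belongs to neither printed traffic
bin and is excluded rather than guessed into one; community boundary ties
(B exactly 20 or 30 with C = 3) resolve by the fixed priority law-abiding >
average > law-avoiding > law-carefree; cells missing the FIX1 reference are
an error rather than silently dropped.

The spill-over analysis (`spillover_linearity()`) fits, per layout × demand,
a line of mean RUD on the telematics rate over 10–90 % (step 10 — not
printed in the source design; chosen for symmetry) at the average
composition (30 % B, 3 % C). Telematics compliance is per-vehicle by
construction, so departures from linearity would indicate emergent
interaction through traffic flow; the fit's R² and maximum residual measure
that directly.

# Numerical choices and degenerate inputs

* Timestep 1 s, horizon 3600 s, warm-up 600 s excluded from all records and
  metrics (removes the empty-road transient).
* Positions are continuous metres from the segment start, lanes 0-based
  from the right; speeds are m/s internally, km/h in every interface.
* Strict inequality defines unsafe speed; σ-noise only ever subtracts, so a
  capped vehicle can sit exactly at the limit without tripping it.
* Zero total distance (RUD) or zero time (mean speed) are hard errors, not
  NaNs; negative gaps are hard errors (a collision would be a simulator
  bug, and is asserted against in tests).
* Empty violator pools make the telematics request vacuously satisfied.
* Seeds are kept below 2³¹ (R integer range); derived seeds are
  counter-based so extending a design never perturbs existing runs.

# Problem sizes used by the tests and scripts

Grid-level checks run a scaled design chosen to keep a full check on one
CPU in minutes while exercising every factor: all four layouts × telematics
{0, 5, 10} × B {10, 30, 50} × C {1, 3, 5} × demand {500, 2000, 3500} with
five common seeds (1,620 runs); the spill-over grid runs its full 144 cells
with three seeds. Safety invariants are asserted over 100 random scenarios
at a shortened horizon (480 s + 120 s warm-up), where violations would
surface just as readily as at full length. The analysis scripts default to
the same desk-scale grid and accept `--full` for the complete design.

# Known limitations

* One homogeneous segment: no ramps, intersections, heterogeneous vehicle
  types, weather or incidents; findings concern uninterrupted flow only.
* Behaviour is static within a run — no time halo (adaptation over days),
  no partial compliance, no speed-then-compensate gaming of point-to-point
  sections (a config-level compliance mode is the natural extension point).
* Crashes are not simulated events; risk comes analytically from the power
  model, whose aggregate-speed validity caveats apply unchanged.
* The overtaking rule is a minimal mechanism, not a calibrated lane-change
  model; lane-level statistics should not be over-interpreted.
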