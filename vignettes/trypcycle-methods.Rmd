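---
title: "Methods: cell-cycle timing and daughter-cell asymmetry in trypanosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle timing and daughter-cell asymmetry in trypanosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trypcycle)
```

## Background

A dividing procyclic *Trypanosoma brucei* cell builds a new flagellum while
keeping the old one, and cytokinesis yields two structurally different
daughters: the new-flagellum daughter (NFD) and the old-flagellum daughter
(OFD). The flagella connector, which tethers the tip of the growing new
flagellum to the old one, is severed at cytokinesis and leaves a short-lived
remnant on each daughter — one at the tip of the NFD's flagellum, one about
halfway along the OFD's. While those remnants are detectable, the two
daughters of a recent division can be told apart within the otherwise
uniform-looking 1F1K1N class (one flagellum, one kinetoplast, one nucleus).
This package implements the quantitative machinery built around that
observation: an ergodic snapshot-timing estimator, an agent-based model of
flagellar-label inheritance under RNAi, cohort morphometrics, and a
mesh-based anterior-caliber measurement, together with a synthetic-data
generator that emulates the statistical structure of the microscopy data.

## The ergodic age distribution and the marker-window estimator

In a steadily, exponentially growing binary-fission population, a snapshot
over-represents young cells: each division turns one old cell into two
newborns. At steady state the fraction of the population younger than
progress $x$ through the unit cycle ($0 =$ birth, $1 =$ division) is

$$\Phi(x) = 2 - 2^{1-x}, \qquad \phi(x) = 2\ln 2\, 2^{-x},$$

implemented as `age_cdf()` / `age_density()`, with the exact inverse
$x = 1 - \log_2(2 - F)$ in `progress_from_fraction()`.

If a marker is visible on a cell for the first $w$ units after cytokinesis,
the marked cells are exactly the population younger than $w$, so their
cumulative fraction is $\Phi(w)$ and $w$ can be read off a single snapshot.
Two corrections matter in practice:

* **One marked daughter per division.** Each remnant segregates to exactly
  one of the two newborns, so only half of the cells younger than $w$ carry
  any given marker. The estimator therefore scales the observed fraction to
  $F_\mathrm{eff} = (2/d)\, n_\mathrm{marked}/N_\mathrm{total}$ with
  $d = 1$ marked daughter. This is the only correction under which the
  counted sample shipped with the package (22 and 7 marked cells among 515)
  reproduces windows of ~34 and ~11 minutes at 8.9 h per unit cycle; the
  factor is exposed as `daughters_marked` and validated in the tests against
  a forward population simulation that marks one daughter at every division.
* **Whole-population denominator.** $\Phi$ is defined over all cells of all
  stages, so $N_\mathrm{total}$ is the all-category count (515), not the
  1F1K1N count (219).

```{r}
marker_window(marker_count_table("tip marker", 22, 515, daughters_marked = 1))
marker_window(marker_count_table("mid marker", 7, 515, daughters_marked = 1))
```

Assumptions: steady-state exponential growth (no death or arrest), a sharp
detection window (marker removal is in reality likely gradual, which would
make $w$ an effective, sensitivity-dependent quantity), and a window that
ends inside the 1F1K1N span — `marker_window()` warns when the implied
window crosses the second-flagellum boundary. Reported windows are given
both unrounded and rounded to the nearest minute, since whole minutes are
the natural reporting precision here.

The default `cell_cycle_map()` places the category boundaries at 0.596 u
(second flagellum), 0.852 u (kinetoplast division) and 0.942 u (mitosis),
with one unit equal to 8.9 h — the standard values for logarithmically
growing procyclic culture, which come from an independent dataset. The
observed 1F1K1N share of a sample (219/515 ≈ 42.5%) need not match the
ergodic expectation at those boundaries (≈ 67.7%); the map is treated as a
set of given constants and the package does not attempt to reconcile the
two.

## The label-inheritance simulation

RNAi against an axonemal protein tagged with eYFP dilutes flagellar label
through the population: flagella built before induction are fully labelled,
flagella under construction when the RNAi takes effect end up partially
labelled, and flagella started later are unlabelled. Because a flagellum,
once built, is inherited intact, the label records when the flagellum was
made, and the population kinetics of the three classes measure the cycle
durations of the two daughter classes.

`run_labelling_sim()` implements the agent model. Each agent carries unit
cycle progress, old- and new-flagellum label states, and which flagellum it
inherited at birth. Defaults (all overridable in `sim_scenario()`):

| parameter | default | meaning |
|---|---|---|
| `n_agents` | 10,000 | initial population, ages drawn from $\Phi^{-1}$ |
| `dt` | 0.01 u | global step |
| `induction_time` | 0.3 u | delay before RNAi takes effect |
| `increment_ofd`, `increment_nfd` | 0.01 u | per-step progress of each inheritance class |
| `report_interval` | 0.05 u | tally cadence |
| `duration` | 1.8 u | total simulated time |

Semantics, in step order: agents advance by their class increment; an agent
crossing the 0.596 u boundary acquires a new flagellum labelled FULL before
induction and UNLABELLED after; at the single step containing the induction
time, every cell already past 0.596 u has its part-built new flagellum
re-flagged PARTIAL; agents reaching 1 u divide — the continuing cell keeps
the old flagellum (progress reset to exactly 0, the sub-step overshoot of at
most one increment is discarded), and the appended sibling inherits the
parent's new flagellum as its old one. Initial inheritance flags are drawn
50/50 at random (the steady state of a process producing one OFD and one
NFD per division); an `alternating` assignment is available to check that
the choice is immaterial. A single seeded generator drives the whole run,
so equal seeds give bit-identical reports. "10% slower" scenarios use the
literal increments 0.009 vs 0.01 u (an 11.1% longer cycle), matching the
step sizes rather than the rounded prose.

### The plateau readout and its clock

`plateau_fraction()` pools the 1F1K1N and 2F1K1N categories into "1K1N" —
the experimental classification sees kinetoplasts and nuclei, not flagella —
and averages the fully-labelled fraction over report times in a window.
The window is expressed on the simulation clock, whose origin is the moment
RNAi induction starts (doxycycline addition); the default 1.24–1.46 u is
the 11–13 h span where the measured proportion plateaus at 8.9 h per unit.
The scenario's `induction_time` is the delay before induction takes effect,
so it is *not* added to the window; a `clock = "post_induction"` option is
provided for readouts relative to effective induction.

Under equal rates the model pins the plateau by a pairing argument: every
post-induction division of a fully-labelled cell creates one fully-labelled
and one affected daughter at identical progress, so as long as every
affected 1K1N cell still has its live fully-labelled sibling, the two
classes balance exactly at 50%. That holds until the earliest
affected-parent division, one full cycle after effective induction
(1.3 u on the simulation clock with the defaults); the test suite asserts
the exact balance at reports up to that point. Beyond it, divisions of
affected cells (two affected grandchildren, against one-full-one-affected
from the full lineage) pull the fully-labelled share down slowly, so the
window average over 1.24–1.46 u computes to ≈ 47.6% rather than exactly
50%. The package reports what the model computes.

With one daughter class slowed by 10%, the slower class spends more time
inside the 1K1N progress span and is correspondingly over-represented
there: slowing the NFD class puts the affected (partially labelled or
unlabelled) share of 1K1N at ≈ 52% and the fully-labelled share at ≈ 48%,
and the mirrored scenario reverses the two. The magnitude — a 2 pp shift
per class, 4 pp separation between the mirrored scenarios — is the model's
sensitivity to a 10% cycle-length asymmetry at these population sizes; the
direction follows from the residence-time argument above and is confirmed
by an independent re-implementation of the dynamics. Published summaries
of this comparison attach these two magnitudes to the opposite classes;
the package deliberately reports the proportions its simulated dynamics
produce.

`generate_timecourse()` emulates the counting experiment on top of the
simulator: at each report time it draws a fixed number of cells (default
500) without replacement — a multivariate hypergeometric draw across the
stage × label classes — so synthetic time courses carry realistic counting
noise.

## Cohort morphometrics

`classify_cohort()` maps validated cell records to NFD (tip marker), OFD
(mid-flagellum marker), no-FCR (neither) or NOT_1F1K1N; a 1F1K1N record
with both markers is rejected as a data error since the remnants mark
different daughters. `summarize_cohort()` reports mean, sample standard
deviation ($n-1$), and counts of used and missing values; missing
measurements are excluded pairwise per parameter.

`two_sample_test()` defaults to Welch's unequal-variance statistic with
Welch–Satterthwaite degrees of freedom, computable directly from per-group
mean/sd/n — necessary when only printed summaries are available, and robust
to the strongly unequal spreads seen in the anterior-angle data
(9.3° vs 3.0°):

```{r}
str(two_sample_test(29.5, 9.3, 19, 12.3, 3.0, 17))
```

A pooled Student variant is available via `var_equal = TRUE`. No
multiple-testing correction is applied across parameters: each comparison
is reported at its own $P < 0.05$, mirroring how such per-parameter
morphometric panels are conventionally presented; users testing many
parameters should correct externally. Percentages from count tallies use
explicit half-up rounding to one decimal (`tally_fraction()`), because
banker's rounding would turn e.g. 6.25% into 6.2%.

## Anterior caliber from surface meshes

The anterior remodelling of an NFD shows up as a non-tapered anterior end.
`anterior_caliber()` quantifies it on a triangulated cell surface (nm
units, watertight, outward-wound): walk 2 µm of arclength from the
anterior tip along an on-surface polyline that follows the flagellum
(`point_at_arclength()`), then measure the cross-cell caliber at that point
(`opposite_caliber()`).

The caliber emulates expanding a sphere centred on the on-surface point
until it touches the surface on the opposite side of the cell. The first
far-wall contact of such a sphere lies along the inward surface normal at
the centre, so the implementation casts a ray along the inward normal and
returns the distance to the first triangle crossed from inside (outward
normal facing along the ray). Triangles within an exclusion radius
(default 300 nm, Euclidean) of the centre are never candidates: they are
the wall the centre itself sits on, which the interactive measurement
implicitly ignores. A plain minimum-distance-to-opposite-wall rule was
rejected because it does not reduce to the diameter on the benchmark
shapes (on a cylinder it returns $R\sqrt{2}$, the shortest chord to the
far half); the normal-ray construction returns $2R$ exactly on cylinders
and spheres and tracks $2\,r(z)$ within 2% on gently tapered tubes at the
default tessellation. The returned quantity is the contact-sphere radius,
which equals the chord to the opposite wall, i.e. the local diameter for
tube-like geometry; it is called "caliber" here to avoid the
radius/diameter ambiguity such measurements often carry. Non-watertight
meshes are rejected rather than repaired.

`generate_tapered_tube()` provides analytic fixtures: watertight surfaces
of revolution with arbitrary radius profiles, their meridian path from the
anterior tip, and an arclength-to-axis mapping so the true caliber
$2\,r(z)$ is known everywhere. Convergence to the analytic value is
first-order in edge length.

## The synthetic snapshot generator

`generate_snapshot()` emulates a counted immunofluorescence sample: ages by
inverse-transform sampling of $\Phi$; categories from the cell-cycle map;
each 1F1K1N cell assigned NFD or OFD birth identity with probability 1/2;
the corresponding marker set when the cell is younger than that marker's
window (defaults 0.063 u and 0.020 u, the cycle-unit equivalents of ~34 and
~11 min); morphometrics from per-cohort truncated-at-zero Gaussians, with
the free flagellum clipped to the flagellum length; optional uniform
missingness. The cohort parameter defaults are anchored on the values
printed in running text — anterior angles 29.5 ± 9.3° (NFD) vs
12.3 ± 3.0° (OFD), FAZ growing 13.2 → 17.2 µm while the flagellum grows
20.1 → 22.8 µm across NFD G1 remodelling, an NFD cell body ~5 µm shorter —
and otherwise chosen once as plausible procyclic values reproducing the
published cohort orderings. They are synthetic fixtures, not measured
values.

What the generator deliberately does not emulate: covariance between
measurements (an optional flagellum–FAZ correlation hook exists but
defaults to independence), gradual FCR signal decay (the window is sharp),
staining/detection variability beyond the missingness rate, and any image
formation. Tests passing on this generator therefore validate the
estimators' statistical logic, not their robustness to those real-data
features.

`recover_windows()` closes the loop: on generated snapshots the marker
windows are re-estimated within binomial error of the generating values
(asserted at 3 standard errors in the tests).

## Numerical choices and problem sizes

All stochastic functions take explicit integer seeds and are bit-reproducible
at equal seeds. The test suite and acceptance script use the modelled
culture conditions directly — 10,000 agents, 0.01 u steps, 0.05 u reports,
515-cell snapshots, 50 cells per morphometric cohort, 500-cell time-course
counts — and larger sizes (100,000-cell snapshots, 1,000-replicate type-I
calibration) where a law-of-large-numbers check needs them; the whole suite
runs in well under a minute. Degenerate inputs (zero marked cells, empty
plateau windows, open meshes, sub-2-µm paths, both-marker records) raise
errors or warnings rather than returning silent values.

## Known limitations

* The ergodic estimator treats marker loss as a step function; gradual
  decay makes the estimated window detection-sensitivity dependent.
* The simulator models neither cell death, nor gradual protein depletion
  after induction (a single effective delay stands in for it), nor the
  axonemal defects the RNAi eventually causes.
* The caliber measurement requires the anterior path as input; choosing the
  path's azimuth on a real segmented surface is up to the user.
* Cohort tests are per-parameter; no multiplicity correction is applied.
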