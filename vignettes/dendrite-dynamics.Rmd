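---
title: "Quantifying dendrite branch dynamics from skeleton time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendrite branch dynamics from skeleton time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrodyn)
```

## The problem

During metamorphosis, *Drosophila* olfactory projection neurons (PNs) grow
dendrites into the antennal lobe and settle on a specific target region. In
ex-vivo imaging of this process, two timescales matter: over many hours
(frames every 20 minutes), the bulk dendritic mass explores in several
directions before committing to one; over minutes (frames every 30 seconds),
individual terminal branches extend, retract, appear and disappear. The
hypothesis this package is built to interrogate is *selective branch
stabilization*: branches pointing towards the eventual target live longer,
while those pointing away are short-lived, so directional bias in branch
*lifetimes* — not in growth speed — produces targeting.

`dendrodyn` takes already-traced skeletons (SWC, one file per time point,
micrometres and minutes throughout) and quantifies both timescales. It does
not segment images or trace neurites, and it assumes all frames of a series
share one coordinate system, as produced by tracing a fixed-position explant
recording.

## Directional partitioning

All directional quantities are defined in an antennal-lobe coordinate frame
(`direction_frame()`): an apex (by default the point where the neuron's main
process enters the neuropil — configurable, since the tracer may prefer the
soma), a dorsolateral (DL) unit axis and an orthogonal dorsomedial (DM) unit
axis. Points are projected onto the DL–DM plane; the angle $\theta$ from DL
towards DM selects one of four 90° sectors:

* DL: $\theta \in [315°, 45°)$, DM: $[45°, 135°)$,
  VM: $[135°, 225°)$, VL: $[225°, 315°)$.

Half-open intervals make the assignment deterministic at boundaries, and the
implementation uses sign/magnitude comparisons of the two projections rather
than an explicit `atan2`, so ties are exact. The 2-D projection (rather than
3-D solid angles) reflects how these directions are defined anatomically in
the frontal plane; the anterior component is deliberately ignored.

Dendritic "volume" is the conical-frustum volume of the traced cable,
$\frac{\pi}{3} L (r_a^2 + r_a r_b + r_b^2)$ per edge — the standard
skeleton-based proxy. Every function that weights by volume also accepts
cable length as the weighting, for tracings with unreliable radii. A
segment contributes to the sector of its midpoint; segments are not split at
sector boundaries, an approximation whose error vanishes with tracing
density (densify the tracing if segments are long relative to sector size).
The main process (the soma-to-entry path, plus any node with SWC type 1 or
2) is excluded from all dendritic metrics by default, since the quantity of
interest is the dendritic mass emanating from the main process.

## Bulk dynamics (20-minute cadence)

`direction_profile()` yields, per frame and direction, the volume fraction
and the *extent* — the largest in-plane radial distance of any dendritic
node in that sector. `detect_bulk_events()` declares an extension event when
the extent grows by strictly more than `bulk_threshold` (default 2 µm)
between two consecutive frames, and a retraction event for the mirror-image
decrease. Two conventions matter:

* **Strictness.** A change of exactly 2 µm is not an event. The same holds
  for the branch-level speed threshold below. Tests pin both.
* **Missing frames.** A frame flagged missing in the series manifest breaks
  consecutiveness; no event is ever scored across a gap, because a
  2-µm-per-20-min threshold is meaningless over a 40-min interval.

The event threshold is applied to extent (a length) rather than to volume
because it is a length; a 95th-percentile variant of extent is a reasonable
robustification against single stray nodes and can be obtained by
densifying or pre-filtering the tracing, but the default is the maximum,
which matches how far the arbor demonstrably reaches.

`event_counts_by_window()` compares the first and last six frames (2 h at
either end of a ~21 h recording) — the conventional pre- versus
post-targeting contrast.

## Branch dynamics (30-second cadence)

A *terminal branch* is the path from a leaf back to the nearest branch
point (degree ≥ 3) or to the main process. Branches deeper in the arbor are
typically unresolvable in vivo and are out of scope.

Branches are linked across frames by greedy nearest-neighbour matching of
tip positions with a distance gate (`match_gate`, default 3 µm). At 30-s
cadence and ~1.5 µm/min tip speeds, a tip travels ≈ 0.75 µm per interval,
so the gate admits genuine continuations with a wide margin while rejecting
cross-matches between branches a few micrometres apart. The matcher is
deterministic (candidate pairs sorted by distance, then by node ids) and a
track never resumes after an absence — a branch that disappears and a
branch that later appears nearby are different branches by definition.
Known limitation: two tips crossing within the gate can swap identities;
the simulator quantifies how often this distorts downstream statistics
(below).

Each track over an `n`-frame window receives exactly one of four lifetime
categories, which partition all contiguous presence masks:

| category | present at frame 1 | present at frame n |
|---|---|---|
| stable | yes | yes |
| retracting | yes | no |
| emerging | no | yes |
| transient | no | no |

Signed tip speed is the per-interval change in branch *path length* (not
tip displacement) divided by elapsed minutes — extension and retraction are
growth and shrinkage of the branch, and path length is insensitive to
rigid-body wobble of the tip. An interval is labelled extending or
retracting only when the speed strictly exceeds `speed_threshold`
(default 0.5 µm/min) in magnitude; otherwise stationary.

A track's direction is the modal sector of its tip over its present frames
(configurable to the first-frame sector); tips rarely cross sector
boundaries mid-window, and the modal rule keeps the assignment stable when
they graze one.

## Targeting phases

Each bulk frame is classed by how many directions are *occupied* — holding
at least `occupancy_threshold` (default 5%) of the frame's dendritic
volume. The threshold is a package choice: some cutoff is needed to
separate genuine occupancy from trace noise, 5% is far below the 25%
uniform share, and users should check sensitivity in their own data. Counts
of 3–4 mean the exploratory *initial* phase, exactly 2 the *transitional*
phase, ≤ 1 the *final* phase. Runs shorter than `phase_smoothing` frames
(default 3, i.e. one hour — transitional phases last about 4 h, so
hour-scale smoothing suppresses flicker without swallowing real phases)
never open a phase, and the admissible order is initial → transitional →
final: frames whose class would move backwards are absorbed into the
preceding phase and flagged rather than creating a phase that reverses
development. Whether phase boundaries should be defined by exactly this
rule is genuinely open; this is one defensible, fully specified
formalization, and the flag counts expose where it bites.

Group comparisons use a two-sided Welch *t*-test (the unequal-variance
variant, chosen because nothing guarantees equal variances between, say,
directions of one cell) and one-way fixed-effects ANOVA, via
`stats::t.test` and `stats::oneway.test`. Zero within-group variance
everywhere is reported as a flagged degenerate result (p = 1 for equal
means, p = 0 otherwise), never NaN.

## The synthetic generator

Because no traced morphologies are published for this preparation, every
stage is validated against `simulate_series()`, a birth–death model with
complete ground truth:

* branches nucleate per direction as independent Poisson processes
  (rate $\lambda_d$ per minute), each at a uniform random angle within its
  90° sector and a random elevation within ±40°, sprouting from its own
  base point 3–10 µm along the ray (real terminal branches sprout from
  distinct positions on the arbor; a common apex would make tips
  artificially collide);
* each branch lives $\mathrm{Exp}(\tau_d)$ minutes — *stabilization is a
  longer mean lifetime*, the simplest memoryless embodiment of the
  mechanism, a modelling choice rather than an empirical claim;
* while alive, its path length follows a two-state extend/retract process:
  per-interval speed magnitude $\sim \mathcal{N}(1.5, 0.4^2)$ µm/min
  (matching the observed branch-speed scale), sign flipping with
  per-minute probability 0.3, a 10% chance of dwelling stationary, length
  clipped at the neuropil radius; a branch whose length returns to 0 is
  eliminated then and there;
* tips get Gaussian position jitter (default sd 0.1 µm) emulating tracing
  noise; set `jitter_sd = 0` for exact-recovery experiments;
* frames are rendered as valid single-tree SWC files (soma + trunk typed
  as main process, branches typed dendrite), and identical seeds give
  bit-identical output.

Presets pin the scenarios used throughout the tests. `uniform` (λ = 0.5/min,
τ = 5 min, 15 min at 30-s cadence) is the no-bias null. `vm_destabilized`
sets τ_VM = τ/4 with a base lifetime of 30 min and λ = 0.8/min: lifetimes
must reach the tens of minutes for any branch to persist through a 15-min
window, and the nucleation rate was set against the scale of roughly
fifteen analysable branches per direction in fast imaging of this system.
Note the realized stable counts are smaller (≈ 3–4 per unbiased direction,
≈ 10 per cell) because elimination by full retraction shortens effective
lifetimes below τ — the truth tables report both. `stepwise_targeting`
scripts per-direction extents over 63 bulk frames (~21 h) through
occupancy 4 → 2 → 1, where the two surviving directions always include DL
and never VM, and the pre-targeting phase contains scripted supra-threshold
extent jumps; because extents are scripted, the true bulk event log is
exact. `static` renders one immobile branch per direction — an end-to-end
null in which every detector must stay silent.

What the generator deliberately does not emulate: curved or arborizing
branch geometry (straight radial segments suffice for every metric
computed here; an optional midpoint node exists for path-resolution tests),
imaging point-spread functions, tracing topology errors, and registration
drift between frames. Passing recovery tests therefore demonstrates the
*analysis* is correct and robust to tip-position noise — not that tracing
errors in real data are harmless.

## Numerical choices and degenerate inputs

* Sector assignment refuses points whose in-plane projection lies within
  1e-9 µm of the apex; the soma is excluded upstream, so this only fires
  on pathological input.
* The exploring volume (convex hull of dendritic node positions, computed
  by an in-package incremental hull) returns 0 with a warning — not an
  error — for fewer than four distinct points or a coplanar set.
* Core-overlap rasterizes cable length into a shared voxel grid (default
  1 µm) by splitting edges into sub-voxel pieces; an arbor's "core" is the
  smallest set of densest voxels holding half its cable, and overlap is
  normalized by the smaller core.
* Frame validation enforces one root, connectivity, acyclicity and
  non-negative radii at construction; radii of zero are preserved
  verbatim through I/O.
* Zero-cable frames yield NA fractions with an explicit flag; they are
  treated as unoccupied, never silently dropped or NaN-propagated.

## Problem sizes used in the validation suite

The test suite and the acceptance script simulate 10 destabilized cells
and 10 × 10 uniform null cells (15 min windows, 31 frames each), plus
63-frame bulk scenarios; oracle-equivalence checks run on 1,000 randomized
instances per operation. These sizes give stable pass/fail behaviour for
the properties tested (e.g. the across-direction ANOVA on 10 cells) while
each suite run remains a matter of minutes on a single core.
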