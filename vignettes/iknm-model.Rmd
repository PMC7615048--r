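---
title: "An individual-based mechanical model of interkinetic nuclear migration"
author: "iknm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based mechanical model of interkinetic nuclear migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iknm)
```

## The biological problem

In pseudostratified epithelia such as the *Drosophila* wing imaginal disc,
every cell touches both the apical and the basal surface, but nuclei sit at
many different depths, shuttling along the apical-basal (A-B) axis through
the cell cycle. Mitosis happens only at the apical surface, so a nucleus in
G2 must migrate apically before it can divide — interkinetic nuclear
migration (IKNM). As the tissue grows, nuclei crowd an increasingly deep
pseudostratified column, and this crowding mechanically throttles the
apical-ward leg of IKNM. `iknm` simulates this feedback: a deformable-nucleus
mechanical model coupled to a cell-cycle state machine, from which the
package computes the statistics that characterize crowding-limited
proliferation — phase censuses over time, apical-basal phase distributions,
G2 durations and G2 arrest, terminal pre-mitotic velocities, crowding
indices, and nuclear layering.

All lengths are measured in units of the diameter of a spherical G1-phase
nucleus (`G1d`), all times in hours of developmental age (h AEL). The
simulated interval, 72 h to 116 h AEL, covers the main larval growth phase
of the wing disc.

## The mechanical model

The tissue cross-section is a 2D elastic box. The basal surface is the
rigid line `z = 0`. The apical boundary is a piecewise-linear chain of
control heights over a fixed lateral grid, elastic about its rest height
`box_height` with a second-difference smoothing term. The lateral walls are
elastic about the rest width `box_width`. A narrow band of depth `d_mz`
under the apical boundary is the *mitotic zone*: a soft one-sided penalty
repels vertices of non-mitotic nuclei from it, so that ordinarily only
nuclei in M reside there.

Each nucleus is a convex 20-sided polygon with a prescribed *target area*.
Its energy terms are:

* **Deformation** — edge springs about the regular rest 20-gon of the
  current target area: `k_deform/2 * sum_e (l_e - l*)^2`. The rest shape is
  round; deviation in shape (not size) is penalized weakly, so nuclei
  squeeze and elongate under load.
* **Cable-to-nuclei energy** — each nucleus is confined by its cell's
  membrane and cortex, which in a pseudostratified epithelium runs from the
  apical to the basal surface. This is modeled as a virtual cable from an
  apical anchor `(ax, apical(ax))` to a basal anchor `(bx, 0)`, attracting
  all 20 vertices: `k_cable/2 * sum_v d(v, cable)^2`. The basal anchor `bx`
  is a free variable of the minimization, which lets nuclei slide past one
  another; the apical anchor is fixed quasi-statically (see below).
* **Apical pulling spring** (G2 only) — the active, cytoskeleton-driven
  apical-ward force on G2 nuclei is an effective zero-rest-length spring
  from the nucleus's center of mass to the apical anchor:
  `k_spring/2 * |c - a|^2`. It is switched off as soon as any vertex
  reaches the apical boundary (within `tol_apical`), and does not act in
  any other phase. Basal-ward descent after division is passive — daughters
  are pushed down only by other nuclei.
* **Gradient flow** — each step minimizes the total energy plus
  `eta/(2*dt) * sum_v |v - v_prev|^2` over all nucleus vertices. This is an
  implicit-Euler discretization of a friction-dominated gradient flow: it
  sets the timescale of all passive motion and prevents large per-step
  jumps. The ratio `eta/dt` plays the role of a drag coefficient.

Constraints are enforced as a combination of soft penalties inside the
objective and exact projections applied within the minimization loop:

* **Area conservation** (equality): a stiff quadratic penalty
  (`k_area`) during descent, finished by an exact uniform rescaling of each
  polygon about its center, so recorded areas equal their targets to
  machine precision.
* **Convexity**: a quadratic penalty on negative consecutive-edge cross
  products, plus a projection that replaces a dented or folded polygon by
  its convex hull, resampled to 20 equal-arc-length boundary points and
  rescaled to the exact target area. The projection also triggers on a
  total boundary turning angle different from `2*pi`, which catches
  multiply-wound self-intersecting rings that a cross-product test alone
  cannot see. The resampled ring is aligned to the original vertex labels
  by the best cyclic shift so relabeling does not masquerade as motion in
  the gradient-flow term.
* **Non-overlap and containment** (inequalities): quadratic penalties on
  penetrating vertices (`k_overlap`, probed against the nearest edge of the
  other polygon) and on vertices outside the box (`k_contact`), plus a
  *contact polish*: rigid separation translations along the line of
  centroids (and rigid clamps at the basal line and walls) iterated until
  the deepest vertex penetration falls below `polish_eps`. Rigid
  translations preserve area and convexity exactly, so the three projection
  families commute well in practice.

A step therefore runs: Barzilai-Borwein descent with monotone backtracking
on the penalized objective, interleaved with the projections, followed by a
*feasible-descent* phase in which every projected-and-polished iterate is
accepted only if the objective decreases. The state returned is feasible
(overlap, protrusion and area residuals within `tol_constraint`, convexity
within `convex_tol`) and its objective does not exceed that of the
*projected* unmoved candidate.

### Why the descent reference is the projected candidate

After S-phase growth raises target areas, the unmoved candidate state
violates the area constraint; its soft area penalty undercounts the real
mechanical cost of inflating a nucleus against its neighbors. Comparing the
returned energy against this undercounted value is therefore not a
well-posed descent test. The test the solver guarantees — and the one the
property suite asserts — is descent relative to the unmoved candidate
*after projection to the feasible set* (`objective_ref` in the solver
diagnostics). For steps without growth or topology changes the two
references coincide.

### Why the apical boundary is never adjusted geometrically

An earlier design resolved apical protrusion inside the contact polish by
raising the chain to cover pressed nuclei. That turns the apical boundary
into a ratchet: every step a G2 spring presses a nucleus into the chain,
the polish lifts the chain by the penalty-equilibrium penetration, and the
elastic restoring force never gets to act — over a full run the box
inflates by several `G1d` and the tissue becomes an unphysically tall,
dilute column. The apical boundary is therefore governed exclusively by its
elastic energy; the contact stiffness `k_contact` is set high enough
(default 4000) that the equilibrium penetration of a pressed nucleus stays
within the feasibility tolerance.

## The cell cycle

Phases advance strictly `G1 -> S -> G2 -> M -> division -> G1`:

* **G1 -> S.** In `timer` mode, G1 lasts a prescribed time that ramps
  linearly from `G1_start = 2 h` at 72 h AEL to `G1_end = 10 h` at 116 h
  AEL, mimicking the lengthening of G1 as the disc matures. In
  `basal_gate` mode, G1 has no timer: S entry requires the nucleus to come
  within range `lambda` (in `G1d`) of the basal surface — the two-gate
  hypothesis in which a basal signal licenses S entry. The gate is
  instantaneous (contact, not residence) and monotone in `lambda`.
* **S.** The duration is drawn once per nucleus, uniform on
  `S_mean ± S_halfwidth` = 8 ± 2 h (bounded support; a truncated-Gaussian
  alternative is available via `S_dist`). The nuclear target area grows
  linearly in time from `birth_area` to exactly `2 * birth_area` — nuclei
  double in size during S and only during S.
* **G2.** No timer: G2 ends when the nucleus reaches the apical surface.
  The gate requires a vertex within `tol_apical` of the apical boundary
  *and* the centroid within `gate_depth` of it. `gate_depth` (default
  1.5 `G1d`) prevents grazing-contact mitoses while accommodating the
  elongated shapes that cable confinement produces: a doubled-area nucleus
  squeezed by its cable is about 2 `G1d` tall, so its centroid sits
  ~1 `G1d` below its top vertex even when pressed against the apical
  surface. (Requiring the centroid inside the mitotic zone itself,
  `d_mz = 0.5`, would deadlock the gate for geometric reasons alone.)
  G2 duration is thus an output of the mechanics, and a G2 nucleus that
  never reaches the apical surface by the end of the run is *G2-arrested*.
* **M.** On M entry the cable is inactivated (mitotic rounding) and the
  nucleus is admitted to the mitotic zone. After `M_duration` (30 min) the
  nucleus divides: the polygon is split by a line through its centroid
  perpendicular to the apical surface, each half is resampled to a 20-gon
  of exactly half the mother's area, and both daughters enter G1 with
  `birth_area = mother_area / 2`. One daughter, chosen by a fair coin,
  keeps the mother's apical and basal connections; the other is unanchored
  — no cable, no spring — until it re-establishes contacts after a delay
  drawn fairly from {6, 12} min.

Two bookkeeping rules keep long runs healthy. First, a cable whose apical
anchor has been left more than `anchor_remodel = 1.5 G1d` behind laterally
re-attaches above its nucleus (junction remodeling); without it, nuclei
that drift far sideways end up on long diagonal cables whose apical pull is
mostly lateral, and the G2 gate can deadlock. Second, the apical anchor
height is evaluated quasi-statically — at the start of each step, from the
current chain — rather than coupled into the minimization.

## Simulation engine

A run seeds the box at 72 h AEL with 10 nuclei — 7 in G1 (entering at
72 h) and 3 in S with uniformly drawn elapsed fractions, the phase ratios
of young discs — on a jittered grid, then relaxes the configuration
mechanically (repeated minimizations at fixed time) until feasible. Each
step applies cell-cycle updates in nucleus order (transitions, growth,
divisions, re-anchorings), then the mechanical minimization, then advances
time by `dt` (3 min). Snapshots (every 15 min by default) serialize every
nucleus's 20 vertices, so stored runs can be re-analyzed fully. A single
RNG stream per replicate, with a documented draw order (seeding jitters,
phase permutation, S fractions; then per step in nucleus order: S-duration
draws, daughter choice, re-anchoring delay), makes each (config, seed) pair
bit-reproducible. Ensembles use seeds `seed + 0 ... seed + n - 1`.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `k_deform` | 0.5 | E/G1d^2 | nuclear shape stiffness |
| `k_cable` | 0.5 | E/G1d^2 | cortical confinement stiffness |
| `k_spring` | 6 | E/G1d^2 | active apical pull on G2 |
| `k_mz` | 0.5 | E/G1d^2 | mitotic-zone repulsion |
| `k_box_apical`, `k_box_curv`, `k_box_lateral` | 5, 1, 0.5 | E/G1d^2 | box elasticity |
| `eta` | 0.15 | E h/G1d^2 | gradient-flow friction |
| `dt` | 0.05 | h | time step (3 min) |
| `box_width`, `box_height` | 5, 3 | G1d | rest box geometry |
| `d_mz` | 0.5 | G1d | mitotic zone depth |
| `S_mean ± S_halfwidth` | 8 ± 2 | h | S duration |
| `G1_start -> G1_end` | 2 -> 10 | h | G1 timer ramp |
| `M_duration` | 0.5 | h | mitosis duration |
| `lambda` | (per experiment) | G1d | basal signal range |

The energy unit is arbitrary; only stiffness ratios matter. The ratios
above are the package's calibrated defaults: the cell-cycle timings and
the seeding census are fixed by the biology, while the mechanical ratios
were chosen in a documented one-time calibration pass
(`scripts/calibrate.R`) targeting the early- and late-window G2 fractions
of the timer-mode ensemble, and then frozen. Three ratios deserve comment.

* `k_spring` must be large against `k_mz`: a zero-rest-length spring is
  weakest near its anchor, so a G2 nucleus that has almost arrived pulls
  only gently; if the mitotic-zone repulsion is comparable, the apical
  gate deadlocks just below the surface and no mitosis ever occurs. The
  zone still excludes passive nuclei because ambient pressure (set by the
  soft lateral walls) is far below the spring force.
* `k_box_lateral` must be soft. The disc grows in surface area as well as
  thickness; with rigid walls the packing jams, nothing reaches the
  apical surface, and the entire population arrests in G2.
* `eta/dt` sets all passive timescales. With the calibrated ratios an
  unobstructed G2 nucleus crosses the early box in well under an hour;
  transit through crowded tissue is one to several hours and, with age,
  increasingly does not complete at all.

## What the statistics mean

* `phase_fractions`: per-snapshot fractions in G1/S/G2, M pooled with G2
  (a FUCCI-style census cannot see M); ensemble mean ± SD.
* `ab_distribution`: nuclei binned by centroid depth below the local apical
  surface in half-`G1d` slices, normalized by the total count.
* `crowding_indices`: 2D analogue of the in vivo voxel crowding measure —
  the fraction of a nucleus's expanded bounding rectangle (margins 0.75
  `G1d` lateral, 0.25 apico-basal, clipped to the box) occupied by other
  nuclei; border nuclei are excluded as in the imaging analysis.
* `g2_durations` / `g2_arrested`: completed G2 times (SG2 to DIVISION per
  lineage, binned 12 h by entry) and the cumulative count of G2 entries
  that never divide; the two partition all G2 entries.
* `terminal_velocity`: apical-ward centroid displacement over the hour
  before each division, against division time, with a degree-3 polynomial
  trend and its end/begin ratio.
* `thickness_and_layers`: mean apical height; 2.5-97.5% interquantile span
  of centroid depths; layers = span/diameter + 1.

## What the synthetic data does and does not emulate

The simulator generates its own data; nothing is fitted to images. The
model reproduces the mechanisms the design encodes — crowding-limited
apical transport, an apical mitotic gate, optional basal licensing of S
entry — in a 2D cross-section with an idealized elastic boundary. It does
not represent: the third dimension (out-of-plane neighbor exchange relieves
crowding in real discs, so 2D crowding effects are stronger at equal
density); tissue curvature; apoptosis; cell-size checkpoints; explicit
cytokinesis or cortical actomyosin dynamics (the active force is an
effective spring); or in vivo measurement noise. Passing tests therefore
demonstrate internal correctness of the model and the statistics, not
quantitative agreement with any particular imaging dataset.

## Numerical choices and degenerate inputs

* Feasibility tolerance `tol_constraint = 1e-3 G1d^2` on overlap and
  protrusion areas; area errors are zero to machine precision by
  projection; convexity is checked at `convex_tol = 1e-5` (relative,
  scaled by squared mean edge length) — contact flattening leaves
  micro-concavities at the projection resolution, so the geometric
  predicate default of `1e-8` is reserved for clean geometry.
* `polish_eps = 4e-4 G1d` bounds residual vertex penetration so that even
  a flat facet contact of length ~1.5 `G1d` stays under the area
  tolerance.
* The minimizer warns (and keeps the best feasible iterate) rather than
  aborting on non-convergence; stiff steps retry the minimization up to
  three times within the step. Division halves are nudged apart by
  0.01 `G1d` to avoid exactly coincident edges.
* Degenerate inputs error early: non-finite vertices, polygons with the
  wrong vertex count or non-positive area, coincident cable anchors,
  zero-length segments, division of a non-M nucleus, and configurations
  whose seed cannot be placed or relaxed.
* Problem sizes in the test suite and acceptance script are scaled-down
  versions of the full experiment (early windows, fewer replicates); the
  full 20-replicate, 44-hour ensemble runs through the same code path via
  `experiment_growth()`.

## Known limitations

* The constrained minimum found each step is local and
  projection-assisted; mirrored initial conditions reproduce mirrored
  outcomes only to the solver's position resolution, not bitwise.
* Under extreme jamming the polish can force displacements whose energy
  cost exceeds the per-step descent margin; the solver then falls back to
  the projected unmoved candidate, which slows (but does not corrupt)
  the dynamics.
* The apical anchor policy (fixed between remodeling events) and the
  junction-remodeling threshold are modeling choices on a point the
  underlying mechanics leaves open; both are parameters.
* With the basal gate enabled and small `lambda`, G1 nuclei high in the
  column may never enter S; this is the intended behavior of the two-gate
  model, not an artifact.
* Under the frozen calibration, G2 transit is strongly bimodal: nuclei
  that complete S adjacent to the apical surface divide within the hour,
  while nuclei deeper in the column mostly arrest. The ensemble G2
  fraction therefore rises chiefly through arrest accumulation rather
  than through a smooth population-wide lengthening of completed G2
  durations; the completed-duration series rises only modestly between
  the early and middle entry windows before survivorship censoring takes
  over. Position exchange between a pushing G2 nucleus and a passive
  neighbor is the rate-limiting (and most numerically delicate) process
  in a strictly non-overlapping 2D packing; see the solver notes above.
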