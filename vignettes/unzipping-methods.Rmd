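---
title: "Coarse-grained nanopore unzipping of knotted DNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained nanopore unzipping of knotted DNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(knotpore)
```

## The system

A double-stranded DNA filament is driven through a cylindrical pore embedded
in a slab. The pore in its narrow setting (1.87 nm nominal diameter, 0.95 nm
steric range, net aperture about 1 nm) admits a single DNA strand, so driven
translocation forces the duplex to unzip at the pore mouth: one strand
threads through, its complement is released on the cis side. When the duplex
carries a knot, the knot cannot pass (any knot at the pore presents at least
three strands) and remains at the cis entrance, where the chain must slide
along its own knotted contour — *topological friction*. The package builds
these systems, evolves them with Langevin dynamics, and tracks both the
unzipping progress and the knotted region itself.

## The model

dsDNA is represented as a two-strand bead-spring **ladder**: one bead per
nucleotide per strand at `bond_r0 = 0.5` nm rise, with

* harmonic backbone bonds (`bond_k = 800` pN/nm),
* Kratky–Porod bending on each strand (`bend_kappa = 200` pN nm on duplex
  strands, `bend_kappa_ss = 8` pN nm on the single-stranded lead, giving
  ssDNA its ~1 nm flexibility),
* breakable Morse base pairing (depth `pair_depth = 30` pN nm ≈ 7 kT, rest
  separation `pair_r0 = 1` nm, broken irreversibly beyond
  `pair_break_cutoff = 1.5 pair_r0`; re-formation is off by default because
  unzipping is effectively irreversible at the studied forces),
* a pairing **orientation term** `pair_perp * (u·t)^2` (default 60 pN nm)
  that penalizes alignment of the pair vector `u` with the local strand
  tangent `t`. Base pairs are lateral to the backbone; without this term a
  ladder duplex can tilt its rungs along the pore axis and thread the narrow
  pore in single file *without* unzipping, which would defeat the geometry
  the narrow pore is meant to impose,
* WCA excluded volume with `ev_sigma = 1` nm (the strand diameter; together
  with `pair_r0` this gives the duplex its B-DNA-like 2 nm width), and
* a screened Debye–Hückel repulsion with `debye_length = 0.3` nm (1 M
  monovalent salt), truncated (shifted-force) at 2.5 screening lengths. At
  this salt the screening length is well below the excluded-volume diameter,
  so the term is a small correction retained for configurability.

Units are nm, pN and pN nm with `kT = 4.1` pN nm (about 297 K) and unit bead
mass, which defines the time unit τ. Stacking, twist–bend coupling,
sequence-dependent pairing and rigid-body nucleotides are deliberately out
of scope: the ladder model is the package's own stand-in for a
full-resolution DNA force field, chosen so the pore-scale phenomenology can
be reproduced at desk scale.

### Why the duplex geometry matters

Two geometric contracts define the study: the narrow pore must pass one
strand and block a side-by-side pair, and the wide pore (4.25 nm) must pass
one duplex but never a knot. Both are properties of the *relative* widths of
strand, duplex and aperture. With a thin strand and a wide ladder
(σ ≪ pair separation) a compact bundle of six strands is no wider than one
duplex and a knot slips through the wide pore; the defaults therefore place
the strands in contact (σ = `pair_r0` = 1 nm), and the pore wall — a
quadratic ramp of stiffness `wall_k = 2000` pN/nm continued linearly inside
the slab material — acts on the bead surface (`steric_range/2 +
bead_contact` on bead centres). Verified consequences: a single strand
passes the narrow pore with a ~0.4 kT squeeze while a paired dimer faces a
140 kT barrier; the wide pore passes a duplex freely while a three-duplex
bundle at realistic packing faces > 80 kT; in dynamics the knot stays on the
cis side of both pores.

## Protocols

`run_translocation()` applies a constant total force, split equally over the
nucleotides currently inside the pore (so the applied total is constant
while the occupancy fluctuates), and integrates BAOAB Langevin dynamics
(`timestep = 0.004` τ, `gamma = 1/τ`, which is below the stability bound of
the stiffest term; a startup heuristic refuses unresolvable timesteps). The
translocated count Q counts strand-A nucleotides past the cis face —
equivalently the index of the nucleotide at the pore entrance — so traces
start at the 40-base threaded lead. Runs end at full translocation, at the
step budget, or when a stall detector sees no progress over a configured
window (stalled runs are flagged, not errors). `run_pinned()` is the
reference protocol: no driving force, one in-pore nucleotide held fixed.

## Synthetic setup

All inputs are generated internally:

* `sample_semiflexible_chain()` draws equilibrated self-avoiding discrete
  worm-like chains (crankshaft + pivot Monte Carlo, Metropolis on the
  bending energy, 2.4 nm hard core) with 50 nm target persistence length,
  monitored through the integrated autocorrelation time of the end-to-end
  distance; knotted samples are discarded and redrawn. (A 500 bp chain at
  0.5 nm rise spans 250 nm = 5 persistence lengths; spontaneous knotting is
  accordingly rare.)
* `build_tight_knot()` makes tight knotted leads from parametric curves
  (torus curve for 3₁, the standard figure-eight curve for 4₁; the granny
  knot as a connected sum of two like-handed trefoils). The sampling density
  is calibrated so the *measured* shortest-knotted-arc core is the 50 bp
  target; an unknot request adds nothing.
* `assemble_initial_state()` threads a 40-base single-stranded lead along
  the pore axis with its tip on the trans side, places the knotted segment
  at the cis mouth, re-orients the equilibrated coil (deterministically,
  tilting toward the cis half-space if needed) until it clears the slab, and
  builds both strands by parallel transport of the pairing frame. The
  contract — translocated count exactly the lead length, correct topology,
  knot on the cis side, no steric overlap above 0.9 nm — is verified, with a
  capped gradient-descent declash resolving residual contacts.
* `relax_pinned()` runs a short athermal quench (the spliced construction
  carries bond and bending kinks) followed by thermal pinned dynamics
  (default 20000 steps). The tight core loosens to lower its bending energy
  — with the defaults a trefoil core grows from ~50 to ~70–85 bp — and the
  knot type must be preserved.

Replicates draw independent streams from one study seed through a
counter-based expansion, and the same equilibrated conformations are reused
across knot types (the pairing scheme that isolates topology effects from
the cis-coil conformation).

## Knot detection and tracking

Knots are only defined for closed curves, so open chains are closed by the
**minimally interfering closure**: when the endpoints' distances to the
convex hull sum to less than their mutual distance, each endpoint exits
along its nearest hull direction to a far radius (10× the bounding radius)
and the exits are joined by an external arc; otherwise the endpoints are
bridged directly. Hull distances use the support function sampled over a
fixed 312-direction Fibonacci sphere — only the branch choice depends on
them, so this approximation is benign. Classification evaluates the
**Alexander determinants** |Δ(−1)|, |Δ(−2)| on the KMT-simplified ring
(vertices whose elimination triangle is uncrossed are removed first), with
projections drawn from a fixed deterministic rotation sequence and redrawn
on degenerate diagrams. The diagram determinant at t = −2 is defined up to a
power of two; the odd part is reported, which is the invariant for every
supported type. The pair separates the supported set
{0₁:(1,1), 3₁:(3,7), 4₁:(5,11), 3₁#3₁:(9,49)}; anything else is
`"unknown"`. Chirality is not resolved (Alexander determinants are achiral),
so granny versus square is a statement about the construction, not the
detector.

`shortest_knotted_arc()` is the bottom-up search: the shortest sub-arc whose
closure carries the target knot while the complement (the chain with the arc
replaced by a straight jump) closes to the unknot, enumerated on a coarse
stride (default 4 beads) and refined by unit steps, ties broken toward the
pore end. Tracking runs on the **strand-A path** (ss lead + threaded
strand), so reported bounds are nucleotide indices directly comparable with
the translocated count; this also keeps the knot visible in the rare state
where it straddles the duplex–lead junction at the pore mouth (a few beads
of slack below the pore-entrance index are therefore allowed when checking
that the knot never crosses the pore). Composite decomposition finds the
pore-proximal trefoil whose complement still carries the second one, then
locates the second in the remainder.

## Trace analysis

`unzip_trace()` extracts Q(t) with the applied-force audit;
`knot_kymograph()`/`knot_length_series()` give the boundary indices and the
inclusive length L = k2 − k1 + 1 (the convention is the package's own);
`time_to_mark()` interpolates first-passage times linearly between frames;
`heterogeneity_ratio()` is the slowest/fastest first-passage ratio of a
replicate set; `detect_velocity_regimes()` fits the best continuous
two-piece line over candidate breakpoints and compares it with a single line
by an F-test, Bonferroni-corrected for the breakpoint selection (α = 0.01);
`wrapping_turns()` accumulates the signed winding of the newly unzipped
cis strand about the stem axis between pore mouth and knot start.

## Calibrated force regimes

The ladder model's unzipping thresholds need not coincide numerically with
a full-resolution model's, so the phenomenological regimes are located by
the shipped scan (`calibrate_forces()`): below ~30 pN total the duplex does
not unzip on accessible time scales; 40 pN is the **low-force regime**
(steady unzipping whose velocity is indistinguishable between knotted and
unknotted chains); 100 pN is the **high-force regime**, where trefoil-led
chains unzip 15–20 % slower with seed ranges that no longer overlap, and
the knot tightens at the pore entrance (core length dropping from ~80 to
~40 bp) while the pinned reference loosens over the same model time. These
regimes were frozen as the study defaults after the calibration scan at
n_bp = 100, five seeds.

## Study sizes

The shipped tests and acceptance analyses run at reduced scale — chains of
50–100 bp plus the 50 bp knotted lead and 40-base threaded lead (about
300–500 beads), five replicate seeds per condition, runs of order 10⁵–10⁶
steps — sizes chosen so a complete study executes on one desktop CPU core
in minutes while still exhibiting every qualitative regime: the unzipping
force threshold, low-force topology independence, high-force topological
friction and knot tightening, and pinned-reference loosening.

## What the generator does and does not emulate

The synthetic stage reproduces the *structure* of the study inputs:
equilibrated cis coils at the DNA persistence length, pre-tightened knotted
leads of the right type and core size, a threaded lead, and pinned
relaxation. It does not emulate sequence heterogeneity (pairing is
sequence-averaged), helical twist or torque transmission (the ladder carries
no twist degree of freedom, so unzipping-generated torsion and the resulting
cis-strand wrapping are weaker than in a helical model), hydrodynamics, or
ionic-current readout. Passing tests therefore demonstrate the topological
and mechanical phenomenology of the model class, not quantitative agreement
with experiments or with rigid-body nucleotide force fields.

## Known limitations

* **Wide-pore jamming is not reproduced.** With the wide pore the knot
  stays on the cis side and visibly tightens with force (L ≈ 52 → 24 bp
  over 40 → 400 pN), but the translocation velocity remains essentially
  linear in the driving force up to far beyond the study range: the smooth
  WCA/Morse/harmonic potentials lack the surface corrugation that lets a
  force-tightened knot jam, so runs end by the knot sliding off the free
  chain end instead of stalling. The package runs the experiment and
  reports the measured ordering honestly; reproducing force-induced
  stalling would need a corrugated (grooved or rigid-body) interaction
  model.
* Knot boundaries from the bottom-up search carry a few beads of
  detection noise; planted-knot tests bound this at ±5 beads.
* The pinned reference at desk scale can untie by end escape (the free
  tail is only ~2 knot lengths); the kymograph records such frames as gaps
  rather than extrapolating.
* A 500 bp chain at the 0.5 nm ladder rise spans 5 persistence lengths
  (the commonly quoted 0.34 nm rise would give 3.4); either way spontaneous
  knotting of the cis coil is negligible, which is what the study design
  requires.
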