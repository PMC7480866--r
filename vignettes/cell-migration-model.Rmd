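---
title: "A fluid-structure model of single-cell migration through a deformable ECM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fluid-structure model of single-cell migration through a deformable ECM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stokescell)
```

## The model

`stokescell` simulates the mid-plane cross-section of a single animal cell
migrating through a fibrous extracellular matrix (ECM).  Three structures
interact through a common viscous fluid:

* the **cortex** -- the cell's actomyosin shell, a closed elastic contour of
  `Nc` nodes with per-node stiffness `k^c(s)` and tangent rest length
  `r(s)`;
* the **nucleus** -- a second closed contour of `Nn` nodes with constant
  stiffness `k^n` and rest length 1;
* the **ECM** -- random point nodes joined by virtual springs along the
  edges of a Delaunay triangulation, plus a tether ("pinning") force per
  node.

All lengths are normalized to the resting cell diameter (10 um), and the
fluid viscosity is normalized to 1; `time_unit_seconds()` converts one
simulation time unit to roughly 10 s using the physical scales
(viscosity 10 Pa s, size 10 um, net tension 10 pN/um).

### Fluid coupling

Every node applies a force to the fluid; every node moves with the fluid
velocity evaluated at its own position (no-slip, impermeable contours).
The velocity and pressure are superpositions of regularized Stokeslets for
the algebraic blob

\[ \phi_\epsilon(r) = \frac{3\epsilon^3}{2\pi (r^2+\epsilon^2)^{5/2}}, \]

which give closed-form kernels (with \(R=\sqrt{r^2+\epsilon^2}\)):

\[ u(x) = \frac{1}{4\pi\mu}\sum_k \Big[ f_k\Big(\ln\frac{L_0}{R+\epsilon}
   + \frac{\epsilon(R+2\epsilon)}{R(R+\epsilon)}\Big)
   + (f_k\cdot\hat x)\hat x \frac{R+2\epsilon}{R(R+\epsilon)^2} \Big], \]

\[ p(x) = \frac{1}{2\pi}\sum_k (f_k\cdot\hat x)
   \frac{R^2+\epsilon R+\epsilon^2}{R^3(R+\epsilon)}. \]

Both are finite at the source and reduce to the singular 2D Stokeslet in
the far field.  The test suite verifies the kernels against an independent
finite-difference residual of the forced Stokes equations
(\(\mu\Delta u - \nabla p + f\phi_\epsilon = 0\), \(\nabla\cdot u = 0\)).

**The screening length `L0`.**  In two dimensions the Stokeslet velocity is
defined only up to an additive constant per unit force (the Stokes
paradox); equivalently, the log kernel needs a length scale,
\(\ln(L_0/r)\).  The choice matters here because the ECM tethers carry a
non-zero net force while the lattice is deformed.  With the conventional
normalization (\(L_0=1\)) the kernel changes sign at \(r\approx 1\) cell
diameter, so the restoring forces of displaced far-away nodes push the
cell *away* rather than dragging fluid along their own direction -- a
spurious positive feedback that we measured as an exponential inflation of
the whole system with a growth rate of roughly 40 per time unit,
independent of the time step (i.e. a property of the continuous model, not
of the integrator).  We therefore fix the constant with an outer screening
length `L0 = 10` cell diameters -- larger than the lattice box -- so that
within the domain every force moves fluid along its own direction, as it
would in the presence of a distant quiescent boundary.  `L0` is exposed as
`flow_cutoff` in `sim_control()` and `cutoff` in `fluid_solution()`.

### Elastic forces

Segment tensions are \(T_m = k_m(\lVert\tau_m\rVert - r_m)\) with the
tangent \(\tau\) taken with respect to reference arclength; force densities
are centered differences of \(T\tau\) back onto nodes, so the total force
of a closed contour telescopes to zero exactly.  Contraction is imposed by
raising the stiffness (cortex: `k_cs = 1` relaxed, `k_cr` contracted) and,
for the rear-squeezing mechanism, lowering the rest length of the rear arc
to `r = 0.1`, which acts as an active tension.

The protrusion applies a force density `f0` along a fixed outward normal
at a chosen cortex node, half that at its two neighbours, and a balancing
backward density `-2 f0/(N-3)` everywhere else, so the protrusion exerts
zero net force on the fluid.  The default amplitude `f0 = 20 k_cs /
(pi/Nc)` extends the protrusion on a time scale (~0.1 time units) much
shorter than a contraction phase (~1-3 time units); the resulting finger
is one node wide, like the published snapshots of this class of model.

The ECM force on node i is
\(F_i = -k_{tether}(X_i - X^{ref}_i) - k^{ECM}\sum_{j\in N(i)}(X_i-X_j)\)
with `k_tether = k_ecm = 50`.  The tether references are precomputed so
the random lattice is exactly force-free at the start, while rigid
translations are penalized -- the lattice behaves as a Kelvin-Voigt
material with the fluid supplying the viscosity.

A small bending rigidity with the preferred curvature of the reference
circle stabilizes the nucleus while protrusions form.  By default
(`bending = "computational"`, `Kb = 0.05`) it is switched off during
contractile phases so it cannot oppose squeezing; `"physical"` keeps it on
throughout, `"none"` disables it.

## The two motility mechanisms

**Push-pull (mechanism 1).**  A protrusion center is drawn uniformly from
the front-half cortex nodes (outward normal with positive x-component).
The protrusion grows until its tip comes within `2*eps` of an ECM node;
the tip is then snapped onto the node ("binding": both points coincide and
therefore co-move with the fluid exactly), the whole cortex stiffens to
`k_cr`, and the system is advanced until every point speed falls below
`eps`.  The node is then released by moving it `2*eps` away from the
cortex, the system re-equilibrates, and the stiffness resets.  Protrusions
that reach four cortical radii without contact retract (global
stiffening); such cycles count as unsuccessful.

**Rear-squeezing (mechanism 2).**  Two protrusions grow from the front
half, 15-45 degrees apart.  The published description says the pair is
"positioned to grow towards two adjacent ECM nodes"; we implement this
literally: the side and offset (within the 15-45 degree band) are chosen
toward the angularly nearest reachable node, falling back to a uniform
draw when no node lies in the band.  When both tips have bound distinct
nodes, the longer (rear) cortex arc gets `k_cr` and rest length 0.1 while
the short leading-edge arc stays relaxed; the rear contraction squeezes
the nucleus through the gap between the bound nodes.  Per-protrusion
length is capped at two cortical radii (three on the first cycle), so the
total protrusive length matches mechanism 1.  If only one tip binds, the
whole system is contracted back to rest and the cycle is unsuccessful.

During the two-node bound phase the rear cortex packs and the front
stretches, so every 100 steps the cortex and nucleus are resampled at
equal arclength (linear interpolation of both current and reference
positions, with the same weights).  The seam of the resampling is anchored
at the first bound tip so attachments survive remeshing; the second tip is
remapped to the nearest new node and re-pinned to its ECM node.  At the
start of each rear-squeezing cycle the cortex reference configuration is
reset to the equispaced resting circle so all cycles begin alike.

## Numerical choices

* **Time stepping:** forward Euler, `dt = 0.001`, refined to
  `dt_fine = 2e-4` for 0.1 time units after every binding (the cortex
  stiffening transient).  In addition, a displacement limiter shortens any
  step in which the fastest point would move farther than `eps/2`: the
  post-binding snap of a highly stretched finger under `k_cr = 100`
  produces transient speeds of order 100 that no fixed step resolves, and
  sub-stepping only those transients keeps the scheme at the nominal steps
  everywhere else.
* **Geometry guards:** each step, ECM nodes strictly inside the cortex
  polygon (and cortex nodes inside the nucleus) are moved in random
  directions until outside (even-odd rule; points on an edge count as
  outside).  The kick length is the resolution scale (`kick_size = 0.02`),
  not the blob width: blob-scale kicks of a stiffened cortex node produce
  elastic shocks (forces of order `k_cr * kick / ds^2`) that re-inject the
  point and can lock the simulation into a kick/recoil chatter.  A point
  that a 50-kick random walk cannot free -- one that slipped deep through
  the stretched one-node-wide finger -- is ejected by a deterministic
  expanding direction search instead of aborting the run.
* **Blob width:** `eps = 0.1` cell diameters (1 um).  The value is tied by
  the model to the contact-capture radius (`2*eps`), the unbinding
  displacement (`2*eps`), the ejection kick (`eps`) and the equilibrium
  speed threshold (`eps`).  A resolution-tied value (half the cortex node
  spacing, `default_epsilon()`, about 0.02) makes the capture radius so
  small that protrusion tips, which deflect approaching nodes through the
  fluid they push, essentially never bind -- neither mechanism can
  complete a cycle.  A 1 um capture distance is a reasonable
  filopodial-adhesion scale and leaves the blob small compared with every
  cell-scale feature (cell diameter 10 eps, nucleus 9 eps).
* **Exclusion disk:** lattice nodes are excluded from a disk of radius 0.6
  around the initial cell center -- the cell radius plus a small
  clearance -- so the cell starts inside the mesh but touching no node.  A
  much larger moat would contradict the premise that the dense mesh
  (spacing ~0.5) is finer than the cell.
* **Equilibrium:** phases end when the largest point speed drops below
  `equil_tol`, with a hard cap (`max_phase_time = 50`) guaranteeing
  termination.  The rest threshold defaults to the *resolution* scale
  (0.02, about half the cortex node spacing), not to the enlarged blob
  width: with the threshold at 0.1 the slow creep of weak-tension regimes
  would be declared "at rest" long before their dynamics finish.  A
  protrusion whose tip stops extending along its own normal (less than
  0.05 progress over 0.5 time units) is retracted as stalled: a finger in
  elastic balance can never reach a node.
* **Determinism:** protrusion placement and ejection kicks draw from two
  independent seeded streams, so matched-seed runs of different stiffness
  regimes see the same protrusion sequence even if their ejection counts
  differ.

## Parameter regimes

The study organizes behaviour by the ordering of three characteristic
forces: T (cortical tension ~ `k_cr`), E (ECM deformation force ~
`k_ecm`), and N (nuclear deformation force ~ `k_n`).  `regime_presets()`
lists the ten named presets (five orderings x two mechanisms); all use
`k_ecm = 50` and relaxed cortex stiffness 1.  The immobile ordering
(E > T, N > T) is available as `"m1:stuck"` / `"m2:stuck"`.

## What the lattice generator does and does not emulate

`generate_ecm()` draws nodes uniformly on the box [0,4] x [-2,2] minus the
exclusion disk and triangulates once; springs never re-wire as nodes move.
A hard-core minimum spacing -- by default three quarters of the
hexagonal-packing spacing for the requested node count -- spreads the
nodes evenly; for 60 nodes this reproduces the stated dense-mesh size
(mean nearest-node distance about 0.45-0.5 cell diameters, so gaps
narrower than the nucleus), and it also keeps the `2*eps` contact logic
well posed.  This captures the coarse geometry of a fibrous network -- pore
sizes above or below the cell diameter for 20 or 60 nodes -- but not fiber
geometry, crosslink dynamics, plasticity, or proteolysis.  Passing tests
on these lattices therefore demonstrate the mechanics of squeezing through
a deformable point-obstacle network, not fidelity to any particular
collagen architecture.  Note that for 20 nodes on this box the mean
nearest-node spacing of a uniform draw is geometrically bounded near 0.9
(hexagonal packing); quoted mesh sizes of ~1.5 for sparse networks can
only refer to a different spacing notion (for example typical pore or
edge scales, which `lattice_spacing()` also reports).

## Problem sizes used in the tests

The packaged checks run at desk scale: two seeds per regime with 2-3
cycles per run for the ordering properties, three seeds for matched-pair
comparisons, and 50 seeds for lattice statistics; the acceptance script
uses five matched seeds and three replicates.  These sizes keep a full
check under a few minutes per mechanism while leaving the regime contrasts
well outside their seed-to-seed scatter.

## Known limitations

* The contours penalize stretching only; under strong rear tension the
  nucleus can buckle at grid scale, a known artifact of shear- and
  bending-free stretching energies (visible for the stiff-contraction,
  intermediate-nucleus ordering).
* Forward Euler plus point-force hydrodynamics conserves enclosed areas
  only approximately; the tests bound the drift at 2% per cycle.
* All fluids share one viscosity; variable nucleoplasm/cytoplasm/
  interstitial viscosities would change time scales per compartment.
* The 2D cross-section exaggerates confinement compared with a true 3D
  pore network; quantitative displacements are in cell-diameter units per
  cycle and should be compared between regimes, not with experiments.
* The 2-eps capture radius that makes binding reliable also means every
  successful binding tugs the cell a fraction of a diameter toward its
  node regardless of regime.  Regimes that cannot deform the nucleus or
  the ECM therefore still creep by roughly 0.1-0.2 diameters per cycle --
  they wedge against the mesh rather than stopping dead -- so
  "immobility" in this implementation is a statement about failing to
  pass gaps, not about literal zero displacement.
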