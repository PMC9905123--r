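---
title: "Locating binodal and spinodal lines from molecular dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating binodal and spinodal lines from molecular dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ljphase)
```

## The problem

Biological condensates (membraneless organelles) form by liquid–liquid phase
separation, and their *metastability* confines them to the band between the
binodal (coexistence) line and the spinodal line of the underlying fluid.
For protein solutions no trusted equation of state exists, so the two lines
must be located directly from simulation trajectories.  `ljphase` implements
a set of trajectory-based estimators for the canonical test system — the van
der Waals fluid realized as Lennard-Jones (LJ) monomers and as coarse-grained
bead–spring chains — so that each estimator can be validated where the answer
is known before being applied to more complex fluids.

All quantities are in reduced units: lengths in $\sigma$, energies in
$\epsilon$, mass in $m$, temperature in $\epsilon/k_B$, time in
$\tau_{LJ}=\sqrt{m\sigma^2/\epsilon}$.  Densities $\rho^*$ are monomers per
$\sigma^3$.

## Force field and dynamics

Particles interact through the plain-truncated 6–12 potential
$$\Phi_{LJ}(r) = 4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^{6}\right],
\qquad r < r_{cut},$$
with $r_{cut}=6.85\sigma$ at full scale.  No energy shift and no tail
correction are applied: phase-boundary locations are cutoff-sensitive, so
the truncation protocol is reproduced literally.  One consequence is worth
spelling out: the *reported* potential energy jumps by $\Phi(r_{cut})$
whenever a pair crosses the cutoff, so the conserved quantity of the
truncated-force dynamics is the cutoff-*shifted* energy.  The package
records both (`pe` and `conserved_energy()`); energy-conservation
diagnostics use the shifted form, all thermodynamic estimators use the
protocol's plain form.

Chains are lines of beads joined by stiff harmonic bonds
$U_{bond}(r)=k_b(r-\sigma)^2$ with $k_b = 75000\,\epsilon/\sigma^2$, strong
enough to hold bonded beads at $\sigma$.  Directly bonded pairs are excluded
from the LJ sum (the minimal exclusion consistent with bonds resting at
$\sigma$, where the LJ potential is strongly repulsive); all other
intra-chain pairs interact normally.

Integration is velocity-Verlet with $\Delta t = 0.005\,\tau_{LJ}$ for
monomers and $0.001\,\tau_{LJ}$ for chains (the bond vibration period is
$\approx 0.016\,\tau_{LJ}$, so the chain step resolves it with ~16 points).
Canonical sampling uses a Nosé–Hoover *chain* of three thermostat variables
coupled to the total kinetic energy (Martyna–Tuckerman–Klein splitting),
with damping time $1.0\,\tau_{LJ}$ (monomers) or $10\,\tau_{LJ}$ (chains).
A single Nosé–Hoover variable is not ergodic for weakly coupled systems:
because the builders rescale velocities exactly to the equipartition target
$(3/2)(n-1)k_BT^*$, an interaction-free gas would start *exactly at the
thermostat's fixed point* and produce zero kinetic-energy fluctuations.  The
chain form — which is also what mainstream MD engines default to — breaks
this degeneracy, and the chain velocities are additionally initialized from
their canonical Gaussians ($\mathrm{Var}(v_{\xi_k}) = k_BT/Q_k$) rather than
from zero.  Uniform velocity scaling preserves the exactly-zero total
momentum set by the builders.

Forces are evaluated through a Verlet neighbor list (default skin
$0.4\sigma$, rebuilt when any particle has moved half a skin) backed by a
cell grid whenever the box admits three cells per axis at the list cutoff,
and by an all-pairs sweep otherwise; both paths are checked against an
O($N^2$) oracle in the tests.

## Cluster analysis

Two atoms are in contact when their minimum-image distance does not exceed
$1.3\sigma$ (exposed as a parameter).  Atom-level clusters are connected
components of the contact graph; chain-level clusters are components of the
chain-quotient graph, two chains being linked by at least one inter-chain
contact.  Isolated particles count as clusters of size 1 — this keeps the
sizes an exact partition of the system and makes $\langle n\rangle$
well-defined at all densities (the alternative, dropping singletons, shifts
$\langle n\rangle$ upward at low density; either convention is defensible,
and the partition property is the more useful invariant).

Cluster geometry under periodic boundaries is computed by unwrapping each
cluster with a breadth-first traversal of its contact graph, placing every
member next to its parent by the minimum-image displacement.  The radius of
gyration is then the ordinary
$R_g = \sqrt{\frac{1}{n}\sum_i |r_i - r_{cm}|^2}$ of the unwrapped
coordinates.  A cluster is *spanning* when its unwrapped extent reaches the
box side along any axis **or** when the traversal reaches a member through
two inconsistent windings (a cycle through the boundary); the second test
catches percolating structures, such as rings, whose tree extent stays
below the box size.  When several clusters tie for largest, the one
containing the lowest particle index is "the largest" — an arbitrary but
deterministic rule that keeps the largest-cluster time series reproducible.

## The four boundary estimators

At each temperature, four densities are estimated from a density scan:

* $\rho_L$ (liquid binodal): the box is divided into cubic bins of side
  $2\sigma$ (about one particle diameter; for polymers the monomer-level
  gyration radius would set the scale).  The pooled probability $P_0$ of an
  empty bin decreases with density; $\rho_L$ is where it *vanishes*,
  operationalized as the first interpolated crossing below a threshold of
  0.005.  The threshold is a design choice — the qualitative statement
  "approaches zero" needs a number — and it is exposed as a parameter; the
  grid is anchored at the box origin and the sub-bin sliver left over along
  each axis is merged into the last bin (undersized slivers would otherwise
  inflate $P_0$).
* $\rho_V$ (vapor binodal): the mean size of the per-frame largest cluster,
  $\langle n_{lar}\rangle/n_m$, grows rapidly when droplets condense.  The
  detector takes the interval of maximum discrete slope of
  $\log\langle n_{lar}\rangle$ on the low-density side of the curve's
  half-maximum (log scale because cluster sizes span orders of magnitude),
  reporting the interval midpoint; a curve whose maximum slope does not
  exceed three times the median slope is declared featureless rather than
  assigned a boundary.
* $\rho_{sL}$ (liquid spinodal): the mean size over *all* clusters
  $\langle n\rangle$ undergoes its own rapid growth at a higher density,
  located the same way; it is cross-checked against the location of the
  $C_v(\rho)$ step down to the liquid value, detected as the steepest
  decrease after a width-3 median filter (an unfiltered steepest-decrease
  rule would mistake the falling edge of a grid-narrow spinodal-entry
  spike for the liquid-side drop).
  Disagreement beyond two grid spacings raises a consistency warning rather
  than silently picking one.
* $\rho_{sV}$ (vapor spinodal): entering the unstable region shows up as
  sudden spikes in the specific heat.  $C_v$ is estimated per state point
  from total-energy fluctuations, $C_v = \mathrm{Var}(E)/k_BT^{*2}$ (total
  rather than potential-only energy: the thermostatted dynamics makes both
  approximate the canonical value, and the total-energy form needs no
  analytic kinetic supplement; the potential-only variant is available).
  The boundary is the tallest local maximum on the low-density side of the
  $C_v$ drop that exceeds twice the gas-phase baseline — the baseline being
  the median over the lowest quartile of scanned densities, *not* over the
  whole low side, because the spinodal region itself has elevated $C_v$.

The expected ordering $\rho_V < \rho_{sV} \le \rho_{sL} < \rho_L$ is
validated on every assembled scan; violations are flagged in the output and
warned about, never silently reordered.  Every locator is a pure function
of its input curves.

A fluctuation-based surface tension accompanies the boundaries:
$\sigma_{ten} = k_BT^*/u^2$ with $u^2$ the time variance of a droplet's
linear size, taken as the $R_g$ series of the largest cluster over the
analysis window.  The estimator refuses to produce a number when the
droplet is smaller than 50 particles, ever spans the box, or the series is
shorter than 100 frames or constant — an undefined result is more useful
than an extrapolated one.

## Scanning and the critical point

`run_scan()` runs one NVT trajectory per $(\rho^*, T^*)$ grid point (one
seed per state point by default, matching a single-trajectory protocol;
multi-seed averaging is available), applies every estimator, and emits one
table row per state point; failures are recorded per row and the scan
continues, and a CSV cache makes long scans resumable.  The full-scale
protocol is $n_m = 4000$ monomers (or 200 twenty-bead chains; the chain
module equally supports the larger 400-chain system), $10^6$ steps
($5\times10^6$ for chains) totalling $5000\,\tau_{LJ}$, with the final
$1667\,\tau_{LJ}$ as the analysis window (equilibration fraction $2/3$) and
frames every $0.5\,\tau_{LJ}$.

`assemble_boundaries()` turns a scan table into per-temperature boundary
estimates and fits the critical point with the mean-field width law
$(\rho_L-\rho_V) = A\,(T_c-T)^{1/2}$ — the exponent is fixed at the van der
Waals value $1/2$, consistent with the mean-field setting; Ising scaling is
deliberately out of scope — together with a rectilinear-diameter regression
for $\rho_c$.  Squaring the width law makes the $T_c$ fit a linear
regression, so synthetic parabolic boundaries are recovered exactly; this
self-consistency is one of the package's acceptance checks.

## Scaled-down operation and what it can and cannot show

The full protocol needs hours per temperature on one CPU, so the package
ships a `desk` preset (1000 particles, $r_{cut}=4\sigma$, $5\times10^4$
steps) used by the test suite and the acceptance script; the suite further
reduces particle counts (400–1000) and step counts ($2$–$5\times10^4$) per
test so the whole run stays in tens of minutes.  Desk scale reproduces the
*mechanisms* — Poisson occupancy statistics in the gas, cluster growth at
condensation, the specific-heat anomalies, boundary ordering — but two
finite-size/finite-time caveats matter when comparing numbers against
full-scale references:

* Inside the metastable band the homogeneous fluid must nucleate a bubble
  (or droplet) to reach two-phase equilibrium.  In a $\sim 11\sigma$ box at
  $T^*=1.1$ the critical cavity is comparable to the box itself and the
  interfacial width ($2$–$3\sigma$ this close to $T_c$) is comparable to
  the cavity, so nucleation may simply not occur within a short window —
  seeded-slab and seeded-void initial states collapse back to the
  homogeneous fluid at these sizes, and an eightfold-longer run
  ($2000\,\tau_{LJ}$ at $\rho^*=0.55$) leaves $P_0 \approx 0.002$
  unchanged, confirming the homogeneous branch is the converged
  finite-size state.  Its empty-bin probability is *lower* than the
  two-phase value, which biases the desk-scale $\rho_L$ estimate downward:
  $P_0$ is already below the 0.005 threshold at $\rho^*=0.55$, so the
  crossing is reported at the scan's low edge rather than at the
  full-scale $0.64$.  This is a property of the scaled
  conditions, not of the estimator: the crossing rule applied to
  well-equilibrated $P_0$ curves recovers the full-scale answer.
* The synthetic generators used in tests (uniform ideal gas, compact
  blobs, cube corners) validate the estimators against closed forms, but
  they contain no interfaces, no slow collective modes and no
  chain connectivity — passing those tests shows the *statistics* are
  computed correctly, not that a given simulation length equilibrates a
  given state point.

Numerical details worth knowing: random placement rejects pairs closer
than $0.85\sigma$ (with a $100n$-attempt budget and a lattice fallback) so
initial forces are finite; occupancy grids guard the exact-multiple case
against floating-point (`floor(L/b + 1e-9)`); the NVE integrator aborts at
1% relative drift of the conserved energy; `r_cut` is clamped to half the
box side (with a warning) when a small test box cannot accommodate the
requested cutoff.

## Worked example

```{r example}
library(ljphase)

# a desk-scale state point in the two-phase region
pr <- preset("desk", "monomer")
traj <- run_state_point(0.10, 1.1, "monomer", pr$params, n = pr$n)

occupancy_histogram(traj, bin_side = 2)
trajectory_cluster_stats(traj, contact_cutoff = 1.3)

# a coarse density scan at T* = 1.1, then the four boundaries
tbl <- run_scan(seq(0.05, 0.85, by = 0.1), 1.1, "monomer",
                pr$params, n = pr$n)
estimate_boundaries(tbl, T_star = 1.1)
```

## Known limitations

Non-cubic boxes, NPT/barostats, long-range corrections, solid phases,
cavity-volume analysis, heterogeneous (amino-acid-like) interaction
matrices and finite-size scaling are out of scope.  Cluster identity is
tracked across frames only through the largest-cluster series; the surface
tension therefore assumes the largest non-spanning cluster is the same
physical droplet over the window, which can fail right at a boundary where
the largest cluster changes identity frame to frame.
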