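---
title: "A deformable capsomer model for T=1 capsid self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deformable capsomer model for T=1 capsid self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softcapsid)
```

## The model

`softcapsid` simulates the self-assembly of empty T=1 icosahedral virus
capsids from *deformable* coarse-grained capsomers. The basic assembly unit
is a trimeric capsid-protein subunit (the minute-virus-of-mice trimer is the
structural prototype) represented as a trapezoidal, truncated-prism block of
78 spherical beads. Unlike classical rigid-block capsomer models, the beads
are connected by an elastic network, so each subunit can stretch and bend
while it assembles.

The system Hamiltonian has three parts:

* **Inter-capsomer sterics.** Beads of different capsomers interact through
  truncated and shifted Lennard-Jones potentials with contact distance
  $\sigma_{ij} = R_i + R_j$. Most pairs are purely repulsive
  (Weeks–Chandler–Andersen form: $\varepsilon_{ij} = 1\,k_BT$, cutoff
  $2^{1/6}\sigma_{ij}$, shift $+1\,k_BT$). Pairs of *attractive* sites use
  well depth $\epsilon_{\mathrm{att}}$, cutoff $2.5\,\sigma_{ij}$ and the
  shift $-4\epsilon_{\mathrm{att}}\!\left[(1/2.5)^{12}-(1/2.5)^{6}\right]$,
  so that every potential is exactly zero at its cutoff.
  $\epsilon_{\mathrm{att}}$ is the model's main control parameter. No
  steric interaction is ever evaluated within a capsomer.
* **Bending.** Selected edges of the triangulated lateral walls carry
  $E_b = \kappa_b\,(1-\hat n_1\!\cdot\!\hat n_2)
       = \tfrac{\kappa_b}{2}\,|\hat n_1-\hat n_2|^2$,
  where $\hat n_{1,2}$ are the oriented normals of the two adjoining faces.
  The planar conformation has zero energy.
* **Stretching.** Every nearest-neighbour edge is a harmonic spring,
  $E_s = \tfrac{k_s}{2}(l - a_e)^2$, with the rest length $a_e$ equal to
  the as-built edge length, so the assembled template carries exactly zero
  elastic energy.

Charged capsomers add a screened Coulomb (Yukawa) term
$l_B q_i q_j e^{-r/\lambda_D}/r$ between all charged beads (intra- and
inter-capsomer), with Bjerrum length $l_B \approx 0.7$ nm for water at
298 K, Debye length $\lambda_D = (8\pi l_B n)^{-1/2}$ for a monovalent salt
of number density $n$, and a cutoff of $12\lambda_D$.

Reduced units are used throughout: length in small-bead diameters (1 nm),
mass in bead masses (32 Da), energy in units of $k_B\,298\,\mathrm{K}$. The
derived time unit is $\sqrt{m\sigma^2/\varepsilon} \approx 3.59$ ps (usually
quoted rounded as 3.5 ps), so the working timesteps 0.002 and 0.0005
correspond to about 7 fs and 1.8 fs.

```{r units}
us <- unit_system()
us
signif(5e-4 * reduced_time_unit() * 1e15, 2)   # dt = 0.0005 in fs
concentration_from_state(100, 59)              # the standard box, in uM
```

## Capsomer geometry

The template is built from four concentric triangular bead layers with
8/7/7/5 beads per edge (bottom to top). The bottom layer faces the capsid
exterior. Layer sides are 7, 6, 5 and 4 bead diameters, which means the
third layer is compressed (spacing 5/6) and the in-plane bead spacing is
exactly one diameter in the other layers. Because the layer inradii then
decrease linearly, a single vertical layer gap makes all four layer edges of
each lateral wall exactly coplanar; the gap is fixed by requiring the wall
planes to meet the bottom-layer normal at 53.9 degrees. The convention for
this inclination is the plane–line angle: a right prism (vertical walls)
would measure 0 degrees. One geometric consequence worth knowing: with the
in-layer spacing pinned at one bead diameter, the 53.9-degree constraint
makes the inter-layer bead distances come out near 0.6 diameters, so the
wall is a dense bead carpet rather than a close-packed one. Rest lengths are
taken from the built geometry, so this costs no energy.

Interior volume is filled by two large beads (radii 1.8 and 1.2 nm) instead
of a space-filling lattice, plus a small apex bead that plugs the top
opening. Every frame bead is tethered to both interior fillers by
(non-bending) springs; these tethers are what give the wall beads their
out-of-plane stretch restraint, since all other springs of a planar wall lie
in the wall plane.

Binding is driven by attractive ("blue") sites embedded in the second and
third layers of each lateral wall: the three central beads of the
third-layer edge plus two dedicated sites at second-layer height, placed
1.4 spacings either side of the wall centre. All five protrude 0.2 nm
outward along the wall normal. The protrusion matters: it lets two bound
faces adhere through their attractive patches while keeping the repulsive
wall beads of the partner out of steric contact, without which thermal
undulations of the walls push bound capsomers apart. The patch size and
placement constitute the model's binding-energy calibration: at
$\epsilon_{\mathrm{att}} = 2$ a bound face contributes about
$14\,k_BT$ of attractive energy.

```{r template}
tpl <- build_template(kappa_b = 10, k_s = 1000)
tpl
validate_template(tpl)
```

Counting: the four layers contribute $21+18+18+12 = 69$ frame beads; with
the two interior fillers that is 71 of the 78 beads. The remaining seven
small beads are the six embedded wall sites (two per wall, preserving the
three-fold symmetry, which an odd count could not) and the apex plug.

Bending edges are the interior mesh edges of the wall triangulation whose
two adjoining faces are coplanar as built — this excludes the wall
boundaries, the corner-to-corner slant edges, all edges involving the
interior beads, and the third-layer edges at the protruding attractive
beads. All bending edges therefore start exactly at the zero of the bending
energy. The bend-edge set is exposed in `tpl$bends` for inspection.

Charged capsomers put $+0.5\,e$ on each of the three central beads of the
three top-layer edges ($+4.5\,e$ per capsomer).

## Elastic moduli

$\kappa_b$ (in $k_BT$) and $k_s$ (in $k_BT/\mathrm{nm}^2$) are the model's
deformability dials. Five study points span rigid to very soft:
$(\kappa_b, k_s) = (5000, 5000), (10, 1000), (10, 500), (10, 300), (5, 300)$.
"Rigid" capsomers are the same elastic network with both moduli at 5000,
not constrained rigid bodies. Experimental estimates for virus shells span
roughly 10–1000 in both quantities, so the deformable study points sit
inside the physically relevant range.

## Dynamics

Time evolution is velocity Verlet. NVT sampling at 298 K (reduced
temperature 1) wraps each step in half-steps of a Nosé–Hoover chain
thermostat — chain length 3, Suzuki–Yoshida subcycling, coupling time
$\tau_T = 100\,dt$ by default; the chain's conserved quantity is tracked in
the sample stream as a health check. NVE and damped-quench modes exist for
validation and fixture preparation. The timestep is 0.002 for the rigid
moduli and 0.0005 for deformable ones; the stiffer intra-capsomer forces of
soft-but-strongly-stretched networks need the smaller step for energy
conservation, and `sim_config()` enforces these bounds.

Initial configurations place capsomers at uniform random positions and
orientations without bead overlaps; initial velocities are uniform on
$[-0.5, 0.5]$ per component with the mean removed, following the model's
stated protocol. A bare uniform draw corresponds to a kinetic temperature
near $1/12$, so runs started this way pass through a heat-up transient.
For carefully prepared states (an energy-minimised bound dimer, say) that
transient is violent enough to eject a $15\,k_BT$ contact, so
`init_velocities()` can rescale the same draw to the target temperature;
the fixtures and the acceptance protocol warm-start this way, while
production runs keep the plain cold start.

Neighbor search treats each capsomer as a mobile cell: a Verlet-type search
over capsomer centroids (extent + cutoff + skin) is refined to a bead-pair
list, which is rebuilt whenever any bead has moved half the skin (0.4 nm by
default). The list is provably complete against an all-pairs search in the
test suite.

## Assembly metrics

* `find_clusters()`: single-linkage components over capsomers, linking two
  capsomers when their minimum bead–bead centre distance is below
  $d_{\mathrm{cut}} = 1.5\sigma$. Bound attractive sites sit near
  $2^{1/6}\sigma \approx 1.12\sigma$, comfortably inside the cutoff, while
  centroid distances of bound capsomers never get that small — hence the
  minimum-bead-distance convention.
* `nmax_over_window()` / `nav_distribution()`: the windowed maximum cluster
  size $N_{\max}$ and the average number of capsomers $N_{\mathrm{av}}(N_c)$
  residing in clusters of size $N_c$, averaged over a trailing 2 ns window
  (557 reduced time units). $\sum_{N_c} N_{\mathrm{av}}(N_c) = N$ in every
  window.
* `classify_assembly()`: size classes fluid ($N_c \le 3$), partial
  (4–15), capsid (16–20), malformed ($N_c > 20$). A complete T=1 capsid
  contains 20 trimers, so anything above 20 cannot be a single capsid; the
  overlap in the class definitions is resolved that way. Classification is
  by size only; no shape inspection is attempted.
* `fluctuations()`: RMS deviation of stretch-edge lengths from their rest
  lengths, and RMS deviation of bending-edge dihedrals from planarity (the
  zero-energy reference, not the time-mean angle), optionally normalised by
  a rigid-baseline report.
* `face_binding_energy()`: the summed attractive pair energy across a bound
  dimer's shared face.

## Worked example: binding energy of a bound face

```{r dimer, eval = FALSE}
dimer <- make_bound_dimer(eps_att = 2, kappa_b = 10, k_s = 1000)
find_clusters(dimer)              # 2: one bound pair
total_energy(dimer)               # quenched attractive energy about -20 kBT
st <- init_velocities(dimer, seed = 1, temperature = 1)
run <- run_md(st, 6000, dt = 5e-4, sample_every = 100)
mean(run$samples$steric_attractive[run$samples$step >= 500])  # about -14
```

A lone bound dimer at $\epsilon_{\mathrm{att}} = 2$ is *transient*: its
bonds peel site by site on nanosecond timescales, consistent with the
transient-bond picture of productive capsid assembly (assembled shells are
stabilised by multivalency — every interior capsomer binds three
neighbours). The binding-energy protocol therefore averages each replica
over its bound period and pools several velocity replicas.

## What the scaled-down experiments show

Full production runs (100 capsomers, about 200 ns, i.e. 30–120 million
steps) are outside a desk-scale test budget. The package's quantitative
checks instead use:

* exact analytic targets (geometry, units, potentials) — instantaneous;
* conservation and oracle checks (NVE drift, finite-difference forces,
  neighbor-list and cluster-label equality against brute force);
* scaled-down physics: three dispersed capsomers for $2\times10^5$ NVT
  steps per moduli pair for the fluctuation measures, and the bound-dimer
  protocol above for the binding energy.

With these conditions the edge-length fluctuations of the $(10,1000)$ and
$(5,300)$ systems come out about $2.6\times$ and $4.9\times$ the rigid
baseline, and the bending-angle fluctuations about $15\times$ and
$25\times$; fluctuations grow monotonically along the softness sequence,
with the edge measure essentially flat on the last step, where only
$\kappa_b$ changes. The corresponding harmonic expectations
($\sqrt{5000/1000} \approx 2.2$, $\sqrt{5000/300} \approx 4.1$) are
exceeded somewhat because soft-wall bending couples geometrically into edge
stretching.

The qualitative assembly transition — singleton-dominated
$N_{\mathrm{av}}$ at weak attraction versus aggregate-dominated at strong
attraction — is demonstrated on the dimer in its stable directions in the
test suite. The full dispersed-system version needs about $10^6$ steps for
10–20 capsomers so diffusion can bring subunits together; the recipe is:

```{r transition, eval = FALSE}
tpl <- build_template(10, 1000)
low <- place_capsomers(15, 25, tpl, seed = 1, eps_att = 1.2)
low <- init_velocities(low, 2)
run_low <- run_md(low, 1e6, dt = 5e-4, sample_every = 5e4)
high <- place_capsomers(15, 25, tpl, seed = 1, eps_att = 3.0)
high <- init_velocities(high, 2)
run_high <- run_md(high, 1e6, dt = 5e-4, sample_every = 5e4)
nav_distribution(cluster_report(run_low), window = 0.5)
nav_distribution(cluster_report(run_high), window = 0.5)
```

## What the generator does and does not emulate

The synthetic systems built by `place_capsomers()` and the fixtures
reproduce the study conditions of the model: identical capsomers, an
implicit solvent (no hydrodynamics, no friction — inertia-dominated
dynamics thermostatted globally), periodic boxes at high working
concentrations (800 uM standard), and parameter-controlled attraction,
elasticity and charge. They do not emulate heterogeneous subunit mixtures,
explicit genome/cargo, solvent-mediated interactions beyond the screened
Coulomb term, or experimental assembly kinetics at micromolar
concentrations. Passing the scaled-down tests shows the implementation
realises this model faithfully; it does not by itself validate the model
against any particular real virus.

## Numerical choices and limitations

* Minimum-image convention everywhere; boxes must exceed twice the largest
  interaction cutoff (enforced).
* Damped quench uses semi-implicit Euler with a global velocity reset when
  the power $F\cdot v$ turns negative — a robust, monotone minimiser for
  fixture preparation, not a production optimiser.
* The two-pointer wall triangulation breaks diagonal ties toward the
  shorter diagonal; the builder is fully deterministic and rebuilds are
  bit-identical.
* Dihedral gradients are the analytic derivative of
  $\hat n_1\!\cdot\!\hat n_2$ through both triangle normals, validated
  against central finite differences at $10^{-5}$ relative tolerance.
* Trajectory frames store wrapped coordinates; intra-capsomer geometry is
  reconstructed through minimum-image differences, which is valid while a
  capsomer is smaller than half the box.
* Checkpoints are RDS containers holding the full state (positions,
  velocities, thermostat chain, step counter); restarts are bit-identical.
* Version 1 plants no complete 20-capsomer icosahedral capsid fixture
  (closure geometry is unsolved here); assembled-capsid statistics must
  come from production runs.
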