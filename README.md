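# softcapsid

Coarse-grained molecular dynamics of **deformable viral capsomers** and
their self-assembly into T=1 icosahedral capsids.

Most bead-based capsomer models treat the subunit as a rigid block.
`softcapsid` implements a trapezoidal trimer subunit — 78 beads in four
triangular layers with two large interior fillers — whose beads are joined
by an elastic network, so the subunit stretches and bends while it
assembles. The package is aimed at soft-matter and structural-virology
modellers who want to study how subunit elasticity competes with
inter-subunit attraction during shell assembly.

The system Hamiltonian is

```
H = Σ_{i<j} 4 ε_ij [ (σ_ij/r_ij)^12 − (σ_ij/r_ij)^6 ]  + shifts
  + Σ_c Σ_e (κ_b/2) | n̂1 − n̂2 |²
  + Σ_c Σ_e (k_s/2) ( l_e − a_e )²           ( + Yukawa term if charged )
```

with truncated-shifted Lennard-Jones sterics between beads of different
capsomers (purely repulsive WCA for most pairs; well depth `eps_att`,
cutoff 2.5 σ for attractive-site pairs), dihedral bending relative to the
planar conformation, harmonic stretching relative to the as-built edge
lengths, and optional screened electrostatics
`l_B q_i q_j exp(−r/λ_D)/r` for charged capsomers. Dynamics are velocity
Verlet in the NVT ensemble (Nosé–Hoover chain thermostat) with a
capsomer-as-mobile-cell Verlet neighbor list. Reduced units: 1 nm, 32 Da,
kB·298 K (time unit ≈ 3.59 ps).

Analysis tools compute the standard assembly metrics: single-linkage
cluster sizes at cutoff 1.5 σ, windowed `Nmax` and `Nav(Nc)` statistics,
fluid / partial / capsid / malformed classification, RMS edge-length and
bending-angle fluctuation measures, and per-face binding energies.

## Worked example

Build a deformable capsomer, verify its geometry, and measure the binding
energy of a bound pair at steric attraction 2:

```r
library(softcapsid)

tpl <- build_template(kappa_b = 10, k_s = 1000)
tpl
#> Capsomer template: 78 beads (15 attractive), 359 stretch edges, 90 bend edges
#>   kappa_b = 10 kBT, k_s = 1000 kBT/nm^2, charge = 0 e
#>   wall inclination: 53.90 deg

concentration_from_state(100, 59)   # the standard 100-capsomer box
#> [1] 808.5243                      # micromolar, usually quoted as 800 uM

dimer <- make_bound_dimer(eps_att = 2, kappa_b = 10, k_s = 1000)
find_clusters(dimer)
#> [1] 2                             # one bound pair
#> attr(,"labels") ...

st  <- init_velocities(dimer, seed = 1, temperature = 1)
run <- run_md(st, 6000, dt = 5e-4, sample_every = 100)
mean(run$samples$steric_attractive[run$samples$step >= 500])
#> [1] -13.78                        # ~14 kBT of attraction across the face
```

The wall inclination (53.9° to the bottom-layer normal), the 78-bead
census, and the ≈14 kBT face binding energy are the model's anchor
numbers; the methods vignette (`vignettes/capsomer-model.Rmd`) explains
the geometry, the elastic network, the thermostat settings, and what the
scaled-down experiments do and do not show.

A thin command-line wrapper for shell use lives at
`inst/scripts/softcapsid` (subcommands `build`, `run`, `analyze`).

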