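---
title: "Coarse-grained dendrimer-surfactant assembly: model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained dendrimer-surfactant assembly: model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrisurf)
```

## The system

`dendrisurf` simulates and analyses the self-assembly of terminally charged
cationic dendrimers with anionic surfactants in implicit solvent.  The model
has seven bead species:

* **dendrimer beads** — a core of two bonded monomers, trifunctional branch
  points, and spacers of `S` bonds; the outermost shell after `G` branching
  generations carries the terminal groups, each with charge +1e.  The
  terminal count of the explicitly built tree is `N_t = 2^(G+1)`
  (`dendrimer_topology()` exposes both `N_t` and the total monomer count
  `N_d` as computed properties of the tree rather than as formulas).
* **surfactants** — linear 4-bead chains: one head bead with charge −1e and
  three neutral hydrophobic tail beads.
* **counterions** — one monovalent anion per dendrimer terminal and one
  monovalent cation per surfactant chain, making every assembled system
  exactly electroneutral.

This charge pattern mimics PAMAM-type cationic dendrimers at neutral pH
complexing with single-tail ionic surfactants.  Charges are fixed; there is
no pH or charge-regulation model.

## Reduced units

Energies are measured in `epsilon_u = kB * T_r` with `T_r = 298` K, lengths
in `sigma_u = lambda_B(eps_r = 81, T_r)`, the Bjerrum length of water at
room temperature (about 7 Å), and the mass unit defaults to 30 g/mol per
bead.  Two consequences give the model its convenient electrostatics:

* the reduced Bjerrum length is exactly 1, so the Coulomb pair energy in
  thermal units is simply `z_i z_j / r*`;
* the reduced elementary charge satisfying
  `e*^2/eps_r = lambda_B*/sigma_u* = 1` is `e* = sqrt(81) = 9`.

The LJ time unit is `t_u = sigma_u * sqrt(m_u / epsilon_u)`, about 2.4 ps.
`unit_system()` computes the full table.

## Force field and integrator

Three interactions act between beads (`force_field()`):

* **Truncated-and-shifted 12-6 LJ.**  Tail-tail pairs attract with
  strength `eps_tt` (1.25, 1.5 or 1.6, the hydrophobicity dial) and cutoff
  2.5 sigma; every other pair uses strength 1 with cutoff `2^(1/6)` sigma,
  i.e. the purely repulsive WCA form that models good solvent.
* **FENE bonds** with `k* = 30`, `R0* = 1.5` (the standard Kremer-Grest
  parameterisation; bonded pairs keep their LJ interaction, and no
  Coulomb exclusions are needed because charged beads are never bonded to
  each other in this topology).
* **Coulomb**, `z_i z_j / r` in thermal units, with real-space cutoff 10
  sigma.

The integrator is a BAOAB splitting of the underdamped Langevin equation
at `T* = 1`, `gamma* = 1`, `dt* = 0.005`.  With `gamma* = 0` it reduces
exactly to velocity Verlet, which is how the energy-conservation tests
probe the force routines.  Because the published study used a particular MD
engine only as a black box, step-for-step equivalence with it is neither
possible nor needed; the tests target stationary-distribution properties
(kinetic temperature, NVE drift, gradient consistency) instead.

Thermostat noise comes from an internal xoshiro256++ generator seeded from
R's RNG stream, so `set.seed()` reproduces a run exactly, and the generator
state travels with the returned trajectory: a run restarted from a
checkpoint at a neighbour-list boundary reproduces the uninterrupted run
bitwise.

### Electrostatics solvers

Two solvers sit behind one interface:

* `ewald_coulomb()` — classical Ewald summation with splitting and
  reciprocal-space cutoffs derived from a force-accuracy tolerance
  (default `1e-4`).  This is the accuracy-critical reference mode; tests
  verify it against an independent plain-R Ewald implementation and the
  NaCl Madelung constant.
* shifted-force cutoff truncation at 10 sigma — the default for desk-scale
  dynamics.  At the dilute concentrations studied here the aggregation
  statistics are driven by the short-range hydrophobic attraction and
  local head-terminal electrostatics, and the cutoff (a third of the
  desk-scale box) captures those while keeping million-step runs within
  minutes.  The full-scale preset (`run_config("paper")`) keeps `ewald`.

Neighbour search uses Verlet pair lists (split by pair type, skin 0.8
sigma) rebuilt at fixed 20-step boundaries; rebuild times are aligned to
the global step count precisely so that checkpoint restarts stay bitwise.
An O(N²) brute-force distance path (`neighbor_pairs()` fallback and the
plain-R test oracles) is retained for validation.

## The aggregate taxonomy

All classification uses one contact distance `r* = 1.5` sigma, compared
strictly (`< r*`) on minimum-image center-to-center distances:

* **micelle** — maximal set of surfactant chains in which each chain has a
  tail bead within `r*` of a tail bead of another chain of the set
  (connected components of the chain-binding graph).  A single unbound
  chain is a mass-1 micelle, a *unimer*.
* **bound** micelle/dendrimer — at least one head of the micelle within
  `r*` of at least one terminal of the dendrimer.  A micelle bound to no
  dendrimer is *free*, to exactly one a *corona* micelle, to two or more a
  *bridge* micelle.
* **mixed cluster** — connected component of the bipartite
  micelle-dendrimer binding graph; dendrimers with no bound micelle are
  free `(0,1)` aggregates and free micelles are `(s,0)` aggregates.
* **condensed counterion** — within `r*` of at least one bead of an
  aggregate.  When a counterion is within `r*` of several aggregates it is
  assigned to the aggregate owning the nearest bead.  This exclusive
  assignment is a design choice (the source material does not address
  multiplicity): it makes the per-frame charge ledger
  `sum(ch) - (free anions) + (free cations) = 0` an exact identity, which
  the tests then verify on every analysed frame.  `exclusive = FALSE`
  switches to counting the ion on every proximal aggregate.

The effective charge of an `(s, d)` aggregate is
`ch = d*N_t - s + n_sc - n_dc`.

## Aggregate indexing and statistics

An aggregate `(s, d)` with `s > 0` is encoded as the single integer
`n_sd = d*n_s + s`; the free dendrimer `(0,1)` is encoded as 0.  The
inverse uses integer division, `d = (n-1) %/% n_s`, `s = n - d*n_s` —
the unique rule consistent with the stated ranges, verified by an
exhaustive round-trip test.

`aggregate_stats()` accumulates, over analysed frames: per-frame histograms
of the absorbed-surfactant count and of the numbers of free micelles, free
dendrimers and mixed clusters; mass histograms of free, bridge and corona
micelles; the index histogram `H(n_sd)` with per-index occurrence counts;
index-conditioned means of micelle number/mass, condensed counterions and
effective charge; and the mean fractions `f_s`, `f_dc`, `f_sc`.
Index-conditioned means are reported only for indices observed strictly
more than `min_occurrence = 10` times — occurrence of exactly ten is
excluded — matching the reliability rule of the underlying study.

**Favored clusters.**  `favored_clusters(stats, d)` restricts `H(n_sd)` to
the d-dendrimer range `(d*n_s, (d+1)*n_s]`, drops zero-count bins (so gaps
are merged), and declares a bin a local maximum when strictly greater than
both retained neighbours (one neighbour at the range ends).  Among local
maxima the highest count wins; ties resolve to the lower index with a
warning.  A window-3 moving average can be applied first (`smooth = TRUE`,
off by default).  These conventions are the package's own choices where
the source analysis did not state its peak-finding rule; the constructed
histogram tests pin them down.

## Planted configurations

Because no deposited reference data exist for this system, every analysis
stage is validated against `plant_frame()`/`plant_trajectory()`: generators
that realise a requested aggregate structure geometrically with a safety
margin of 0.2 sigma on both sides of `r*` (intended contacts at
`r* - margin` or closer, everything else at `r* + margin` or farther), so
the distance criteria are unambiguous.  Each aggregate occupies its own
well-separated region; micelle tails form a tight cluster with heads on a
surrounding shell — a cartoon of the dense hydrophobic core and charged
corona of a real micelle — and each intended micelle-dendrimer bond is
realised by placing a dedicated terminal bead next to a head.  A
verification pass asserts every margin before the frame is returned.

Planted frames are deliberately *not* thermodynamically realistic: they
validate classification logic, not physics.  What a passing planted-frame
test shows is that the implementation applies the stated distance criteria
exactly; what it cannot show is whether the dynamics produce realistic
aggregates — that is what the engine-physics and scaled-down dynamic
checks are for.

## Problem sizes and run lengths

The published study used two dendrimers, 600 chains, box `L* = 70` and
10^7 production steps.  The package supports that configuration
(`run_config("paper")`) as a long-running mode, but its test suite works
at desk scale: one G3S4 dendrimer, 60 chains with matching counterions,
`L* = 30` (`run_config("desk")` — the same chain concentration to within
25%).  For the qualitative hydrophobicity checks the desk runs integrate
10^6 steps and discard the first half as equilibration; absorption
equilibrates by micelle diffusion onto the dendrimer, which at this
density takes several times 10^5 steps, so shorter runs measure kinetics
rather than the stationary state.  Because absorption at intermediate
hydrophobicity happens by attach/detach of whole micelles, single desk
runs fluctuate strongly; the qualitative checks therefore average three
independent replicas per hydrophobicity.  These runs resolve
direction-of-effect (monotone growth of the absorbed fraction `f_s` with
`eps_tt`, unimer-dominated free micelles at weak hydrophobicity) but not
the full-scale headline numbers, which require the 10^7-step
two-dendrimer runs.

## Known limitations

* No pressure coupling, explicit solvent, pH/charge regulation, or GPU
  path; cubic periodic boxes only.
* The shifted-force Coulomb default for desk dynamics trades far-field
  accuracy for speed; quantitative charge-sensitive observables at full
  scale should use `coulomb = "ewald"`.
* Histogram estimates carry no error bars; occurrence counts are exposed
  so users can bootstrap if needed.
* The favored-cluster peak rule (strict local maximum after gap merging)
  is one defensible convention among several; with `smooth = TRUE` the
  choice can matter for noisy histograms.
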