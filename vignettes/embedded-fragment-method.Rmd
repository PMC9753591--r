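---
title: "The embedded fragment method in efmr: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The embedded fragment method in efmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter and their
defaults, the synthetic-data generator and what passing tests do and do
not demonstrate, and the numerical decisions taken where the design was
genuinely open.

## The model

A cluster of `N` neutral, noncovalently bound monomers is treated by the
truncated many-body expansion

$$E \;\approx\; \sum_i E_i \;+\; \sum_{i<j}\,(E_{ij} - E_i - E_j),$$

exact at order `N` and truncated here at pairs.  Truncation alone is a
poor approximation for polar monomers such as water, because long-range
polarization is strongly nonadditive: the Coulomb field of all other
monomers shifts each fragment's density.  The embedded fragment method
restores the dominant part of that many-body polarization by solving
*every* monomer and dimer in an external potential representing the rest
of the cluster, so that three-body-and-higher Coulomb effects enter
through the embedding even though only one- and two-body subsystems are
ever solved.

The embedding potential is deliberately minimal.  The exact choice would
be the full Coulomb potential of every other monomer (nuclei plus
self-consistent density, as in the fragment molecular-orbital method);
`efmr` implements that operator (`coulomb_embedding_reference()`) but only
as a validation reference.  The production embedding truncates the
multipole expansion of each monomer's potential after the dipole term —
the monopole vanishes for neutral monomers, which is why charged
monomers are rejected at construction — and realizes the dipole as a
physical pair of point charges $(+e_j, -e_j)$ separated by a fixed
length $d$ along the dipole direction, centred at the monomer's
nuclear-charge centre (the unique point about which its nuclear dipole
vanishes, so nuclear and electronic contributions are consistently
referenced).  Self-consistency couples the fragments: each monomer is
solved in the field of all other sites, its dipole is re-evaluated, and
$e_j d = |\boldsymbol{\mu}_j|$ is re-imposed, until no site charge moves
by more than a threshold.

Assumptions worth keeping in mind:

* monomers are neutral and internally rigid closed-shell molecules;
* dimer-and-higher exchange and correlation between fragments are kept
  only at second order;
* the embedding represents electrostatics only — no exchange, charge
  transfer, or magnetic induction between fragments;
* quadrupole and higher multipoles of the embedding are dropped.

## Magnetic fields

A uniform field $\mathbf B$ (in units of $B_0 = 2.3505\times10^5\,$T)
adds the orbital Zeeman, spin Zeeman and diamagnetic terms to the
electronic Hamiltonian.  Two treatments are provided:

* **CGO** — real Gaussians with a single gauge origin.  Simple, but
  energies depend on the origin in any finite basis; configuring it
  therefore requires an explicit `allow_gauge_dependent = TRUE`, and the
  default origin is the cluster's nuclear-charge centroid.
* **LAO** — London atomic orbitals, each Gaussian multiplied by
  $\exp(-i\,\mathbf A(\mathbf C_\mu)\cdot\mathbf r)$ with
  $\mathbf A(\mathbf C) = \tfrac12\,\mathbf B\times(\mathbf C-\mathbf O)$.
  With this phase convention every integral depends only on *differences*
  of shell centres, so the gauge origin cancels analytically and
  observables are origin-invariant by construction.  The published
  rendering of the phase factor leaves its sign convention ambiguous; the
  implementation fixes the convention above and the test suite verifies
  the physically meaningful property (origin invariance of the energy)
  rather than a formula transcription.

At zero field both paths reduce exactly to real RHF, which the tests
assert at $10^{-9}$ hartree.  The embedding dipoles are recomputed in the
presence of the field (the complex density's real dipole), but the
embedding operator itself remains electrostatic: magnetically induced
contributions to the inter-fragment interaction are neglected, one known
limitation at very strong fields.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| dipole length `d` | 0.01 | bohr | small against every intermolecular distance, so the charge pair reproduces the ideal dipole potential to $O((d/r)^2)$; large enough that $e_j = |\mu_j|/d$ stays well-conditioned in double precision |
| embedding threshold | 1e-4 | a.u. on $\max_j|\Delta e_j|$ | charge changes below this alter subsystem energies by far less than the pair-truncation error |
| attenuation `mu` | `Inf` (off) | 1/bohr | Hartree–Fock densities are compact enough that the bare dipole converges; finite `mu` (ordinarily a few tenths) is the pragmatic remedy when close contacts destabilize the outer iteration |
| mixing | 0.5 | — | under-relaxation of the dipole update; plain iteration can oscillate when two polarizable monomers face each other |
| SCF energy / density tolerances | 1e-9 / 1e-7 | hartree / RMS | tighter than single-molecule practice because the expansion sums $O(N^2)$ subsystem energies and their errors accumulate |
| DIIS subspace | 8 | — | standard; fallback to damped iteration on extrapolation breakdown |
| overlap eigenvalue floor | 1e-8 | — | below this the (ghost-augmented) basis is declared linearly dependent, with the offending eigenvalue reported |
| `bond_scale` | 1.2 | × covalent-radius sum | fragment auto-detection; plain XYZ files carry no fragment annotation, so a conventional covalent-bond criterion partitions them, and the multiplier is tunable |
| dimer cutoff | `Inf` | bohr | optional radial cutoff on pair corrections; off by default so nothing is silently dropped |

Unit conventions live in one place each: coordinates are bohr internally
(XYZ files are angstrom, conversion 0.52917721092), energies hartree with
627.509474 kcal/mol per hartree for reporting.

## The synthetic cluster generator

`generate_water_cluster()` places rigid water monomers (r(OH) = 0.9572 Å,
∠HOH = 104.52°, the geometry fixed by rigid three-site water models) with
uniformly random positions and orientations in a cubic box, rejecting any
placement with an O–O distance below 4.7 bohr (2.5 Å), and is
bit-reproducible per seed.  The default box packs the monomers at liquid
water's ~30 Å³ per molecule, so neighbours sit at hydrogen-bonding
distances, emulating a droplet snapshot.  What it does *not* emulate:
thermal orientational correlations (random orientations do not favour
hydrogen-bond alignment, so a given seed can be net repulsive), an
equilibrated radial distribution, intramolecular relaxation, or any
field-induced geometry change.  Consequently, tests passing on generated
clusters demonstrate the *machinery* — exactness identities, limits,
invariances, trend directions — on realistic geometry scales; they do not
reproduce ensemble-averaged observables of real water.  Binding-related
trends (for example the field response of the mean interaction energy)
are interaction effects and are only visible on seeds whose random
packing actually makes contact; the fixed-seed fixtures used in the
suite are compact in this sense.

## Numerical choices

* **Cartesian Gaussians throughout**, no spherical transformation; AO
  order is atoms in input order, shells in basis-file order, Cartesian
  components $l_x \ge l_y \ge l_z$ lexicographic.  Every contracted
  component is normalized to unit self-overlap.
* **Boys functions.** Real arguments: the all-positive-term series with
  $e^{-T}$ prefactor and downward recursion below $T = 35$, asymptotic
  form with upward recursion above.  Complex arguments (needed for every
  LAO Coulomb kernel): the same series below $|T| = 43$ — its terms decay
  like the real case for the small imaginary parts London phases
  generate — and the principal-branch asymptotic above; validated against
  direct quadrature of $\int_0^1 t^{2m} e^{-Tt^2}\,dt$.
* **London integrals by complex centre shift.** The pair phase
  $e^{i\mathbf k\cdot\mathbf r}$ is absorbed by completing the square,
  shifting the Gaussian product centre to
  $\mathbf P + i\mathbf k/2p$; all McMurchie–Davidson recurrences then
  run unchanged in complex arithmetic.  The magnetic one-electron matrix
  is built directly as $\tfrac12\langle\pi\omega_\mu|\pi\omega_\nu\rangle$,
  which covers kinetic, orbital-Zeeman and diamagnetic terms in one
  Hermitian object and doubles as a cross-check of the separately
  assembled CGO matrices.
* **erf attenuation** is applied per point charge through the exact
  long-range-kernel identity (Boys argument scaled by
  $\mu^2/(p+\mu^2)$), not as a numerical damping of the summed dipole
  potential; the same $erf(\mu r)/r$ factor multiplies the
  nucleus–charge terms so electrons and nuclei feel one consistent
  potential.  Whether attenuation should multiply each charge or the
  summed potential was an open reading; per charge was chosen because it
  has an exact integral route, and the two differ only at
  $O((d/r)^2)$.
* **Jacobi outer iteration.** All embedding sites are refreshed
  simultaneously from the previous iteration's field, which keeps the
  monomer SCFs independent and parallelizable; a sequential
  (Gauss–Seidel) sweep would typically converge in fewer outer cycles
  but serializes the loop.  Iteration counts are therefore
  implementation-specific even where final fields agree.
* **Fixed `d`, directional update.**  The self-consistency updates the
  site charge magnitude and direction while `d` stays at 0.01 bohr;
  re-scaling `d` instead would be equivalent at the fixed point but
  worsens the conditioning of $e_j$.
* **GHF rather than UHF** for field calculations: the spin-Zeeman term
  is diagonal in $S_z$ for a z-aligned field, but a general spinor
  treatment keeps arbitrary field orientations and future spin-coupled
  extensions uniform.  A constrained per-spin occupation
  (`nalpha`/`nbeta`) is available for scanning $S_z$ sectors when the
  Fock matrix is spin-block-diagonal; the default is plain aufbau, which
  selects the ground sector automatically in the regimes the package
  targets (closed-shell monomers, moderate fields).
* **Deterministic reduction.** Subsystem energies are summed with
  compensated (Kahan) summation over sorted subsystem keys, so totals
  are bit-stable across worker counts and restarts.
* **Dense in-core ERIs** with a 400-AO guard: embedded subsystems are
  monomers and dimers by construction, so tensor sizes stay modest, and
  clarity wins over screening machinery.
* **Degenerate inputs.** Zero dipoles produce legal zero-charge sites;
  zero-charge embedding reproduces the unembedded result identically;
  single-monomer clusters converge their embedding in one outer cycle by
  construction.

## Problem sizes used in the tests

The suite runs water monomers through tetramers (plus a 12-molecule
cluster for fragment detection and a 20-molecule one for the distance
constraint) in the bundled STO-3G and 6-31G sets — 7 to 28 AOs per
subsystem.  These sizes make every identity checkable in seconds while
exercising all code paths (s and p shells, contracted and split-valence
bases, ghost atoms, complex tensors); nothing in the implementation is
specific to them.  The counterpoise and noninteracting limits are probed
at 500-bohr separations, gauge shifts at 5 bohr, and field scans over
0–0.02 $B_0$ with single points at 0.1–0.2 $B_0$.

## Known limitations

* Second-order truncation: three-body exchange/correlation beyond the
  electrostatic embedding is absent; the full-order expansion exists but
  only as an unembedded exactness oracle.
* Embedding is dipole-only and purely electrostatic (no quadrupoles, no
  induction by the magnetic field, no inter-fragment exchange).
* Correlation is MP2; no MP3/CC, and no density-functional backend in
  this package.
* CGO energies are intentionally exposed as gauge-dependent; LAO is the
  production field treatment.
* Bundled basis data covers H and O only; other elements need a
  user-supplied Gaussian94 file, and spherical-harmonic (5d) conventions
  are not implemented, so published results in spherical d-function
  bases are not directly comparable.
* Uniform density grids cannot integrate sharp O-core densities
  accurately (the trace with the overlap is the exact conservation
  check; grids are for visualisation and difference densities, where
  core errors cancel).
* Geometries are fixed: no optimization, no field-dependent relaxation.
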