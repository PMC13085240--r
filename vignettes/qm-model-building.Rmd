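---
title: "Building multiscale QM/MM models: region selection, composite energies, and projection embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multiscale QM/MM models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmembed)
```

## The modelling problem

Enzyme reaction energetics computed with hybrid QM/MM schemes depend on
three coupled modelling choices: which atoms receive the quantum
treatment, which level of electronic-structure theory is applied, and how
the expensive high-level method is confined to the chemically active
subsystem. This package implements the computable core of a systematic
workflow for those choices: a deterministic, topology-aware QM-region
selection algorithm; composite-energy assembly with basis-set and
local-correlation extrapolations and reduced-size coupled-cluster
corrections; and a self-contained projection-based (Huzinaga) embedding
engine, together with seeded generators that make every component testable
without external data.

## QM-region selection

The selection pipeline has five deterministic stages.

**Radial seeding.** Heavy atoms within a radius $r$ of any declared core
atom are selected. Distances are measured in every requested
stationary-point frame and the union is taken, so atoms transiently close
to the reactive center anywhere along a preliminary reaction path are
included. Hydrogens never seed through the distance criterion; instead,
hydrogen completion runs afterwards (every hydrogen bonded to a selected
heavy atom joins, and vice versa), which keeps the radius semantics purely
heavy-atom.

**Topological extension.** The seed grows along covalent bonds of the MM
topology until every boundary bond matches a cut rule. The default rule
table lists the aliphatic C--C bonds of standard sidechains
(C$\alpha$--C$\beta$ and the successive sidechain carbon pairs). On top of
the table, three hard constraints apply at match time: both atoms must be
carbon, neither may be hydrogen, and the bond must not lie in a ring (ring
membership is computed from the bond graph as the non-bridge edges). Bond
orders are not modelled — MM topologies do not carry them — so "apolar
single bond" is encoded by the name-pair table plus these constraints.
Traversal is breadth-first with ties broken by ascending internal index,
which makes the provenance log byte-reproducible.

**Shared-link merging.** Two cut events with the same MM-side atom would
place two link hydrogens on top of one another. The shared atom (smallest
index first) is absorbed into the region and the extension re-runs; this
iterates to a fixed point, so the final cut events have pairwise distinct
MM atoms.

**Fragment pruning.** Connected components of the selection that do not
contain a core atom, consist solely of carbons plus their hydrogens, and
have at most two carbons are removed with their cut events. Pruning runs
*before* link-atom placement, so generated link hydrogens never count
toward a fragment — the alternative ordering would let a pruned ethyl
island retain a phantom link atom.

**Charge accounting and links.** Hydrogen link atoms are placed at a fixed
1.09 Å (a standard C--H bond length; configurable) along each cut bond.
Formal charges come from residue templates (carboxylates −1, ammonium and
guanidinium +1, nucleotide polyphosphates, metal ions), each with a single
designated charge-center atom: a partially selected charged group counts
only when its charge center is inside, and always warns. Templates are an
ordinary named list with per-residue overrides, because formal charge is a
bookkeeping convention, not a derivable quantity, and intermediates with
unusual protonation need user control.

Residue exclusion scans (`exclusion_variant()`) remove a moiety from a
finished region and re-finalize it; bonds into the excluded moiety are cut
regardless of the rule table, since the user has asserted the moiety must
leave. Shared-link merging will not re-absorb excluded atoms.

## Composite reaction energetics

Energies are stored in hartree and reported in kcal/mol
(1 hartree = 627.5094740631 kcal/mol). Reaction profiles are referenced to
the reactant state; the tracked quantities are the two barriers, their
difference (which discriminates the rate-determining step), and the
reaction energy.

Two two-point CBS models are implemented: the inverse-cubic form for
correlation energies and an exponential form (default decay constant
1.63) for the mean-field part. Both recover a planted asymptote exactly
when the input series follows the model, which is the basis of the
extrapolation tests.

The local-approximation-free (LAF) limit is estimated from a
Normal/Tight threshold pair as $E_T + c\,(E_T - E_N)$ with the residual
threshold error reported as the half-width $|c\,(E_T - E_N)|$. The
coefficient defaults to $c = 0.5$, matching the conventional
$\pm 0.5 (E_\mathrm{Tight} - E_\mathrm{Normal})$ uncertainty measure, and
is exposed as an argument because the extrapolant (as opposed to the
uncertainty) is a convention that different composite schemes set
differently. The composite reference
$E = E^{CBS}_{Normal} + E^{X}_{N\text{-}T} - E^{X}_{Normal}$ reduces to
the plain Normal CBS value when the two threshold sets give identical
energies.

The reduced-size coupled-cluster correction exploits the observation that
$\Delta\Delta E_{CC} = \Delta E_{CC} - \Delta E_{DFT}$, evaluated at one
and the same smaller QM size, converges faster with region size than the
relative energies themselves, so it can be transferred to a
larger-region DFT profile. `composite_assemble()` is the final sum
$\Delta G = \Delta E_{DFT_E} + \Delta\Delta E_{CC} - T\Delta S$ with the
entropic term supplied externally (0 for electronic-only profiles).

Mean absolute errors of profiles exclude the reference state from the
mean: it is identically zero in both profiles, and including it would
deflate every MAE by a constant factor without adding information.

Convergence reports take the largest available QM size as the asymptote
and return, per quantity, the smallest size from which the deviation
stays within tolerance *for that size and all larger ones* — a series
that dips inside the band and exits again is not converged at the dip.
Non-monotonic approach is flagged.

## The toy electronic-structure engine

The embedding methods operate on explicit model Hamiltonians: an SPD
overlap $S$, a symmetric one-electron matrix $h$, a two-electron tensor
with 8-fold symmetry, an atom assignment for each basis function, and an
even electron count. The energy functional is Hartree--Fock-like with a
tunable fraction $c_x$ of exact exchange,
$$E[D] = E_0 + \mathrm{Tr}(Dh) + \tfrac12 \mathrm{Tr}(D J[D])
       - \tfrac{c_x}{4} \mathrm{Tr}(D K[D]),$$
so the high-level/low-level pair ($c_x = 1.0$ vs $0.25$) mimics the
hybrid-versus-GGA accuracy gap that motivates embedding, without any DFT
machinery. Densities carry the occupation factor 2; everything is
closed-shell.

**SCF solver.** The solver uses optimal-damping iterations: each step
diagonalizes the Fock matrix of the current (possibly non-idempotent)
density, forms the aufbau candidate, and mixes along the segment with the
line-search-optimal weight. Because the energy functional is exactly
quadratic in the density, the optimal weight has a closed form,
$\lambda^* = -\mathrm{Tr}(\Delta F[D]) / \mathrm{Tr}(\Delta G[\Delta])$,
and every step is guaranteed non-increasing in energy. Convergence is
declared on the idempotent aufbau candidate against its own Fock matrix
(commutator norm $\max|FDS - SDF| \le 10^{-8}$), so the returned density
is idempotent and the returned occupied orbitals span it exactly — a
property the localization and embedding stages rely on. Plain Roothaan
iterations with DIIS and level shifting were tried first and abandoned:
on small-gap random fixtures they enter limit cycles, stall at residuals
around $10^{-2}$–$10^{-5}$, or converge to different stationary points
depending on the acceleration history, all of which break the exact
limit identities the embedding must satisfy. The iteration budget is
generous (6000) because near-degenerate fixtures approach the fixed point
slowly; iterations cost microseconds at this scale.

**Localization and active-MO selection.** Occupied orbitals are localized
by Jacobi sweeps maximizing the Pipek--Mezey objective (sum of squared
per-atom Mulliken populations); the occupied density is invariant by
construction. Active MOs are the localized orbitals with summed Mulliken
population $\ge 0.3$ on the active atoms — the conventional threshold for
this selection.

**Huzinaga-embedded SCF.** The environment density $D_B$ (frozen from the
non-active localized LL orbitals) enters the effective operator
$F_{HL}[D_A + D_B] - \tfrac12 (F D_B S + S D_B F)$. The projection makes
the frozen orbitals exact eigenvectors with reflected eigenvalues, so the
aufbau candidate is taken over eigenvectors with negligible environment
character, and the converged active density is $S$-orthogonal to the
environment to machine precision. The optimal-damping logic carries over,
with the line search shifted by the constant environment density. Two
exact limits are enforced by tests on 100 seeded Hamiltonians: with
HL = LL the embedding reproduces the full LL energy
($\le 10^{-8}$), and with every atom active it reproduces the full HL
energy. The second limit is implemented by delegation: an empty
environment makes the embedded problem literally the full HL problem, so
the same deterministic solver is invoked — solving it twice through two
different iteration paths can land on different near-degenerate SCF
solutions, which is a statement about SCF nonconvexity, not about the
embedding.

**Embedding energy.** The total energy
$E = E_{LL}[D] - E_{LL}[D_A] + E_{HL}[\tilde D_A]
   + \mathrm{Tr}\{(\tilde D_A - D_A) V_{emb}\}$
carries a first-order correction in the active-density difference. The
embedding potential is realized as $V_{emb} = F_{LL}[D] - F_{LL}[D_A]$,
the standard projection-embedding form of the derivative of the
LL-minus-HL energy difference with respect to the active density; the
matrix can be overridden by the caller, because the printed theory fixes
the derivative only symbolically and other realizations are defensible.
On random fixtures the corrected energy is, on average, closer to the
full-HL reference than the uncorrected three-term sum; this is asserted
statistically at fixed seeds.

**AO truncation.** The reduced HL problem keeps basis functions whose
Mulliken-type contribution to any active MO exceeds $\tau_{AO}$ (default
$10^{-4}$) plus all functions on active atoms. Two corrections make the
reduced problem faithful rather than merely smaller. First, the plainly
restricted environment density is no longer idempotent; it is purified to
the nearest idempotent density in the reduced metric, and a projected
environment with near-zero trace purifies to zero rather than to a
phantom occupied orbital. Second, environment electrons whose functions
were dropped still act on the active block through their mean-field
potential — Coulomb is long-range and does not decay with the
coupling length scale — so the residual potential
$G[D_B^{full}]\big|_{kept} - G_{red}[D_B^{red}]$ is folded into the
reduced one-electron term used by the embedded SCF, while the energy of
the converged active density is evaluated with the plain (unaugmented)
reduced Hamiltonian. Without this term, truncation errors on block-decay
fixtures were dominated by the missing environment field and did not
vanish with decreasing coupling; with it, relative-energy deviations at
$\tau_{AO} = 10^{-4}$ are below $10^{-3}$ toy units and go to zero
exactly at $\tau_{AO} = 0$.

**ONIOM comparator.** The subtractive combination
$E_{LL}(full) - E_{LL}(capped) + E_{HL}(capped)$ uses a capped active
subsystem: the Hamiltonian restricted to active-atom functions plus one
cap function per severed strong one-electron coupling, carrying a
diagonal attraction (default $-0.5$) and the severed function's couplings
to the active block — the toy analogue of a hydrogen link atom. The
electron count is twice the number of full-system localized MOs assigned
to the active atoms by majority population, the natural generalization of
assigning integer charges to an ONIOM subsystem. With HL = LL the
combination collapses to $E_{LL}(full)$ identically.

## What the generators emulate — and what they do not

`make_topology()` builds a peptide-like chain with sidechains drawn from
a template menu (neutral and charged), an Mg²⁺ ion surrounded by crystal
waters, and five stationary-point frames with small seeded displacements.
It reproduces the *combinatorial* features the selector must handle —
branched sidechains, charged groups, ring-free cut candidates, detached
fragments, multi-frame unions — with crude geometry; it does not attempt
realistic protein conformations, hydrogen-bond networks, or force-field
parameters. Selector tests passing on these fixtures demonstrate
algorithmic correctness (agreement with an independently coded
brute-force pipeline on hundreds of randomized cases), not that a given
radius yields a converged QM region for any real enzyme.

`make_hamiltonian()` places atoms on a jittered line with
distance-decaying overlap and one-electron couplings (made strictly
diagonally dominant, hence SPD) and a separable, distance-damped
two-electron tensor built from a positive-semidefinite pair-space kernel.
Small coupling length scales give near-block-diagonal fragments, the
regime the truncation tests exploit. Two electrons per atom keeps each
fragment closed-shell. These models exercise every algebraic property of
the embedding but say nothing about basis-set physics of real molecules.

`make_energy_series()` plants a geometric approach to a declared
asymptotic profile such that the first barrier's deviation from the
largest size crosses the 1 kcal/mol band exactly at the declared
convergence size; the other states carry smaller, same-signed deviations
so no tracked quantity converges later than the planted one. The default
grid (101–500 atoms) and the default crossing at 431 atoms mirror the
QM sizes at which radial selections of enzyme active sites typically
converge. Threshold rows at two basis cardinals follow an exact
inverse-cubic basis model with a planted Tight−Normal gap of
0.28 kcal/mol on the first barrier, so the CBS and LAF pipelines recover
known answers.

All generators are pure functions of their recipes: they seed a local RNG
and restore the caller's stream, and repeated calls are byte-identical.

## Numerical choices

* Internal unit hartree, reports in kcal/mol, conversion constant fixed.
* SCF and embedded SCF converge the commutator to $10^{-8}$; electron
  count and environment orthogonality are checked to the same tolerance.
* Deterministic tie-breaks everywhere: BFS by ascending internal index,
  shared-MM absorption smallest-first, fixed SCF initialization from the
  core Hamiltonian.
* Degenerate inputs: empty PDB files parse to empty systems; a selection
  that would prune its own core errors; coincident atoms at a cut bond
  error at link placement; an energy table with an unknown unit errors
  rather than assuming.
* Problem sizes in the test suite: topologies of 80–200 atoms, model
  Hamiltonians of 8–12 basis functions, 100-case oracle and identity
  sweeps, chosen so the full suite completes in a few minutes on one CPU.

## Known limitations

* Element inference from atom names is heuristic; PDB element columns are
  preferred, and `"CA"` is always taken as an alpha-carbon, never calcium.
* The cut-rule table covers standard amino-acid sidechains; exotic
  residues need user-supplied rules (the table is data, not code).
* The toy functional has no correlation beyond exchange scaling; the
  HL/LL gap is a proxy, and embedding accuracy statements transfer to
  real systems only structurally.
* Density-fitting (auxiliary-basis) truncation is not modelled — the toy
  Hamiltonians have no density-fitting layer — only AO truncation is.
* The ONIOM cap construction is a one-function placeholder per severed
  coupling; it reproduces the exact subtractive identities but is not a
  parameterized link-atom model.
* Gradients, geometry optimization, and free-energy sampling are out of
  scope; the entropic term of the composite is an external input.
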