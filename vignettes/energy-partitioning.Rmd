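---
title: "Fragment partitioning of AMBER molecular mechanics energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment partitioning of AMBER molecular mechanics energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amberDecomp)
```

## The problem

In large biomolecular calculations — ligand–protein scoring, or hybrid
QM/MM studies of enzyme mechanisms — the total molecular mechanics (MM)
energy changes between conformations, but the total alone does not say
*which* residues or molecules drive the change. amberDecomp evaluates the
single-point AMBER energy of a system and splits it into user-defined
fragments plus inter-fragment interaction terms, such that the arithmetic
sum of all parts reconstructs the unpartitioned total exactly. Comparing
the per-fragment parts between two conformations (reactant vs product,
bound vs unbound) localizes the energy change — for instance to decide
which residues deserve promotion into a QM region.

## The energy model

The Hamiltonian is the standard AMBER form,

$$
E = \sum_{\text{bonds}} k_b (l - l_0)^2
  + \sum_{\text{angles}} k_a (\theta - \theta_0)^2
  + \sum_{\text{dihedrals}} \sum_{i=1}^{4} \frac{k_{d,i}\,
      \bigl(1 + \cos(i\phi - A_i)\bigr)}{N}
  + \sum_{\text{impropers}} k_i \bigl(1 - \cos(P(\sigma - A))\bigr)
  + \sum_{i<j} \Bigl(\frac{A_{ij}}{r_{ij}^{12}} - \frac{B_{ij}}{r_{ij}^6}\Bigr)
      S_{\mathrm{LJ}}
  + \sum_{i<j} \frac{1}{4\pi\epsilon_0}\,\frac{q_i q_j}{r_{ij}}\,
      S_{\mathrm{Coulomb}}
$$

with no nonbonded cutoff and plain Euclidean distances (no periodic
boundary conditions). All energies are kcal/mol, lengths Angstrom,
charges elementary-charge units.

* **Bonds/angles** are harmonic; equilibrium angles are stored in degrees
  (as parameter files print them) and converted to radians exactly once,
  at evaluation.
* **Proper torsions** are a four-slot cosine series: slot $i$ carries the
  magnitude $k_{d,i}$ (kcal/mol) and phase offset $A_i$ (degrees) of
  periodicity $i$; the path count $N$ divides the series. The dihedral
  angle is the angle between the $ijk$ and $jkl$ plane normals (cross
  products), signed by the orientation about the $j\!\to\!k$ axis. The
  plane-normal construction alone gives an unsigned angle; the sign
  convention is strictly more general, and with the phase offsets of 0°
  or 180° found in AMBER parameter tables the cosine is even, so the
  choice does not change any energy (the test suite checks reversal
  invariance explicitly).
* **Improper (out-of-plane) torsions** penalize displacement of an atom
  from the plane of three atoms bonded to a common centre,
  $k_i(1-\cos(P(\sigma - A)))$, with the central atom third in the
  four-atom list. Every atom bonded to exactly three others is a
  candidate; candidates with no matching parameters are skipped with a
  warning, never an error — an unparameterized improper is routine in
  AMBER topologies, and the warning simply flags the centre for
  inspection.
* **Nonbonded terms** use the Lorentz–Berthelot combination
  ($\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}$,
  $D_{ij} = R_i + R_j$, $A_{ij} = \epsilon_{ij}D_{ij}^{12}$,
  $B_{ij} = 2\epsilon_{ij}D_{ij}^{6}$) and the Coulomb prefactor
  $1/(4\pi\epsilon_0) = 332.063712827427$ kcal·mol⁻¹·Å·e⁻².
* **Exclusions and 1-4 scaling**: pairs one or two bonds apart are
  excluded entirely (their physics lives in the bond/angle terms); pairs
  exactly three bonds apart are scaled by $S_{\mathrm{LJ}} = 0.5$ and
  $S_{\mathrm{Coulomb}} = 1/1.2$ (computed as `1/1.2` in working
  precision); everything else is full strength. Pair separation is the
  *minimal* bond-path length (breadth-first search truncated at depth 3),
  so ring closures take the shorter path — opposite atoms of a 4-cycle
  are 1-3, not 1-5 — consistent with standard AMBER exclusion-list
  construction.

## Partitioning

A fragment scheme is a total mapping from atom index (0-based, matching
AMBER tooling) to a fragment label. User selections must be disjoint;
atoms in no selection fall into the reserved remainder fragment `"X"`,
and empty fragments are dropped. Every energy term — each bonded
instance and each nonbonded pair — is evaluated exactly once and routed
into the bucket of the distinct fragment labels its atoms span: one
label is a fragment self-energy $E_{\mathrm{frag}\,i}$; two, three or
four labels are the pair, triple and quadruple interaction terms
$E_{\mathrm{int}\,i\text{-}j}$, $E_{\mathrm{int}\,i\text{-}j\text{-}k}$,
$E_{\mathrm{int}\,i\text{-}j\text{-}k\text{-}l}$. Bonds and nonbonded
pairs can span at most two fragments, angles three, torsions and
impropers four, so four labels is a hard ceiling. Bucket keys are
*sorted* label sets ($E_{\mathrm{int}\,1\text{-}2}$ and
$E_{\mathrm{int}\,2\text{-}1}$ are one bucket), and scaled 1-4 pairs are
routed by their two end atoms only.

Because `partitionedEnergy()` and `totalEnergy()` consume the identical
per-term energies and only group them differently, the reconstruction

$$E_{\mathrm{system}} = \sum_i E_{\mathrm{frag}\,i}
  + \sum_{i\ne j} E_{\mathrm{int}\,i\text{-}j}
  + \sum_{i\ne j\ne k} E_{\mathrm{int}\,i\text{-}j\text{-}k}
  + \sum_{i\ne j\ne k\ne l} E_{\mathrm{int}\,i\text{-}j\text{-}k\text{-}l}$$

holds by construction up to floating-point accumulation order; the test
suite bounds the residual at $10^{-9}$ kcal/mol on systems up to 200
atoms and 17 fragments.

A partitioned single structure has little physical meaning on its own;
the value appears when two related structures are compared.
`deltaReport()` subtracts two reports bucket-wise (two conformations,
reactant vs product), which is the per-residue $\Delta E$ workflow.

## Parameters and file formats

Parameters live in a `ParameterSet`, readable from two sources:

* a **Gaussian-style MM block** (`parseGaussianParams()`): records
  `VDW`, `HrmStr1`, `HrmBnd1`, `AmbTrs`, `ImpTrs`, whitespace-delimited,
  units as printed (Å, kcal/mol, degrees). Only explicit atom types are
  supported — no wildcards; a missing bond/angle/torsion parameter at
  evaluation is an error naming the type sequence, a missing improper a
  warning. `writeGaussianParams()` is its exact inverse (deterministic
  ordering; 4-decimal fixed point where exact, full precision
  otherwise).
* an **AMBER PRMTOP/PARM7 topology** (`readPrmtopTopology()`,
  `paramsFromPrmtop()`): per-type $R$ and $\epsilon$ are recovered by
  inverting the diagonal Lennard-Jones coefficients
  ($\epsilon = B^2/4A$, $D = (2A/B)^{1/6}$); charges are divided by the
  file's 18.2223 premultiplier so the package's Coulomb prefactor
  applies to elementary charges; bonded tables are keyed by atom-type
  labels, and torsion records of one quadruple merge their periodicities
  into the four slots. Off-diagonal LJ coefficients edited away from
  Lorentz–Berthelot (NBFIX-style) are not representable per-type; pair
  coefficients are always recombined from per-type values, and such
  topologies will diverge. Per-dihedral SCEE/SCNB scale sections, if
  present, are ignored in favour of the global 1/1.2 and 0.5 factors.
  Duplicate records for one key (same periodicity) keep the first
  occurrence with a warning — deterministic behaviour beats silent
  summation.

Coordinates come from AMBER ASCII inpcrd/restart files (parsed here) or
PDB (via bio3d). A restart is treated as a stream of 3N-number frames
and `frame` selects one (0-based); velocities appended to a restart
would surface as a spurious extra frame, so the default frame 0 is
always the coordinate block.

## Deterministic choices on open corners

* **Improper ordering.** The central atom is fixed third, but nothing
  fixes the order of the other three. Lookup canonicalizes the
  peripheral types (sorted), and enumeration emits the neighbours sorted
  by atom index — the first permutation of the deterministic sequence —
  so a given topology always produces the same terms and energies.
* **Accumulation order** is fixed (ascending index), making results
  bit-reproducible on one platform; across platforms the contract is
  agreement within $10^{-9}$ kcal/mol. Evaluation is vectorized,
  single-threaded R; the worker count in the run configuration is
  recorded in the report metadata for provenance only.
* **Near-collinear angles**: the normalized dot product is clamped to
  $[-1, 1]$ before `acos`, so floating-point overshoot cannot raise a
  domain error. Truly collinear i–j–k in a dihedral (undefined plane
  normal) is an error naming the atoms.
* **Torsions through rings**: all simple 4-paths are enumerated,
  including ring closures, as standard AMBER tools do.

## The synthetic-system generator

`makeFixture()` builds small, fully parameterized systems so the whole
pipeline is testable without external data: helical chains (the
canonical 1-2/1-3/1-4 ladder), stars (3-coordinated centres exercising
impropers), rings (shortest-path exclusions), two disconnected molecules
(purely nonbonded inter-fragment interactions), and a `random` recipe —
several chain molecules placed in a 20 Å box with a 0.8 Å minimum pair
separation (bounded retries), charges uniform in $[-1, 1]$ e, and
seeded random parameter tables. Regular recipes carry the reference
record values (e.g. $k_b = 340$, $l_0 = 1.09$) on every type sequence
that occurs, and sit near their bond equilibrium so energies stay in a
realistic range. Generated coordinates are rounded to $10^{-7}$ Å so the
fixed-width coordinate format round-trips them losslessly.

What the generator does *not* emulate: real force-field chemistry
(types, charges and parameters are synthetic), solvent, periodic boxes,
or system sizes beyond a few hundred atoms. Passing tests therefore
demonstrate the correctness of the energy algebra, the term enumeration
and the partition bookkeeping — not agreement with any production
force-field distribution.

`bruteForceEnergy()` is an independently coded oracle: separate term
enumeration, angles from the law of cosines, dihedrals from the atan2
formulation, pair classification from igraph shortest paths, naive
accumulation. The engine is validated against it per energy class on
every recipe and on batches of random systems ($\le 10^{-9}$ kcal/mol).
The test problem sizes (up to 200 atoms, 20 random systems, 17
fragments) were chosen as representative desk-scale workloads for an
interpreted double loop.

## Worked example

```{r example}
sys <- makeFixture("two-molecule", 10, seed = 3)
scheme <- assignFragments(list("0" = 0:4, "1" = 5:9), nAtoms(sys))
report <- partitionedEnergy(sys, scheme)
report
writeLines(writeReport(report, "text"))
```

The `Fragment 0 + Fragment 1` lines under VDW and Coulomb are the full
inter-molecular interaction energy; all bonded terms are fragment
self-energies because no covalent bond crosses the boundary.

## Known limitations

* No forces or gradients, minimization, Ewald/PME, cutoffs, neighbour
  lists, implicit solvent, or periodic boundary conditions.
* Wildcard atom types and NBFIX-style off-diagonal LJ edits are
  unsupported (see above).
* Improper candidates are restricted to exactly-three-coordinated
  centres; atoms with four or more neighbours never generate impropers.
* Terms involving more than four atoms do not exist in this Hamiltonian,
  so interaction buckets stop at quadruples by construction.
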