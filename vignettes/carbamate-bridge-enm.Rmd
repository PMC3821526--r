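---
title: "Elastic network models of carbamate-bridged hemichannel gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic network models of carbamate-bridged hemichannel gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbanm)
```

## The model

`carbanm` asks a narrow mechanical question: if CO₂ carbamylates a lysine
at each subunit interface of a hexameric hemichannel and the carbamate
salt-bridges to an arginine on the neighbouring subunit, does that set of
six local constraints change which collective motions dominate — in
particular, does it suppress pore closure?

The machinery is the anisotropic elastic network model (ANM). A protein
is reduced to its Cα atoms; every pair within a cutoff radius is joined
by a Hookean spring whose rest length is the observed separation, so the
input structure is the energy minimum by construction. For a spring
between nodes $i,j$ with unit bond vector $\hat r$, the Hessian carries
the $3\times3$ blocks $-k\,\hat r\hat r^\mathsf{T}$ off-diagonal, with
the diagonal accumulating the positive counterparts. Eigenpairs
$(\lambda_m, v_m)$ of the $3N\times3N$ Hessian are the normal modes;
with unit masses, $\sqrt{\lambda_m}$ is proportional to the mode
frequency and $1/\lambda_m$ to its thermal mean-square amplitude. A
connected three-dimensional network has exactly six zero eigenvalues
(rigid translations and rotations); these are flagged and excluded, and
mode numbering is 1-based over the remainder.

CO₂ binding is represented without any new atoms: one extra spring per
adjacent-chain interface between the donor lysine and the acceptor
residue (R104-type arginine, or lysine — the conservative K104 variant).
Six springs for a hexamer. Everything else — coordinates, cutoff,
constants — is held fixed, so the unbound and bound states share one
coordinate space and their eigenvector bases can be compared directly
through absolute dot products (absolute, because eigenvector signs are
arbitrary; the package nevertheless fixes signs deterministically so
files are byte-reproducible).

### What is measured

* **Mode fraction.** The contribution of mode $m$ to the total motion is
  $f_m = \lambda_m^{-1} / \sum_k \lambda_k^{-1}$ over non-rigid modes.
  The source analysis this package reimplements reports such fractions
  without stating the weighting; inverse-eigenvalue (thermal amplitude)
  weighting is the standard ENM convention and is the default here, with
  $1/\sqrt{\lambda}$ exposed as `weighting = "inverse_frequency"` for
  sensitivity analysis.
* **Overlap and reordering.** `overlap_matrix()` computes
  $|v_a^{\text{unbound}} \cdot v_b^{\text{bound}}|$; each unbound mode's
  best match is the per-row argmax (ties to the lower index). This is
  deliberately not forced one-to-one — "mode 1 moves to mode 9" is a
  per-mode statement — but a greedy one-to-one assignment is available
  behind `one_to_one = TRUE`.
* **Pore occlusion.** `pore_profile()` displaces the structure along a
  unit-normalised mode by a chosen amplitude, slices it along the pore
  axis (2 Å slices by default, commensurate with Cα spacing) and records
  the minimum radial clearance per slice. The pore axis defaults to the
  principal axis of the Cα cloud whose moment is most separated from the
  other two — for a ring-like oligomer that is the symmetry axis; for
  synthetic systems it is the z-axis exactly. This is a radial-distance
  metric, not a probe-based (HOLE-style) radius: it tracks relative
  occlusion along a mode, not absolute conductance geometry.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cutoff` | 8 | Å | contact radius; inclusive comparison (`<=`), fixed so exact spring-count tests are well defined |
| `k` | 1 | kcal mol⁻¹ Å⁻² | uniform spring constant of the source parameterisation |
| `bridge_k` | 1 | kcal mol⁻¹ Å⁻² | the source does not distinguish bridge stiffness; the simplest reading is "same constant", configurable |
| `rigid_tolerance` | 1e-8 | relative | eigenvalue below `1e-8 × max(λ)` counts as rigid; scale-free across system sizes; more than six such modes raises a disconnected-network error rather than silently analysing a floppy system |
| masses | unit | — | no mass-weighting anywhere in the model |

Bridges are stored as their own `tag = "bridge"` rows even when a contact
spring already joins the same pair; the Hessian sums per-spring
contributions, so this is numerically identical to incrementing that
pair's stiffness while keeping "six additional springs" countable and
auditable (the equivalence is asserted by a test).

## The synthetic hemichannel: what it emulates, and what it does not

Real structures cannot be assumed available at test time, so the
generator `make_cn_oligomer()` produces a deterministic C_n-symmetric toy
whose *mechanics* — not anatomy — mirror a hemichannel:

* Each subunit has a **wall section** (an out-and-back double strand at
  the outer radius, full axial height) whose ends nearly touch the
  neighbouring subunits. Interfaces are therefore held by clusters of
  springs with tangential *and* diagonal directions. This matters: a
  single-point interface leaves each subunit a free pivot and produces
  spurious zero-frequency mechanisms.
* A **funnel leg** descends from the wall to a pore-lining tip. The leg
  is coiled like an α-helix (~3.6 residues per turn) so that the 8 Å
  cutoff captures $i\pm3$, $i\pm4$ contacts; a near-straight chain would
  have free-dihedral mechanisms, for exactly the reason real ANMs rely on
  secondary structure to be rigid.
* **Donor/acceptor arms** flank each tip, the donor lysine of chain $i$
  pointing at the acceptor arginine of chain $i+1$. The tips of adjacent
  subunits are otherwise out of contact range, so the bridge spring is
  the only inter-chain constraint in the pore region.

The donor→acceptor Cα distance defaults to 9.5 Å — just outside the
cutoff. This is a deliberate reading of the real geometry: the published
6.5 Å gap is between *side-chain* ends (Lys Nζ to the Arg guanidinium),
while the corresponding Cα pair sits beyond the 8 Å cutoff; it is
precisely because the pair is not already spring-connected that the
carbamate bridge is a *new* constraint. A toy with a 6.5 Å Cα gap
already contains the bridge as a contact spring in the unbound state, and
(as verified numerically) no reordering can then occur. The 6.5 Å value
lives where the chemistry puts it: `decorate_side_chains()` plants Nζ and
guanidinium pseudo-atoms at an exact side-chain distance (default 6.5 Å)
for the bridge-scan module.

On this stated world the mechanism reproduces qualitatively: the closing
mode (identified by `closing_mode_index()` as the mode with maximal
overlap with a concerted radial-inward pattern on the pore-lining atoms)
is unbound mode 4 carrying ~6% of the motion; with the six bridges it
best-matches bound mode 18 at ~0.8%. A green test here establishes that
the *implementation* produces bridge-selective demotion of pore closure
on a system built to have that property. It does not establish anything
about connexin 26 itself: the toy has no realistic sequence topology, its
closing mode is not mode 1 (softer tip-tilt pairs sit below it), and the
demotion magnitudes are geometry-dependent. Quantitative statements
(~40% unbound mode-1 fraction, reordering to mode 9 at ~2%) belong to
the 2ZW3 structure and are tested only when that file is present; in
offline environments that acceptance test fails with an explanatory
message rather than being skipped.

Noise: `perturb()` adds independent per-coordinate Gaussian displacement
(so per-coordinate $|\Delta|$ is half-normal — the property the tests
check) under a seed that never touches the caller's RNG state. The
noiseless generator is exactly symmetric; rotation by $2\pi/n$ maps chain
$i$ onto chain $i+1$ to machine precision, which forces the doubly
degenerate eigenvalue pairs the tests assert.

## Numerical choices and degenerate inputs

* Eigendecomposition is dense symmetric (`eigen(symmetric = TRUE)`);
  values are returned ascending. Degenerate pairs are kept as returned —
  only overlaps, which are basis-quantities *within* the pair, should be
  interpreted cautiously there.
* Eigenvector sign: the largest-magnitude component is made positive
  (first index wins ties), so repeated runs and exports are identical.
* Cutoff comparison is inclusive; coincident atoms (zero rest length) are
  an error, not a silent infinite-stiffness spring.
* PDB reading keeps the first-listed altloc conformer, excludes HETATM
  records (CO₂ enters as springs, never as atoms), uses model 1 by
  default, and treats (residue number, insertion code) as the residue
  key. Residues lacking a Cα are skipped and reported, not interpolated.
* Side-chain distances use Lys Nζ versus Arg {NE, CZ, NH1, NH2}, minimum
  over pairs, with the realising atom pair recorded for audit. Residues
  with unresolved side-chain atoms are skipped with a warning — never
  approximated by Cβ — because silent substitution would corrupt a
  distance screen whose whole point is a 6.5 Å threshold.
* Sequence edits are 1-based and guarded: a point mutation label like
  `K125R` refuses to apply if position 125 is not lysine, which catches
  off-by-one numbering between sequence and structure conventions.

## Known limitations

* No mmCIF input, no crystallographic symmetry expansion (the deposited
  hexamer is assumed biological), no Gaussian (isotropic) network
  variant, no all-atom force field or dynamics.
* The pore metric is geometric; it does not model solvent or probe radii.
* The mode-fraction weighting is a convention, not a derivation; both
  available weightings give "low frequency dominates", but absolute
  percentages shift between them, which is why the weighting is a
  reported, configurable parameter.
* The one-to-one assignment variant is greedy, not an optimal
  assignment-problem solution; for the near-diagonal overlap maps it is
  used on, the two agree.
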