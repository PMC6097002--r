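---
title: "Recognizing beta-sheet topology from backbone-grain contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing beta-sheet topology from backbone-grain contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandscan)
```

## The problem

Self-assembling peptides aggregate into molten oligomers inside which
beta-sheet order nucleates and evolves. In coarse-grained molecular dynamics
(one backbone bead per residue, as in MARTINI) hydrogen bonds are not
explicitly modeled, so beta-structure cannot be read off the force field:
it must be recognized geometrically, from the spatial arrangement of
backbone beads. strandscan implements that recognition for both static
structures (PDB) and trajectories (GRO frames), reporting which strand
pairs are aligned, in what registry, and which strands form sheets.

The system is treated as a 2D lattice: one axis runs along each peptide
backbone (covalent direction), the other across strands (hydrogen-bond
direction). The analysis needs only two integers from the user: the number
of strands `S` and the strand length `SL` (backbone grains per strand) into
which the grain sequence is divided.

## The recognition pipeline

**Beta-contacts.** Two backbone grains on *different* strands at distance
$r_{ij}$ form a beta-contact when

$$ \beta\text{-contact}_{ij} \;=\; \mathbb{1}\!\left[\, r_\min \le r_{ij} \le r_\max \,\right],
\qquad [r_\min, r_\max] = [4.7, 5.3]\ \text{Å}, $$

the typical inter-strand distance in cross-beta structures. The closed
interval is used at both ends; both bounds are configurable. All contacts
form the binary BB matrix over the $S \cdot SL$ grains; with a periodic box,
distances use the orthorhombic minimum-image convention.

**Registry matching.** For each strand pair $(p, q)$ the $SL \times SL$
block of the BB matrix is compared against a library of *shift matrices*:
binary templates enumerating every mutual alignment, indexed by orientation
and a signed shift $k$ (with 1-based indices):

* parallel, shift $k$: $T_{ij} = \delta_{j,\,i+k}$ — $k = 0$ is the
  in-register identity pattern;
* antiparallel, shift $k$: $T_{ij} = \delta_{j,\,(SL+1-i)+k}$ — $k = 0$ is
  the exact reversal (anti-diagonal).

A template with shift $k$ has $SL - |k|$ entries; the library spans
$|k| \le k_\max$ (default $SL - 3$, below which fewer than three positions
overlap). Similarity is scored by the normalized cross-correlation, which
for binary matrices reduces to

$$ \mathrm{NCC}(B, T) = \frac{\sum_{ij} B_{ij} T_{ij}}
   {\sqrt{\left(\sum_{ij} B_{ij}\right)\left(\sum_{ij} T_{ij}\right)}} \in [0, 1], $$

1 exactly when the supports coincide, undefined (no match) for an empty
block. The best-scoring alignment becomes the pair's entry in the
strand-by-strand **P matrix**, provided the winning template explains at
least `min_contacts = 3` contacts — the minimum number of hydrogen-bond-like
contacts for a credible pairing. Score ties are broken deterministically:
smaller $|k|$, then parallel before antiparallel, then positive before
negative shift. The histogram of matched $(orientation, k)$ over all pairs
is the **shift profile**.

**Sheet reconstruction.** A pair of aligned strands is only a *potential*
beta-interaction; a sheet requires continuity across at least three
strands. For every triplet $(a, b, c)$ with central strand $b$ and both
pairs present in the P matrix, the two BB areas are reduced along $b$ to
count vectors $v_r$ (contacts with $a$ per residue of $b$) and $v_c$
(contacts with $c$). Their elementwise product $v_p = v_r \odot v_c$ marks
residues of $b$ contacting both neighbours; the triplet qualifies when
$\sum v_r \ge 3$, $\sum v_c \ge 3$, and the inclusive index span between
the first and last non-zero of $v_p$ — a span, not a count, so a single
interior gap does not disqualify — is at least 3. Qualifying triplets
sharing a strand are merged into sheets, and

$$ \%Ms = \mathrm{round}\!\left( 100 \cdot \frac{\#\text{strands in sheets}}{S} \right) $$

with half-up rounding (chosen so 27/35 prints 77 and 31/34 prints 91).
Strands appearing only in 2-strand pairings never count toward %Ms.

**Aggregates.** Peptide centers of mass (unweighted mean over backbone
grains) are thresholded at 11 Å (1.1 nm, the typical equatorial distance of
cross-beta structures in XRD); connected components of the neighbour graph
are the oligomers, isolated peptides are singletons. Each oligomer is
scored by its radius of gyration and by the nematic order parameter: with
$\hat u_m$ the unit vector from the first to the last grain of peptide $m$,

$$ Q = \frac{1}{N}\sum_m \left( \tfrac{3}{2} \hat u_m \hat u_m^{\top} - \tfrac12 I \right),
\qquad P_2 = \lambda_{\max}(Q), $$

1 for perfect (head–tail symmetric) alignment, near 0 for an isotropic set.
The eigen-tensor definition is the standard choice in peptide-assembly MD;
the source method names the parameter without a formula.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `r_min`, `r_max` | 4.7, 5.3 | Å | beta-contact window (closed) |
| `min_contacts` | 3 | contacts | pair match and triplet qualification threshold |
| `k_max` | `SL - 3` | residues | largest enumerated shift |
| `cutoff` | 11.0 | Å | oligomer COM threshold |
| `S`, `SL` | — | — | strand division; for trajectories, peptides × grains per peptide |

Distances below `r_min` score 0: the window is read literally, and
coarse-grained excluded volume makes sub-4.7 Å backbone-backbone distances
rare. Whether a real system's contacts should extend to 0 Å is exposed via
`contact_range()` rather than decided here.

## The synthetic-fixture generators

`make_ideal_sheet()` builds sheets with *known* registry: strands along x
with per-residue rise 3.4 Å, stacked at 4.8 Å — inside the contact window —
along a stacking direction that rotates by `twist` degrees per strand about
the sheet's long axis. This curved-sheet twist model keeps every registered
inter-strand distance exactly at the design spacing, so designed contacts
are never destroyed by the distortion itself; a model twisting strands
radially about a common axis would push outer-strand distances out of the
window already at 5°/strand for 12 strands, which is why it is not used.
Orientation and shift are prescribed per adjacent pair and realized by
flipping strand direction and sliding offsets, inverting the same template
convention the matcher uses — the generator and the matcher are coupled
only through the geometry, not through shared code.

Jitter is per-coordinate Gaussian noise truncated at ±`jitter` Å. Because
the default 4.8 Å spacing sits asymmetrically in the 4.7–5.3 Å window, any
jitter above ~0.05 Å can push individual designed contacts out of the
window; recovery of the designed registry at the tested 0.2 Å jitter is
therefore statistical rather than guaranteed per contact — with ≥ 10
designed contacts per pair the probability that fewer than 3 survive, or
that stray off-template contacts outscore the designed diagonal, is
negligible, and the test suite verifies recovery end-to-end at fixed seeds.

`make_random_gas()` places rods with uniform random positions/orientations
under a minimum COM separation (rejection sampling, bounded retries);
`make_clustered_aggregate()` chains peptide COMs at a prescribed
intra-cluster spacing with clusters far apart, so a cutoff between the two
spacings must recover the designed partition exactly.

What the fixtures deliberately do **not** emulate: real backbone geometry
(dihedrals, side chains), sequence-dependent interaction strength,
thermal disorder beyond isotropic jitter, and the dense molten-globule
environment of real assemblies where near-window distances abound. Passing
the fixture tests therefore demonstrates correctness of the recognition
logic, not field accuracy on any particular force field or sequence.

## Numerical and design choices

* **Indexing.** R-native 1-based indexing throughout; the template formulas
  above are the 1-based re-derivation of the usual Kronecker-delta
  notation, fixed so that antiparallel $k=0$ is the exact reversal map.
* **NCC ties.** Compared with a 1e-12 tolerance before tie-breaking, so
  equal rational scores computed through different floating-point routes
  collapse to the same candidate set.
* **Triplet merging.** Sheets merge triplets sharing *one strand* (not a
  full pair). In aggregates, sheets extend through non-sequential strands,
  and single-strand sharing is the weakest link that still gives a
  connected lattice.
* **"Consecutively adjacent"** is adjacency in the P matrix, not sequence
  adjacency: any ordering $(a, b, c)$ with $b$ central is enumerated.
* **Degenerate inputs.** Two-strand systems yield %Ms = 0 by construction;
  an all-zero contact block is unmatched rather than scored 0; a zero-length
  peptide axis is an error naming the peptide (P2 undefined).
* **Trajectory formats.** GRO topologies and multi-frame GRO trajectories
  are supported (plus single-structure PDB); compressed binary trajectory
  formats (XTC/TRR) are not read — convert with `gmx trjconv -o traj.gro`.
* **Strand homogeneity.** One analysis run assumes a single `SL` for all
  strands; systems with unequal strand lengths must be analyzed per
  homogeneous subset.
* **Chain breaks.** PDB chain ends and residue-numbering gaps are chain
  breaks; the strand partition restarts after each break and refuses to
  form strands across one, so unresolved residues never fake continuity.

## Problem sizes

The bundled tests and the acceptance script run entirely on generated
fixtures: sheets up to 12 strands × 32 residues, gases up to 200 peptides,
1,000-case randomized cross-checks of the matcher and the component finder
against brute-force oracles, and 100-seed Monte-Carlo bounds on the
isotropic P2 limit — sizes chosen to exercise every code path with exact,
enumerable ground truth. Published reference structures (PDB entries 2mxu,
2fkg, 1d2s, 3bep) are supported by `analyze_structure()` with their
published strand divisions; the entries themselves must be downloaded from
the RCSB into `inst/extdata/pdb/` (they are not redistributed with the
package), after which the validation test in `test-acceptance.R` runs them
automatically.

## Known limitations

* Whole-submatrix matching: partial-strand alignments (a template matching
  a sub-window of a pair block) are not searched; strongly bent strands
  with two distinct registries against the same partner report only the
  dominant one.
* Shifts beyond $SL - 3$ are not enumerated, since fewer than three
  positions would overlap; registry peaks at extreme shifts reported for
  very short peptides elsewhere are thus outside the search space by
  design.
* Oligomer identity is per frame; components are not tracked across frames.
* Orthorhombic boxes only.
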