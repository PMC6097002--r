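# strandscan

Beta-sheet topology recognition for coarse-grained peptide and protein
systems.

## What it does, and for whom

In coarse-grained molecular dynamics of self-assembling peptides (one
backbone bead per residue, MARTINI-style), hydrogen bonds are not explicit,
so beta-structure formation cannot be read from the force field — it has to
be recognized geometrically. strandscan does that recognition for anyone
studying peptide self-assembly, amyloid-like aggregation, or beta-rich
protein architecture from bead-level coordinates: it reports which strand
pairs are aligned, in what registry (parallel/antiparallel, residue shift),
which strands form sheets, and how ordered the resulting aggregates are.

The pipeline, for a system divided into `S` strands of `SL` backbone grains:

1. **Beta-contacts** — grains *i*, *j* on different strands are in contact
   when `4.7 Å ≤ r_ij ≤ 5.3 Å` (the typical inter-strand distance in
   cross-beta structures; closed interval, configurable, minimum-image with
   a periodic box). Contacts form the binary `BB` matrix.
2. **Registry matching** — each `SL × SL` strand-pair block of `BB` is
   matched against a library of shift templates
   (`T_ij = δ_{j,i+k}` parallel; `T_ij = δ_{j,(SL+1−i)+k}` antiparallel) by
   normalized cross-correlation
   `NCC(B,T) = ΣBT / sqrt(ΣB·ΣT)`. The argmax alignment, if it explains
   ≥ 3 contacts, becomes the pair's entry in the strand-level `P` matrix;
   the histogram over `(orientation, k)` is the *shift profile*.
3. **Sheet reconstruction** — a triplet of strands `(a, b, c)` qualifies
   when the central strand contacts each neighbour ≥ 3 times *on a shared
   portion* (inclusive span of the elementwise product of the two
   per-residue contact-count vectors ≥ 3). Qualifying triplets sharing a
   strand merge into sheets, and `%Ms = round(100 · strands-in-sheets / S)`.
4. **Aggregates** — oligomers are connected components of peptide
   centers-of-mass thresholded at 11 Å (1.1 nm); each is scored by its
   radius of gyration and the nematic order parameter `P2` (largest
   eigenvalue of the orientational order tensor of end-to-end axes).

Inputs: PDB structures (backbone-COM or CA-only mapping to one grain per
residue) and GRO coordinate/trajectory files with `BB` beads. Synthetic
generators (`make_ideal_sheet`, `make_random_gas`,
`make_clustered_aggregate`) produce fixtures with exact ground truth.

See `vignettes/strand-registry.Rmd` for the full model description and the
design rationale.

## Worked example

```r
library(strandscan)

fx  <- make_ideal_sheet(12, 32)               # 12 strands x 32 residues, in-register
res <- analyze_structure(fx$frame, S = 12, SL = 32)

print(res$p_matrix)
#> p_matrix: 12 strands, 11 beta-interactions
#>     p  q orientation k score contacts
#> 1   1  2    parallel 0     1       32
#> 2   2  3    parallel 0     1       32
#> ...
print(res$sheets)
#> sheet_report: 1 sheet(s), 12 / 12 strands in sheets, %Ms = 100
#>   sheet 1: 12 strands (extent 32): 1,2,3,4,5,6,7,8,9,10,11,12
print(res$profile)
#>   orientation shift count fraction
#> 1    parallel     0    11        1

olig <- identify_oligomers(peptide_centers(fx$frame, res$topology))
print(order_report(fx$frame, res$topology, olig))
#>   id size p2       rg
#> 1  1   12  1 35.49718
```

Reading: the 12 strands form 11 adjacent pairs, every one matched as
parallel in-register (`k = 0`) with a perfect NCC score of 1 and all 32
contacts explained; the triplet heuristic merges them into a single sheet
containing all strands (`%Ms = 100`); as an aggregate the sheet is one
12-mer oligomer with perfect nematic order (`P2 = 1`).

For trajectories, `analyze_trajectory()` runs the same pipeline per frame
and writes `trajectory.csv` (β-interactions, % peptides in sheets, oligomer
count/size, mean P2 per frame) plus per-frame shift profiles.

The command-line interface wraps the same functions:

```sh
Rscript inst/scripts/strandscan.R analyze-structure \
    --input structure.pdb --strands 12 --strand-length 32 --out out_dir
```

### Reference PDB validation

`analyze_structure()` reproduces published beta-strand statistics of
reference structures when run with their published strand divisions
(2mxu: SL 32, S 12; 2fkg: 9, 35; 1d2s: 10, 34; 3bep: 6, 122). The entries
are not redistributed; download them from the RCSB into
`inst/extdata/pdb/` (see the note there) and the validation test in
`tests/testthat/test-acceptance.R` will pick them up.

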