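# Reference PDB entries (not redistributed)

Place the following RCSB entries here, named `<id>.pdb`, to enable the
reference-structure validation in `tests/testthat/test-acceptance.R`:

| entry | strand division (SL, S) | system |
|-------|-------------------------|--------|
| 2mxu  | 32, 12 | Abeta(1-42) amyloid fibril (ssNMR) |
| 2fkg  |  9, 35 | engineered OspA beta-sheet mimic |
| 1d2s  | 10, 34 | laminin G-like module |
| 3bep  |  6, 122 | E. coli beta clamp |

Download, e.g.:

    for id in 2mxu 2fkg 1d2s 3bep; do
      curl -O https://files.rcsb.org/download/${id^^}.pdb
      mv ${id^^}.pdb ${id}.pdb
    done

Without these files the corresponding acceptance test reports the entries
as unavailable; all other tests are self-contained.
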