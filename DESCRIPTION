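Package: strandscan
Title: Beta-Sheet Topology Recognition in Coarse-Grained Peptide Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pattern-recognition toolkit for beta-structuring in coarse-grained
    peptide and protein systems. Detects inter-strand beta-contacts from backbone
    bead coordinates (one grain per residue), assigns strand-pair registries
    (parallel/antiparallel orientation and residue shift) by normalized
    cross-correlation against a shift-matrix template library, reconstructs
    beta-sheets with a triplet continuity heuristic, and scores aggregates by
    distance-threshold oligomer identification, nematic order parameter and
    radius of gyration. Reads PDB structures and GRO coordinate/trajectory
    files; includes generators for synthetic ideal sheets, random peptide gases
    and clustered aggregates with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
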