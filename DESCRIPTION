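Package: insertag
Title: Screening and Design of Loop-Insertion Crystallization Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for carrier-driven crystallization of recalcitrant
    proteins via internal loop-insertion tags. Screens candidate carrier
    domains from PDB/mmCIF coordinate files against six hard structural
    criteria (size, disulfides, ligands, resolution, N/C-termini proximity,
    globularity) plus soft ranking factors (B-factors, surface charge),
    designs chimeric fusion constructs that replace flexible insertions with
    a tag while tracking segment provenance and point mutations, and
    quantitatively compares structures: Kabsch superposition with
    outlier-rejected RMSD, global sequence identity, solvent-accessible and
    buried surface area, hydrogen-bond and salt-bridge interface census.
    Includes a deterministic synthetic-structure generator so the full
    pipeline is testable without downloading archive entries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
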