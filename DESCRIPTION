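Package: ssmap
Title: Secondary Structure Assignment from Protein Coordinates and
    Structure-Annotated Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns protein secondary structure from three-dimensional
    coordinates in PDB format using the Kabsch-Sander hydrogen-bond energy
    model (electrostatic H-bond detection, n-turns, beta-bridges, ladders
    and sheets, helices, bends), including backbone amide-hydrogen modelling
    for structures deposited without hydrogens.  Reports assignments in the
    classic fixed-column DSSP layout or in a whitespace-separated tabular
    layout with absolute residue names, and parses DSSP-format reports for
    import.  Provides residue-level comparison of two assignments (8-state
    and collapsed 3-state confusion matrices with per-class agreement), a
    3-state simplification for painting secondary structure onto sequence
    alignments, pairwise identity and p-distance matrices, and physical
    peptide properties (mass, extinction coefficient at 280 nm, isoelectric
    point, charge).  Ideal-geometry backbone builders generate test
    structures with known secondary structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
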