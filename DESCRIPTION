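Package: abagmap
Title: Mapping and Statistics of Antibody-Antigen Binding Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing antibody-antigen binding interfaces from
    experimentally determined structures. Reads PDB files together with a
    SAbDab-style chain annotation table, eliminates crystal-packing duplicates
    by mean B-factor, removes redundant antibodies by greedy 95% sequence
    identity clustering of IMGT variable domains, extracts non-hydrogen
    atom-atom contacts at a 5 Angstrom cutoff, and computes interface
    statistics: unique paratope/epitope residue and atom accounting, IMGT
    region and hotspot maps, amino-acid and physicochemical class frequencies,
    paratope-epitope co-occurrence, discontinuous epitope segmentation,
    Wu-Kabat variability, germline mutation rates, and percentile bootstrap
    confidence intervals. A ground-truthed synthetic complex generator makes
    every pipeline stage testable without downloading structures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
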