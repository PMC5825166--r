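Package: tetherscope
Title: Comparative Structure, Dynamics and Frustration Analysis of Tethered Protein Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how the tethering of extra domains changes a
    protein domain relative to the same (or a homologous) domain in isolation.
    Implements Kabsch superposition with global RMSD and a seed-extend GDT
    score, two-sigma detection of locally deviating regions, C-alpha contact
    networks with communicability centrality, anisotropic-network-model normal
    modes with distance-dependent springs (80 percent variance mode selection,
    terminal trimming, cross-correlation matrices and Rv-coefficient
    comparison), an energetic frustration framework (single-residue,
    mutational and configurational indices over decoy ensembles with a
    pluggable pairwise contact potential), in-silico control constructs
    (domain amputation, domain swap, homolog chimera with junction-clash
    trimming), and a seeded synthetic-structure generator so that every stage
    of the pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
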