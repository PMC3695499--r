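Package: rnasphere
Title: Sphere-Neighborhood RMSD Profiling for RNA 3D Model Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares RNA 3D structural models against a reference
    structure by optimally superimposing, for every nucleotide, the set
    of atoms inside a sphere centred on a chosen backbone or sugar atom
    (C1', P, O5' or O3'), across a vector of sphere radii.  Small radii
    probe local geometry; radii covering the whole molecule recover the
    global RMSD.  Produces per-residue RMSD profile matrices,
    radius-averaged curves and cutoff statistics, renders the associated
    multi-model, averaged, 2D-map, 3D-surface and cutoff plots, validates
    PDB input, and generates seeded synthetic helices and decoys for
    controlled evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
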