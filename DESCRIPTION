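Package: valvemorph
Title: Mesh-Based Shell Volumetrics and Phylogenetic Comparative Analysis of Bivalve Valves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric and macroevolutionary analysis of bivalve shell
    valves. Reads and validates triangle meshes of single valves (STL, OBJ,
    PLY), computes proportional shell volume (pSV) by signed-tetrahedra
    volumetrics, shell length (SL) and cross-sectional aspect ratio (XS)
    from hinge-aligned bounding boxes, classifies specimens into
    substratum-use functional groups, performs disparity rarefaction with
    confidence envelopes, and fits phylogenetically corrected linear models
    with residual-randomization permutation ANOVA alongside phylogenetic
    signal statistics (Blomberg's K, Pagel's lambda). Includes a synthetic
    data generator (parametric hemi-ellipsoid valves with analytically known
    volumes, birth-death trees, Brownian traits) so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
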