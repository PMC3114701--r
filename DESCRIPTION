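Package: patchlib
Title: Protein Surface Patch Libraries for Native Structure Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts chemically typed solvent-exposed surface patches around
    exposed beta-carbons of protein structures, compares patches under a
    chemically constrained minimum-RMSD distance (exact enumeration and an
    inner-sphere seeded heuristic), clusters patches with K-means++ seeded
    medoid clustering into a centroid library, and scores structures against
    such a library via the distance to the closest library element (DCLE),
    cluster-preference vectors and rank-sum tests, so that native structures
    can be discriminated from predicted decoy models.  Includes a seeded
    synthetic mini-protein generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
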