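Package: bilayermech
Title: Mechanics, Ordering and Mixing Statistics of Binary Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for planar lipid bilayer simulations.
    Computes surface tension from the pressure tensor, the area
    compressibility modulus K_A from a weighted regression of surface
    tension on area strain with autocorrelation-corrected uncertainties,
    carbon-carbon acyl-tail order parameter profiles, phosphorus spacing
    distributions, periodic Voronoi leaflet tessellations, mixed-contact
    and neighbor-composition mixing statistics, and a head / phosphate /
    glycol / tail decomposition of pairwise nonbonded interaction
    energies.  Includes synthetic-bilayer generators with known ground
    truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    deldir,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
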