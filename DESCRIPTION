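Package: cryofel
Title: Free-Energy Landscapes and Ligand-Binding Transition Maps from
    Cryo-EM Particle Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Geometric analysis of conformational heterogeneity in
    single-particle cryo-EM. Bins aligned particle images into projection
    directions on the orientation sphere, embeds each direction with a
    diffusion map, propagates and homogenizes the resulting conformational
    coordinates into global coordinates, and converts sighting counts into
    inverse-Boltzmann free-energy landscapes per experimental condition
    (with and without ligands). A master-equation model of ligand
    association yields interlandscape transition-probability maps and
    their hotspots; least-energy functional paths from the apo minimum
    through a hotspot to the ligand-bound minimum are extracted, resampled
    into movie frames with per-frame snapshot sets, and toy volumes are
    reconstructed by real-space back-projection. Includes a fully
    ground-truthed synthetic-ensemble generator (a deformable voxel
    phantom with two conformational degrees of freedom sampled from
    prescribed analytic landscapes) used to validate the pipeline end to
    end, plus residue-pair distance-series utilities for per-frame atomic
    models. Reads and writes MRC/MRCS image stacks and RELION-dialect
    STAR tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
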