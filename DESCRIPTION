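Package: rhizogrow
Title: Root System Architecture Growth Simulation Around Rigid Obstacles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the growth of a plant root system in a thin
    (pseudo-2D) substrate chamber, coupling unsaturated soil water flow
    (Richards equation with Van Genuchten-Mualem closure, solved on a
    structured grid with a mass-conservative Picard scheme) to water flow
    in the root xylem (axial Darcy flow plus radial soil-root exchange)
    and to tip-level growth rules: age-dependent elongation limited by
    substrate penetration resistance, a weighted growth-direction rule
    combining growth-history inertia, gravitropism, a penetration
    resistance gradient and a random deviation angle, arc-length
    triggered lateral branching, and a contact/recovery model for growth
    around rigid obstacles in which the along-obstacle growth direction
    keeps a linearly vanishing weight during a recovery period
    proportional to the contact time. Also provides root-network indices
    (total length, foraging area, branching density, graph statistics,
    fan-tree and Steiner-tree reference lengths), RSML/VTK/CSV input and
    output, a synthetic fixture generator, and least-squares calibration
    utilities for the growth-rule parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
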