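Package: dotmapr
Title: Dot Mapping for Multi-Parameter Cardiac Chamber Visualization
Version: 0.1.0
Authors@R: person("dotmapr", "developers", role = c("aut", "cre"),
    email = "dotmapr@example.org")
Description: Displays two or more scalar datasets on a single 3D cardiac
    chamber model by combining a colour-shaded mesh with a density-stippled
    dot overlay. Dot counts per mesh element follow a distance-corrected,
    Poisson-sampled weighting of element scalar values, so that screen dot
    density stays constant under zoom for regions of uniform signal. Includes
    surface (triangle) and volumetric (tetrahedron) samplers, VTK/PLY/OFF
    mesh I/O, an offscreen orthographic renderer, synthetic electroanatomic
    and imaging fixtures (activation, voltage, late gadolinium enhancement),
    and a computational perception bench for gradient-axis and focal-source
    recovery from dot clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png,
    MASS,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
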