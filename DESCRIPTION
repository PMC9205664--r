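Package: beescape
Title: Bumblebee Colony Dynamics and Pollination Services on Simulated
    Agricultural Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A weekly-timestep, spatially explicit simulator of bumblebee
    (Bombus sp.) colony dynamics and crop pollination services on artificial
    agricultural landscapes. Generates neutral raster landscapes of
    semi-natural habitat, early- and late-flowering mass-flowering crops and
    non-bee matrix; drives floral resources with a generalized seasonal
    progression (a growing-degree-day proxy) and per-habitat flowering
    windows; models central-place foraging with an exponential distance
    kernel on a toroidal grid; runs a five-stage within-season colony model
    for the average nest in the landscape; and evaluates drought
    perturbations of floral resource growth in a case-control design.
    Includes a latin-hypercube simulation experiment and a one-at-a-time
    local sensitivity analysis of the population parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
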