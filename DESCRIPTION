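Package: mossreactor
Title: Kinetic Modelling of Recombinant Protein Production in Moss Photobioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unstructured kinetic model of protonema suspension cultures of
    Physcomitrella (Physcomitrium patens) producing a recombinant protein in
    stirred-tank photobioreactors. Growth follows Monod kinetics under
    nitrate/light co-limitation combined by the minimum (threshold) law; the
    light field inside the side-illuminated cylindrical vessel is computed from
    the Beer-Lambert law with angular and radial averaging. Macroscopic mass
    balances for biomass, nitrate, intracellular product and culture volume are
    integrated through batch, fed-batch and semi-continuous operating schedules
    (continuous dilution or discrete daily medium exchanges). Kinetic
    parameters are estimated from observed trajectories by bounded global least
    squares using differential evolution, with per-variable coefficients of
    determination. A synthetic-data generator reproduces the measurement
    structure of bioreactor runs (daily sampling, replicate measurements,
    multiplicative noise) so the full simulate-generate-fit pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
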