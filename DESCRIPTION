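Package: hepacal
Title: Multi-Scale Simulation of Hepatic Calcium Signaling and
    Glycogenolysis Under Autonomic Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a liver lobule as a chain of 15 hepatocyte and
    sinusoidal blood compartments coupled to a systemic body compartment,
    with per-hepatocyte IP3-calcium cross-coupling oscillators, gap-junction
    IP3 exchange, calcium-potentiated glycogenolysis, advective blood
    transport, and autonomic feedback through CNS glucose sensing,
    pancreatic hormone secretion, and adrenal catecholamine release.
    Provides scenario presets contrasting innervation patterns (human-like,
    rodent-like, denervated), gap-junction coupling strengths, adrenal
    amplification, and portal-hypertensive blood flow, together with an
    analysis layer for calcium spike detection, intercellular wave metrics,
    and zonal glucose output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    graphics,
    jsonlite,
    stats,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
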