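Package: permafrostAOM
Title: Quantifying Anaerobic Methane Oxidation in Thawing Submarine Permafrost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying anaerobic oxidation of methane (AOM) from
    depth-resolved pore-water geochemistry of submarine permafrost cores.
    Classifies sediment horizons into oxidized and source zones by their
    stable carbon isotope signature of methane, extracts the maximal isotope
    shift, estimates the fraction of methane oxidized under a registry of
    literature fractionation-factor scenarios with physical rejection of
    impossible scenarios, and propagates retained fractions through a
    permafrost-degradation methane-release model upscaled to the pan-Arctic
    submarine permafrost area. Includes a sulfate-methane transition zone
    detector, a headspace-equilibration dissolved-methane calculator, GDGT
    lipid biomarker indices (BIT, methane index), and a seeded synthetic-core
    generator with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
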