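Package: pollenCaOsc
Title: Quantification of Pollen Calcium Oscillations and Hypo-Osmotic Shock
    Transients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of cytosolic calcium dynamics in
    germinating pollen grains imaged with GCaMP-type or ratiometric
    indicators. Builds bleach-corrected dF/F0 traces from raw fluorescence
    tables or image stacks, detects calcium spikes and classifies them by
    amplitude into small (CaOscS) and large (CaOscL) oscillation events,
    segments traces into the resting/oscillation phase grammar that precedes
    germination, quantifies hypo-osmotic shock transients (peak, decay,
    desensitization, dose-response), aggregates cohorts across genotype and
    medium osmolarity, and converts osmolarities to water potentials with
    the van't Hoff relation. Includes a seeded synthetic-trace generator
    with ground truth emulating wild-type and osca2.1/2.2 mutant pollen
    signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, minpack.lm, tiff, withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
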