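Package: phaselink
Title: Chaperone-Linked Phase Equilibria and Particle Size Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of how a nuclear-import receptor
    (Karyopherin-beta2) remodels the dilute phase of prion-like RNA-binding
    proteins such as FUS. Implements the 1:1 chaperone-cargo binding
    equilibrium that renormalizes the free cargo concentration, the
    polyphasic-linkage shift of the saturation concentration, processing and
    Kullback-Leibler comparison of microfluidic resistive pulse sensing
    (MRPS) particle-size distributions including dual-cartridge bootstrap
    merging, fitting of fluorescence correlation spectroscopy (FCS)
    autocorrelation traces with Stokes-Einstein conversion to hydrodynamic
    radii, and a seeded synthetic-data generator that emulates
    concentration-dependent heavy-tailed cluster-size landscapes observed
    through the MRPS and FCS instrument models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
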