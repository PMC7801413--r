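Package: chromosaxs
Title: Coarse-Grained SAXS Modelling of Nucleosomes and Chromatosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the small-angle X-ray scattering (SAXS) analysis of
    nucleosome and chromatosome particles in solution and in Mg2+-condensed
    phases. Builds coarse-grained bead models of wrapped nucleosomal DNA with
    parameterised end unwrapping and on-dyad linker histone placement;
    computes Debye scattering intensities, pair-distance distributions, and
    Guinier/indirect-Fourier shape parameters; ranks DNA-unwrapping
    hypotheses against experimental profiles; indexes lamellar and
    two-dimensional hexagonal Bragg series in condensed-phase diffraction
    to classify columnar-isotropic versus lamello-columnar mesophases; and
    analyses Mg2+ precipitation/resolubilisation titrations with charge
    ledgers and Boltzmann sigmoid EC50 fits. Includes seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
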