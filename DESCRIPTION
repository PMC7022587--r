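Package: einshdx
Title: Particle Dynamics from Elastic Neutron Scattering and Hydrogen-Deuterium Exchange Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary probes of lipoprotein and protein
    dynamics. For elastic incoherent neutron scattering (EINS), the package
    extracts hydrogen mean-square displacements from the Q-squared dependence
    of elastic intensities under the Gaussian approximation and converts
    piecewise-linear MSD(T) slopes into effective force constants
    (resilience). For hydrogen-deuterium exchange mass spectrometry (HDX-MS),
    it computes random-coil intrinsic amide exchange rates, deconvolves
    bimodal isotopic envelopes into slow- and fast-exchanging populations,
    fits stretched-exponential uptake kinetics, derives protection factors,
    pools peptides into chain populations by relative abundance, and resolves
    residue-level protection factors from overlapping peptides by iterative
    permutation. A synthetic-data generator produces elastic scans and
    deuterated isotopic envelopes with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
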