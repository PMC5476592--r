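Package: hdxfp
Title: Single-Amide Stability Fingerprints from Hydrogen-Deuterium
    Exchange Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Deconvolutes peptide-level hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) centroid uptake data into per-amide exchange
    rates and free energies of exchange. Overlapping proteolytic peptides
    are decomposed into minimal subfragments, subfragment deuterium
    levels are fitted by constrained global linear least squares, and
    per-amide rate constants are then obtained by a global bounded
    non-linear least-squares fit with back-exchange correction.
    Random-coil intrinsic exchange rates are computed from bundled
    reference factors (Bai et al. 1993; Molday et al. 1972), and the
    per-residue stability fingerprint dG_ex = -RT ln(k_ex/k_int) is
    exported as tables, plots and structure colourings. A synthetic-data
    generator emulating overlapping pepsin/protease-XIII peptide
    libraries with EX2 kinetics, back-exchange and centroid noise makes
    every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    bio3d,
    graphics,
    grDevices,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
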