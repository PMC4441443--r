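Package: hydrotemp
Title: Temperature Dependence of Amino-Acid Hydrophobicity from Protein Structure Sets
Version: 0.1.0
Authors@R:
    person("Hydrotemp", "Developers", email = "hydrotemp@example.org",
           role = c("aut", "cre"))
Description: Extracts the temperature dependence of amino-acid
    hydrophobicity from sets of protein chains resolved at known
    acquisition temperatures (typically NMR ensembles). Implements
    knowledge-based core-to-surface transfer free-energy estimators
    (contact, surface-propensity, area and scaled-area based), temperature
    binning, reference correction against pooled charged and polar
    residues, split-sample standard errors, label-shuffle permutation
    significance of the low-versus-room-temperature difference, and
    weighted least-squares parabola fits of energy against temperature.
    Includes parsers for DSSP accessibility output and PDB-header
    acquisition temperatures, and a synthetic chain-set generator with a
    configurable injected temperature signal so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
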