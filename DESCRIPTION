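Package: butyrogen
Title: Stoichiometry, Thermodynamics and Hydrogen Regulation of Gut Butyrogen Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the branched fermentation network of human gut
    butyrate-producing bacteria (butyrogens) and its regulation by hydrogen
    gas.  Provides a redox-balanced stoichiometric flux model of the
    glycolysis/LDH/PFOR/PFL/acetate-kinase/butyrate-branch network, the
    one-parameter family of elementally balanced glucose fermentation
    reactions spanning pure acetate to acetate-consuming butyrate
    production, Gibbs energy calculations of those reactions as a function
    of hydrogen partial pressure with ATP-feasibility thresholds,
    carbon-share accounting for culture metabolite endpoint data, a
    breath-gas pipeline classifying human subjects by gut methanogenesis
    and comparing methanogenic to non-methanogenic groups, and synthetic
    culture and cohort data generators so the entire pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
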