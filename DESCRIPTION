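Package: psessc
Title: Pre-miRNA Hairpin Classification via Pseudo Structure Status Composition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discriminates real microRNA precursor hairpins from pseudo
    hairpins. RNA secondary structures in dot-bracket notation are encoded
    over a 10-symbol structure-status alphabet (4 unpaired bases and 6
    orientation-distinguished base pairs); feature vectors combine local
    n-tuple status compositions with tiered free-energy correlation factors
    (PseSSC), optionally extended with the minimum free energy, a Monte
    Carlo randomization-test P-value and tri-nucleotide composition
    (ExPseSSC). Classification uses a radial-basis-function support vector
    machine trained by sequential minimal optimization, with grid search,
    k-fold/jackknife cross-validation, ROC/AUC and the Sn/Sp/Acc/MCC metric
    set. Includes Vienna/FASTA readers, a maximum-base-pairing baseline
    folder, benchmark admission filters and a synthetic hairpin generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
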