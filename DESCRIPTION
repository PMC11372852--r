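Package: sba
Title: Short Branch Attraction in Gene and Species Tree Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Theory and simulation tools for studying short branch
    attraction (SBA), a systematic bias of maximum-likelihood phylogenetic
    inference that groups taxa subtended by very short branches when the
    internal branch separating them carries little or no signal.  Provides
    exact site-pattern probabilities for four-taxon trees under the
    Jukes-Cantor model, the exact finite-length distribution of the ML
    quartet topology, multispecies-coalescent gene-tree simulation with
    per-population size parameters, sequence simulation under GTR+Gamma,
    an exhaustive quartet ML engine and NNI-based tree search, NJst
    species-tree estimation from gene trees, and scenario runners that
    quantify SBA in gene trees and species trees together with the
    polytomy-collapse remedy for short estimated internal branches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
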