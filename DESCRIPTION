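Package: ncmnet
Title: Integrated Likelihood of Species Trees and Networks Under a
    No-Common-Mechanism Coalescent Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topology-only inference of species trees and rooted phylogenetic
    networks from multi-locus gene tree topologies under the multispecies
    (network) coalescent with a no-common-mechanism (NCM) model, in which
    every locus evolves under its own branch lengths and inheritance
    probabilities.  Branch lengths (exponential prior, optionally truncated)
    and inheritance probabilities (Beta prior) are integrated out
    analytically, so the likelihood of a topology is computed without
    optimising or sampling continuous parameters.  Includes exhaustive and
    hill-climbing topology search, a minimize-deep-coalescences (MDC)
    comparator, a seedable multispecies network coalescent simulator,
    displayed-tree extraction and network indistinguishability utilities,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
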