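Package: repeatfield
Title: Evolutionary Energy Fields for Tandem Repeat Proteins
Version: 0.1.0
Authors@R:
    person("Repeat", "Field Developers", email = "maintainer@repeatfield.org",
           role = c("aut", "cre"))
Description: Infers a statistical energy function ("evolutionary field") for
    families of tandem repeat proteins from multiple sequence alignments of
    consecutive repeat pairs.  The model combines per-position amino-acid
    fields, pairwise couplings over a 21-state alphabet (20 amino acids plus
    gap) and a repeat-identity potential that captures the excess similarity
    of adjacent repeats.  Parameters are learned by Monte Carlo gradient
    descent with an L1 penalty that drives uninformative couplings to exactly
    zero.  Includes Metropolis sequence sampling, energy scoring and repeat
    array decomposition, mutation ddG-proxy regression, consensus and
    identity analyses, coupling/contact-map comparison, a synthetic-data
    generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
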