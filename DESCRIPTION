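Package: moltwin
Title: Conditioned Molecular Generation with Graph-Aligned SMILES Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and samples a small GPT-style autoregressive SMILES
    generator whose sequence representation is aligned, during training
    only, with a two-layer graph-attention encoding of the molecular graph
    through a Barlow Twins redundancy-reduction loss. Generation can be
    conditioned on target values of logP, TPSA, QED and synthetic
    accessibility, and on a Bemis-Murcko scaffold. Includes a deterministic
    fragment-grammar generator of valid drug-like SMILES fixtures and the
    standard generative-chemistry evaluation suite: validity, uniqueness,
    novelty, internal diversity, Frechet distance between descriptor
    distributions, KL-divergence scores, and per-property deviation
    statistics for conditioned sampling. Molecular parsing, descriptors,
    scaffolds and fingerprints are delegated to RDKit through a bundled
    command-line bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the rdkit package, resolvable as
    'python' on the PATH
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
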