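Package: retromol
Title: Retrospective Validation of Molecular Generative Models on Project Time Axes
Version: 0.1.0
Authors@R:
    person("Retromol", "Developers", email = "retromol@example.org",
           role = c("aut", "cre"))
Description: Tools for retrospectively evaluating de novo molecular
    generative models against drug-discovery project data.  A bioactivity
    table (SMILES + pXC50, optionally dated) is mapped onto a project time
    axis -- real synthesis dates or a pseudo-time built from structural
    fingerprints, principal component analysis and potency -- and stratified
    into early/middle/late stages and alpha/beta/gamma activity regions.
    Generated compound sets are scored with validity, uniqueness, novelty,
    rediscovery and stratified average single-nearest-neighbour Tanimoto
    similarity (aSNN); an ECFP6 random-forest activity model supports
    score-based top-k selection; k-means cluster predictivity analysis and
    per-region negative log-likelihood diagnostics complete the workflow.
    A Markov-chain SMILES generator provides a desk-scale stand-in for an
    external neural generative engine, and a synthetic-project simulator
    emulates public-like and in-house-like project chemistry regimes.
    Chemistry primitives (SMILES standardization, hashed fingerprints,
    random forests) are delegated to RDKit and scikit-learn through a
    batched Python subprocess bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    digest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
SystemRequirements: Python (>= 3.8) with rdkit and scikit-learn on PATH as
    'python'
Config/testthat/edition: 3
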