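Package: chitopa
Title: Simulation and Fingerprint Analysis of Chitosan Acetylation Patterns
Version: 0.1.0
Authors@R: person("chitopa", "maintainers", email = "chitopa@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the pattern of acetylation (PA) of chitosans
    in silico. Chitosan chains are binary copolymers of N-acetylglucosamine
    (A) and glucosamine (D); the package generates chain ensembles with
    controlled degree of polymerisation, fraction of acetylation (F_A) and
    PA (Bernoullian random, first-order Markov block-wise, or regular),
    simulates reverse-mode chitin-deacetylase N-acetylation with
    subsite-specific preference weights (kinetic Monte Carlo), digests
    ensembles with subsite-specific endo-hydrolases (chitinase, chitosanase,
    chitinosanase, lysozyme, chitotriosidase presets), and implements the
    analytics used to characterise PA: dyad fractions and the P-sigma
    deviation-from-randomness statistic, enzymatic-mass-spectrometric (EMS)
    fingerprint F_A estimation, block-size profile inference from DA/XX
    chitinosanase products, dispersity of chain-length distributions, and
    closed-form Bernoulli (random-PA) theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
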