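Package: cswltools
Title: Phonotactic Stimulus Construction, Design Generation and
    Chance-Offset Mixed-Logistic Analysis for Cross-Situational Word
    Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and analysing cross-situational word
    learning (CSWL) experiments with phonotactically controlled
    pseudoword stimuli. Computes positional biphone phonotactic
    probabilities from a frequency lexicon (log-token-frequency
    weighting), searches for consonant-vowel pseudowords that maximise
    phonotactic probability and recombines their syllables into a
    matched slightly-lower-probability set, generates interleaved
    ambiguous 2x2 training trials and 4-alternative forced-choice test
    trials with full balancing diagnostics, simulates learner cohorts
    (associative co-occurrence learner, guesser, and the generative
    counterpart of the analysis model), and fits chance-offset mixed
    logistic regressions (frequentist via lme4, Bayesian via JAGS) with
    latent-scale intraclass correlations, marginal/conditional R2,
    combined odds ratios, bootstrap accuracy summaries and one-sample
    t-test power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
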