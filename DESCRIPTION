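Package: tdehmm
Title: Time-Delay Embedded Hidden Markov Models for Transient
    Phase-Coupling Network States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers transient, frequency-resolved power and
    phase-coupling network states in multichannel electrophysiological
    recordings. Implements time-delay embedding with PCA reduction, a
    variational-Bayes hidden Markov model with zero-mean Gaussian
    observation models over the embedded space, greedy sign-flip
    disambiguation of source-reconstructed dipole polarity, state-wise
    multitaper power/cross-spectra/coherence, non-negative matrix
    factorisation of coherence spectra into data-driven frequency modes,
    temporal dynamics statistics (dwell times, interval times, fractional
    occupancy, onset point-process spectra, permutation tests), Riemannian
    distances between state autocovariances, and a Markov-switching
    oscillator simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
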