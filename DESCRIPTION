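Package: megreplay
Title: Decoding Working-Memory Replay from MEG Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding which of several sequentially encoded visual
    stimuli is replayed during the retention period of a working-memory task,
    from multichannel MEG sensor recordings. Implements time-bin-resolved
    pairwise linear classification of encoding epochs with cross-validation
    and cluster-permutation group statistics, margin-thresholded state
    decoding of delay periods with a quantile rejection rule, Markov-chain
    replay dynamics with directionality tests, linkage of replay duration to
    memory behavior via mixed-effects models, and an event-related field
    contrast between predominantly maintained and other stimuli. A synthetic
    data generator emulating the sensor array, trial design, hidden replay
    process, and behavioral coupling makes every stage testable without
    access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
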