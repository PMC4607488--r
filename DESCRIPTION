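Package: dynsync
Title: Dynamic Phase Synchronization Micro-States of Intrinsic Connectivity
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sliding-window analysis of time-varying phase synchronization
    and amplitude between intrinsic connectivity network (ICN) time courses.
    Computes instantaneous phase and amplitude via the analytic signal,
    windowed mean phase coherence (dPS) and windowed amplitude (dAMP),
    censors motion-corrupted windows using framewise displacement and DVARS,
    discovers connectivity micro-states by Ward hierarchical clustering with
    Gaussian-mixture cluster-number detection, and contrasts eyes-open versus
    eyes-closed resting conditions with t-tests, FDR control and Fisher
    r-to-z comparisons of correlations. Includes a synthetic cohort
    generator that plants known micro-states, condition effects and motion
    spikes so the whole pipeline is testable without imaging data, plus
    per-window graph metrics (node strength, global efficiency) and a
    sliding-window-size robustness harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    mclust,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
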