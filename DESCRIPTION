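Package: hierdyn
Title: Hierarchical Dynamics of Cortical Fluctuation Amplitude
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the spatial allocation of slow cortical
    signal fluctuations shifts along the unimodal-transmodal connectome
    hierarchy with global states of consciousness. Implements band-limited
    variability and (f)ALFF maps, diffusion-map embedding of functional
    connectomes, a scalar hierarchical index and its windowed dynamics,
    spatial-autocorrelation-preserving spin permutation tests, global-signal
    topography state clustering with connectivity and sample entropy,
    quasiperiodic spatiotemporal pattern (QPP) template building and event
    detection, and multitaper band-limited power analysis for
    electrocorticography. A synthetic-data generator with known ground truth
    stands in for restricted fMRI/ECoG recordings so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
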