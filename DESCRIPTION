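Package: musclenet
Title: Frequency-Specific Muscle Networks from Multichannel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates undirected (intermuscular coherence) and directed
    (partial directed coherence) connectivity spectra between all pairs of
    muscles from multichannel surface electromyography, unmixes the stacked
    spectra into frequency-specific weighted muscle networks by non-negative
    matrix factorization (alternating least squares), and characterises the
    resulting networks with weighted graph metrics (clustering coefficient,
    global efficiency, betweenness centrality) and repeated-measures
    statistics. Includes a seedable multichannel-EMG generator with planted
    band-limited common drives and directed envelope coupling, so every stage
    of the pipeline can be validated against known ground truth, and a
    time-domain muscle-synergy extraction for comparison with the
    frequency-domain networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
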