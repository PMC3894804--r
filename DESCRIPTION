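Package: optrode
Title: Spike-Train Analysis for Optogenetic Control Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying optogenetic control of single neurons
    recorded extracellularly in vivo. Provides a ground-truthed synthetic
    generator of voltage traces with light-evoked (channelrhodopsin-style)
    and light-silenced (halorhodopsin-style) spiking, band-pass filtering
    and amplitude-threshold spike detection, alignment of spikes to TTL
    light-command events, per-pulse spike-probability (fidelity) and
    first-spike latency statistics, peristimulus time histograms,
    silencing and rebound metrics for continuous-light protocols, and
    autocorrelogram construction with phasic/non-phasic classification.
    All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
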