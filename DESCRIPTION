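Package: emosim
Title: Event-Driven Agent-Based Simulation of Emotional Bookkeeping in
    Primate Groups
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A spatially explicit, event-driven agent-based model of a
    primate group in which two emotional dimensions (arousal, anxiety)
    and a pleasure dimension (satisfaction), together with
    partner-specific FEAR and LIKE attitudes, regulate social behaviour.
    LIKE attitudes either integrate received grooming over time
    (emotional bookkeeping, the dynamic-attitude model) or are a fixed
    function of rank distance (the fixed-attitude control model). The
    package implements the simulation engine in C++, the behavioural
    observation protocol (one-zero proximity sampling, interval-based
    hourly rates, yearly averages), and the social-matrix statistics
    used to quantify the emergent group structure: Shannon/Buzas-Gibson
    evenness, rowwise Kendall Tau-Kr matrix reciprocity, rank-distance
    categorisation, partner-specificity standard deviations, and rowwise
    Pearson predictability with Fisher-z pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
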