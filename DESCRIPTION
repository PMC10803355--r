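Package: secsim
Title: Agent-Based Microsimulation of Speed Enforcement Cameras and Crash Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time car-following microsimulation of a multi-lane highway
    with heterogeneous driver behaviour (law-abiding drivers, kangaroo drivers
    that brake only inside camera detection zones, and consistent speeders),
    under fixed and average (point-to-point) speed enforcement camera layouts
    and in-vehicle telematics enforcement. Computes the ratio of unsafe driving
    (RUD, the share of distance travelled above the speed limit threshold),
    fits scenario-grid regressions of RUD on enforcement and traffic factors,
    and translates mean-speed differences between camera layouts into crash
    relative-risk changes with the Nilsson power model.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
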