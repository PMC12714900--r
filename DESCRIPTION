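Package: micrograze
Title: Estimation and Evaluation of Microzooplankton Grazing Mortality Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating picophytoplankton mortality rates from
    incubation experiments and for evaluating those estimators against known
    truth. Implements the dilution technique (Model I regression of apparent
    growth rate on the fraction of whole water), the disappearance rate of
    fluorescently labeled bacteria (FLB) with filtered-medium control
    correction, and direct observed mortality from abundance change, together
    with a deterministic prey-grazer-virus-bacteria community simulator that
    builds virtual dilution series and tracer experiments with Poisson
    counting noise. A comparison pipeline computes percent differences against
    observed rates, interquartile-range outlier removal, abundance binning,
    curve alignment at a reference log abundance with window slopes, and
    summary tables with Welch, Wilcoxon and Kruskal-Wallis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
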