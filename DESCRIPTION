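Package: wbepi
Title: Wastewater-Based Epidemiology of Illicit Drug Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wastewater-based epidemiology (WBE) of illicit
    stimulant use: conversion of influent drug-residue concentrations to
    population-normalized mass loads with a censoring (below-LOQ) policy,
    back-calculation of consumed pure-drug mass and average daily doses
    via excretion correction factors, city-level combined-dose profiles,
    slope-based multi-year trend classification, anomaly screening for
    direct disposal events, Monte-Carlo propagation of multiplicative
    measurement uncertainties, and a synthetic-data generator that
    emulates multi-city annual one-week monitoring campaigns with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
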