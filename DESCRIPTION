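Package: prrpsim
Title: System Dynamics Projection of Coexisting Tobacco Product Use and
    Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Stock-and-flow population simulator for markets where
    combustible cigarettes coexist with up to two potentially reduced
    risk nicotine products (e-cigarettes, tobacco heating products).
    Enumerates the joint product-status state space and its admissible
    transition flows, runs cohort-component demography (ageing, births,
    net migration) with risk-adjusted all-cause mortality, projects
    smoking and alternative-product prevalence and cumulative life-years
    lost under configurable market scenarios, and quantifies uncertainty
    by Monte-Carlo resampling of transition probabilities within their
    95% confidence intervals.  A seeded synthetic fixture generator
    provides Italy-shaped demographic and smoking inputs so every
    component is runnable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
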