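Package: axoquant
Title: Quantification of Anterograde Transport Maps and Ocular Neuroinflammation Imaging
Version: 0.1.0
Authors@R: person("Axoquant", "Developers", email = "maintainer@axoquant.dev", role = c("aut", "cre"))
Description: Tools for quantifying retinal ganglion cell axonopathy and
    neuroinflammation in rodent ocular-hypertension experiments. Reconstructs
    flattened retinotopic maps of anterograde cholera-toxin-B transport from
    serial superior-colliculus sections and computes the percent-intact-transport
    statistic; quantifies percent area of positive immunolabel and per-animal
    microbead:saline ratios; scores NF-kB nuclear localization in DAPI-gated
    nuclei; measures retinal layer thickness and RGC density; and applies the
    accompanying statistical battery (Shapiro-Wilk-gated t tests, Mann-Whitney
    fallback, one-way ANOVA with Holm-Sidak comparisons, one-sided tests against
    a unity ratio). Includes a synthetic-data generator that renders every input
    modality with known ground truth for validation without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
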