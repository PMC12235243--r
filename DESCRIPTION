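Package: mscpassage
Title: Probabilistic Design Space for Mesenchymal Stem Cell Passage Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mesenchymal stem cell (MSC) passage culture with a
    senescence-dependent growth model in which the specific growth rate
    declines sigmoidally with the cumulative population doubling level
    (cPDL). Provides deterministic and Monte-Carlo simulation of repeated
    seed-grow-harvest cycles, nonlinear least-squares estimation of the
    senescence model constants from growth-rate observations with rotating
    hold-one-sample-out validation, a synthetic-experiment generator for
    parameter-recovery studies, and probabilistic design-space determination
    over passage number and harvesting time against quality specifications
    on senescence level, confluency level, and total harvested cells,
    including a sensitivity analysis for variability in the maximum cell
    density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
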