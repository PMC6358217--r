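Package: oopolar
Title: Quantification of Cortical Membrane Polarity in Drosophila Oocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reproducible quantification of antero-posterior cortical polarity
    from single-plane fluorescence images of Drosophila oocytes. From three
    user-supplied anchor points the package traces the plasma membrane,
    partitions it into anterior, lateral and posterior domains, corrects the
    anterior signal for the apposed nurse-cell membrane, and computes
    total-normalised per-domain quantities, membrane densities, and the
    posterior-exclusion and antero-posterior asymmetry ratios. Companion
    tools implement masked Pearson and Manders colocalization with a
    90-degree rotation null, FRAP recovery-curve normalisation, Mann-Whitney
    group comparisons with Tukey box-plot summaries, and a synthetic
    oocyte-image generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    tiff,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
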