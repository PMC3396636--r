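Package: rechase
Title: Reverse-Chase Analysis of mRNA Half-Lives from Transcriptional
    Shutoff Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring mRNA half-lives in cultured cells from
    tetracycline-conditional transcriptional chase experiments. Implements
    delta-delta-Ct relative quantitation of RT-qPCR chase time courses with
    technical-replicate outlier censoring, estimation of the culture-specific
    cell-expansion constant from cell-count series, exponential decay fitting
    (log-linear or damped nonlinear least squares, optionally with a
    background plateau term), and the growth-corrected half-life
    t1/2 = ln2/(k - j). Supports both the conventional design (per-aliquot
    cell-count correction) and the reverse-chase design (staggered shutoff,
    simultaneous sacrifice, expansion-factor correction), and includes a
    mechanistic simulator of both designs for validation and
    experimental-design comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
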