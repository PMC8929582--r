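Package: pyra
Title: Paired Year Ratio Assessment of Population Trends from Gappy
    Detection Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric estimation of year-on-year population trend from
    seasonally patterned, gap-ridden detection time series such as those
    produced by static acoustic monitoring of cetaceans.  Detections on day
    positions fully logged in two successive annual cycles are paired, and
    the ratio of second-year to first-year paired sums gives a trend
    estimate that needs no explicit model of the seasonal pattern.
    Includes a moving block bootstrap for percentile confidence intervals,
    four permutation (randomisation) trend tests, scenario generators for
    method evaluation, CSV/JSON result writers and a population trend plot.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
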