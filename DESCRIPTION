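Package: hookquant
Title: Quantification of Apical Hook Geometry and Auxin Reporter Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the apical hook of dark-grown seedlings from
    photographs and landmark annotations: the hook angle between the hypocotyl
    axis and the cotyledon line, gray-value staining profiles sampled along the
    bisector chord of the hook and normalized onto the concave-to-convex [0,1]
    axis, total integrated staining intensity, and the Auxin Response
    Distribution Index (ARDI), the relative position at which the cumulative
    signal reaches half of the total. Includes group comparisons (one-way and
    two-way ANOVA with Tukey post-tests and compact letter displays),
    dose-response slope analysis for auxin-transport-inhibitor series, and a
    synthetic seedling-image generator with analytic ground truth so every
    stage of the pipeline can be verified without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
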