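Package: cfosnet
Title: Functional Connectome Analysis of Regional c-Fos Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs immediate-early-gene (c-Fos) functional
    connectomes from two-group rodent studies. Aggregates per-slide
    bilateral c-Fos cell counts into regional densities, compares
    activation between groups with negative-binomial mixed models
    (litter random intercepts, log-area offset, Holm-adjusted
    likelihood-ratio tests, Cohen's d screening), builds group-wise
    Pearson correlation networks constrained by an anatomical
    connectivity mask and dual significance/strength thresholds, and
    identifies hub regions by joint degree and betweenness centrality
    quantile cutoffs. Includes a calibrated synthetic-data generator
    (nested litter effects, negative-binomial dispersion, latent
    cross-region correlation with optional planted hubs) so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmmTMB,
    igraph,
    MASS,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
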