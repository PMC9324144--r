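Package: paleoresil
Title: Persistence, Resilience and Stochasticity of Fossil Nearshore Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the long-term response of nearshore mollusk
    assemblages to glacial-interglacial cycles and classifies it as
    persistent, resilient, or stochastic. Implements the full analysis
    pipeline: valve-resolution and data-selection rules, relative-abundance
    transforms, Bray-Curtis dissimilarity, NMDS ordination and PERMANOVA,
    two bespoke randomization null models (a size-preserving specimen
    permutation test on mean between-interval dissimilarity and a pooled
    multinomial envelope for per-species interval abundances), rarefied
    richness, dominance, biogeographic-affinity profiles, top-k rank
    overlap, abundance-weighted bathymetric estimation, and a
    Dirichlet-multinomial synthetic community generator that emulates the
    study system so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
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
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
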