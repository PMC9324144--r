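# paleoresil

Did nearshore communities ride out the last glacial–interglacial cycle
unchanged, shift and then reassemble, or wander to a new state at every
climate interval? `paleoresil` answers that question for sample-by-species
fossil count data from three Quaternary time intervals — a last
interglacial (LIG), a last late glacial (LG), and the current interglacial
(CIG) — and classifies the long-term response as **persistent**,
**resilient**, or **stochastic**. It is written for quantitative
paleoecologists and community ecologists working with specimen count
tables, species trait tables, and bathymetric census records.

## What it computes

The resemblance measure throughout is Bray–Curtis dissimilarity on
fourth-root transformed relative abundances,

    BC(x, y) = 1 − 2 Σᵢ min(xᵢ, yᵢ) / (Σᵢ xᵢ + Σᵢ yᵢ),

after the data-selection rules of the analysis (valve counts halved with
ceiling, freshwater/terrestrial species excluded, samples with fewer than
25 marine specimens dropped, single-occurrence species removed for the
multivariate matrix). Around that core the package provides:

* **Two bespoke randomization null models** for pairwise interval
  comparisons, both under the hypothesis that the compared samples came
  from one homogeneous system:
  * `bc_permutation_test()` — the observed mean between-interval BC
    against a null built by pooling all specimens and randomly
    reassigning them (without replacement) into synthetic samples that
    keep the exact per-sample sizes; equivalently, hypergeometric
    contingency tables with both margins fixed. One-sided p by the
    (b+1)/(B+1) rule, 1000 iterations by default.
  * `pooled_abundance_envelope()` — per-species interval totals redrawn
    by multinomial sampling from the pooled species-abundance
    distribution into the observed sample structure, giving a null cloud
    per species plus the observed Spearman correlation of totals.
* **Ordination and group testing**: NMDS (k = 2, Kruskal stress-1, via
  vegan) and a one-way PERMANOVA with exhaustive-enumeration option.
* **Ecological descriptors**: analytic rarefied richness (to 25 and 60
  specimens), dominance, biogeographic-affinity profiles (MED/LUS, WAF,
  BOR, COS), top-10 rank overlap between intervals, and
  weighted-averaging bathymetric estimation (per-species preferred depth
  from census records; per-sample abundance-weighted depth).
* **A scenario classifier** (`classify_pattern()`): persistent if no
  pairwise test rejects, resilient if the interglacial pair matches while
  both glacial comparisons reject, stochastic if all three reject.
* **A synthetic-data generator** (`scenario_spec()`,
  `generate_dataset()`, `paper_shape_spec()`): Dirichlet-multinomial
  communities with geometric dominance ladders that reproduce the study
  system's structure (extreme interglacial dominance, convergent
  interglacials, divergent glacial), so the whole pipeline runs and is
  validated without any external data.

Results are tibbles or small S3 objects with `tidy()`/`glance()` methods
and `autoplot()` visualisations (ordination scatter, null-distribution
histograms, envelope clouds, stacked affinity bars).

## Worked example

```r
library(paleoresil)

spec <- scenario_spec("resilient", seed = 42)   # 15/18/65 samples, 60 species
d <- generate_dataset(spec)
run <- run_pipeline(d$community, d$metadata, d$traits, d$census,
                    config = pipeline_config(iterations = 1000, seed = 42))
run
```

```
Glacial-interglacial pipeline run
  samples retained: 98 | species (multivariate): 60
  NMDS stress: 9.18e-05 | PERMANOVA p: 0.000999
  BC test LIG-CIG: observed 0.265, p = 0.5814
  BC test LG-LIG: observed 0.964, p = 0.000999
  BC test LG-CIG: observed 0.959, p = 0.000999
Community-response pattern: RESILIENT (alpha = 0.05)
  p (interglacial pair): 0.5814
  p (glacial comparisons): 0.000999 / 0.000999
  abundance-correlation corroboration: corroborated
```

Reading the output: the two interglacials are no more dissimilar than the
homogeneous-system null allows (mean BC 0.265, p = .58), while the glacial
interval departs overwhelmingly from both (mean BC ≈ 0.96, p = .001, the
smallest value reportable with 1000 iterations) — the signature of a
community that disassembled during the glacial and reassembled afterwards.
The envelope correlations corroborate the call, and PERMANOVA agrees that
interval centroids differ overall.

The published Adriatic top-10 rank table ships with the package:

```r
r <- adriatic_top10_ranks()
overlap_from_ranks(r$rank_lig)  # 7 of the CIG top 10 are also LIG top 10
overlap_from_ranks(r$rank_lg)   # 4 shared with the LG top 10
```

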