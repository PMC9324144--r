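test_that("rarefied richness matches hand-computed hypergeometric cases", {
  expect_equal(rarefied_richness(c(1, 1), 2), 2)
  expect_equal(rarefied_richness(c(9, 1), 10), 2)   # n = N returns observed richness
  expect_equal(rarefied_richness(c(3, 1), 2), 1.5)  # 1 + (1 - C(3,2)/C(4,2))
  expect_error(rarefied_richness(c(3, 1), 5), class = "paleoresil_validation_error")
})

test_that("rarefied richness is nondecreasing in n and matches vegan", {
  set.seed(11)
  counts <- rpois(12, 6) + 1
  vals <- vapply(2:sum(counts), function(n) rarefied_richness(counts, n), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(rarefied_richness(counts, 20),
               as.numeric(vegan::rarefy(counts, sample = 20)))
})

test_that("rarefy_samples excludes undersized samples from a level", {
  cm <- tibble::tibble(sample_id = c("big", "small"), spA = c(40, 10), spB = c(30, 5))
  msgs <- testthat::capture_messages(out <- rarefy_samples(cm, n = c(25, 60)))
  expect_true(any(grepl("excluded", msgs)))
  expect_false(is.na(out$rarefied_25[1]))
  expect_true(is.na(out$rarefied_25[2]))
  expect_false(is.na(out$rarefied_60[1]))  # 70 specimens support both levels
  expect_true(is.na(out$rarefied_60[2]))
})

test_that("dominance is the share of the top species", {
  expect_equal(dominance(c(10, 0, 0)), 1)
  expect_equal(dominance(c(1, 1)), 0.5)
  expect_equal(dominance(c(86, 14)), 0.86)
  expect_error(dominance(numeric(0)), class = "paleoresil_validation_error")
})

test_that("biogeographic profiles pool specimens and sum to one", {
  cm <- tibble::tibble(sample_id = c("s1", "s2"),
                       spA = c(30, 20), spB = c(25, 25), spC = c(0, 0))
  meta <- tiny_meta(ids = c("s1", "s2"), intervals = c("LIG", "LIG"))
  traits <- tiny_traits()
  prof <- biogeo_profile(cm, meta, traits, "LIG")
  expect_equal(sum(prof$proportion), 1, tolerance = 1e-12)
  expect_equal(prof$proportion[prof$biogeo_class == "MED/LUS"], 0.5)
  expect_equal(prof$proportion[prof$biogeo_class == "COS"], 0.5)
  # splitting a sample in two leaves the pooled profile unchanged
  cm_split <- tibble::tibble(sample_id = c("s1a", "s1b", "s2"),
                             spA = c(15, 15, 20), spB = c(10, 15, 25),
                             spC = c(0, 0, 0))
  meta_split <- tiny_meta(ids = c("s1a", "s1b", "s2"),
                          intervals = c("LIG", "LIG", "LIG"))
  expect_equal(biogeo_profile(cm_split, meta_split, traits, "LIG")$proportion,
               prof$proportion)
  # a missing trait row is an error naming the species
  expect_error(biogeo_profile(cm, meta, traits[-1, ], "LIG"), regexp = "spA")
})

test_that("warm-water specimen fractions are per-sample relative abundances", {
  cm <- tibble::tibble(sample_id = "s1", spA = 60, spB = 20, spC = 20)
  fr <- biogeo_fraction(cm, tiny_traits())  # spA is MED/LUS
  expect_equal(fr$fraction, 0.6)
})

test_that("top-k overlap is k for identical intervals and honors tie-breaks", {
  cm <- tibble::tibble(sample_id = c("a1", "b1"),
                       spA = c(5, 5), spB = c(9, 9), spC = c(2, 2), spD = c(9, 9))
  meta <- tiny_meta(ids = c("a1", "b1"), intervals = c("CIG", "LIG"))
  ov <- topk_overlap(cm, meta, "CIG", "LIG", k = 3)
  expect_equal(ov$overlap, 3)
  # ties (spB, spD at 9) break lexicographically: spB before spD
  expect_identical(ov$rank_table$species_id[1:2], c("spB", "spD"))
  # fewer than k species present warns and uses the available ones
  expect_warning(ov2 <- topk_overlap(cm, meta, "CIG", "LIG", k = 10),
                 regexp = "only 4 species")
  expect_equal(ov2$overlap, 4)
})

test_that("rank overlap recovered from counts equals the printed-rank shortcut", {
  # interval B counts arranged so species ranks are known exactly
  cm <- tibble::tibble(sample_id = c("a1", "b1"),
                       sp1 = c(50, 40), sp2 = c(40, 1), sp3 = c(30, 30),
                       sp4 = c(20, 0), sp5 = c(10, 20))
  meta <- tiny_meta(ids = c("a1", "b1"), intervals = c("CIG", "LG"))
  ov <- topk_overlap(cm, meta, "CIG", "LG", k = 3)
  # B ranks: sp1 = 1, sp3 = 2, sp5 = 3, sp2 = 4, sp4 absent
  expect_equal(ov$overlap, overlap_from_ranks(c(1, 4, 2), k = 3))
  expect_equal(ov$overlap, 2)
})

test_that("preferred depths are abundance-weighted census means", {
  census <- tibble::tibble(species_id = c("spA", "spA", "spB", "spC", "spC"),
                           depth_m = c(2, 5, 5, 2, 8),
                           live = c(2, 1, 4, 1, 1), dead = c(0, 0, 0, 0, 0))
  pd <- preferred_depths(census)
  expect_equal(pd$depth_m[pd$species_id == "spA"], 3)   # (2*2 + 5*1) / 3
  expect_equal(pd$depth_m[pd$species_id == "spB"], 5)
  expect_equal(pd$depth_m[pd$species_id == "spC"], 5)   # symmetric weights
  expect_equal(species_preferred_depth(census, "spA"), 3)
  expect_error(species_preferred_depth(census, "spZ"),
               class = "paleoresil_validation_error")
})

test_that("live-only weighting changes the estimate when dead shells differ", {
  census <- tibble::tibble(species_id = c("spA", "spA"),
                           depth_m = c(2, 10),
                           live = c(4, 0), dead = c(0, 4))
  expect_equal(species_preferred_depth(census, "spA"), 6)
  expect_equal(species_preferred_depth(census, "spA", live_only = TRUE), 2)
})

test_that("sample depths renormalize over census-covered species", {
  depths <- tibble::tibble(species_id = c("spA", "spB"), depth_m = c(2, 6))
  cm <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       spA = c(3, 4, 0), spB = c(1, 0, 0), spX = c(0, 4, 5))
  expect_warning(est <- sample_depths(cm, depths), regexp = "s3")
  expect_equal(est$depth_m[1], 3)        # (3*2 + 1*6) / 4
  expect_equal(est$coverage[1], 1)
  expect_equal(est$depth_m[2], 2)        # spX has no census data
  expect_equal(est$coverage[2], 0.5)
  expect_true(is.na(est$depth_m[3]))
  # estimates stay inside the hull of contributing preferred depths
  ok <- !is.na(est$depth_m)
  expect_true(all(est$depth_m[ok] >= 2 & est$depth_m[ok] <= 6))
})
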