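test_that("mean between-interval dissimilarity matches a hand average of pairs", {
  d <- small_dataset(seed = 2)
  cm <- d$community
  meta <- d$metadata
  got <- mean_between_bc(cm, meta, "LIG", "LG")
  # hand oracle: transform the union, average the 5 x 6 scalar dissimilarities
  sub <- cm[meta$interval[match(cm$sample_id, meta$sample_id)] %in% c("LIG", "LG"), ]
  tm <- community_matrix(transform_composition(sub, "fourth_root"))
  iv <- meta$interval[match(rownames(tm), meta$sample_id)]
  pairs <- expand.grid(i = which(iv == "LIG"), j = which(iv == "LG"))
  oracle <- mean(mapply(function(i, j) bray_curtis(tm[i, ], tm[j, ]),
                        pairs$i, pairs$j))
  expect_equal(got, oracle)
})

test_that("identical single-sample intervals have zero mean dissimilarity", {
  cm <- tibble::tibble(sample_id = c("a1", "b1"), spA = c(4, 4), spB = c(6, 6))
  meta <- tiny_meta(ids = c("a1", "b1"), intervals = c("LIG", "LG"))
  expect_equal(mean_between_bc(cm, meta, "LIG", "LG"), 0)
  expect_error(mean_between_bc(cm, meta, "LIG", "CIG"),
               class = "paleoresil_validation_error")
})

test_that("the permutation test is deterministic given a seed", {
  d <- small_dataset(seed = 6)
  r1 <- bc_permutation_test(d$community, d$metadata, "LIG", "LG",
                            iterations = 30, seed = 99)
  r2 <- bc_permutation_test(d$community, d$metadata, "LIG", "LG",
                            iterations = 30, seed = 99)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value,
               (1 + sum(r1$null_values >= r1$observed - 1e-12)) / 31)
})

test_that("strongly divergent intervals reach the minimal attainable p", {
  d <- small_dataset(seed = 8, scenario = "resilient")
  r <- bc_permutation_test(d$community, d$metadata, "LIG", "LG",
                           iterations = 99, seed = 1)
  expect_equal(r$p_value, 1 / 100)
  expect_gt(r$observed, max(r$null_values))
})

test_that("non-integer counts are rejected with guidance to resolve valves", {
  cm <- tibble::tibble(sample_id = c("a1", "b1"), spA = c(4.5, 4), spB = c(6, 6))
  meta <- tiny_meta(ids = c("a1", "b1"), intervals = c("LIG", "LG"))
  expect_error(bc_permutation_test(cm, meta, "LIG", "LG", iterations = 5),
               regexp = "resolve_valves")
})

test_that("null tables conserve sample sizes and species totals", {
  # reconstruct the null tables the test draws and check both margins
  d <- small_dataset(seed = 13)
  cm <- d$community
  meta <- d$metadata
  sub <- cm[meta$interval[match(cm$sample_id, meta$sample_id)] %in% c("LG", "CIG"), ]
  m <- community_matrix(sub)
  tabs <- withr::with_seed(42, stats::r2dtable(25, rowSums(m), colSums(m)))
  for (tb in tabs) {
    expect_equal(rowSums(tb), unname(rowSums(m)))
    expect_equal(colSums(tb), unname(colSums(m)))
  }
  # and the with-replacement variant still preserves sample sizes
  r <- bc_permutation_test(cm, meta, "LG", "CIG", iterations = 10, seed = 3,
                           replace = TRUE)
  expect_length(r$null_values, 10)
  expect_true(all(r$null_values >= 0 & r$null_values <= 1))
})

test_that("pooling scope 'all' uses every interval's specimens but compares two", {
  d <- small_dataset(seed = 17)
  r <- bc_permutation_test(d$community, d$metadata, "LIG", "CIG",
                           iterations = 20, seed = 2, pool = "all")
  expect_equal(r$n_pairs, 5 * 7)
  expect_length(r$null_values, 20)
})

test_that("the envelope conserves interval grand totals in every iteration", {
  d <- small_dataset(seed = 10)
  env <- pooled_abundance_envelope(d$community, d$metadata, "LIG", "CIG",
                                   iterations = 40, seed = 5)
  expect_true(all(colSums(env$sims_a) == sum(env$observed$count_a)))
  expect_true(all(colSums(env$sims_b) == sum(env$observed$count_b)))
  # determinism and the long tidy layout
  env2 <- pooled_abundance_envelope(d$community, d$metadata, "LIG", "CIG",
                                    iterations = 40, seed = 5)
  expect_identical(env$sims_a, env2$sims_a)
  long <- tidy(env)
  expect_equal(nrow(long), nrow(env$observed) * 40)
})

test_that("a single-species system collapses the envelope to the totals", {
  cm <- tibble::tibble(sample_id = c("a1", "a2", "b1"), spA = c(10, 20, 30))
  meta <- tiny_meta(ids = c("a1", "a2", "b1"), intervals = c("LIG", "LIG", "LG"))
  env <- pooled_abundance_envelope(cm, meta, "LIG", "LG", iterations = 15, seed = 1)
  expect_true(all(env$sims_a == 30))
  expect_true(all(env$sims_b == 30))
})

test_that("envelope rho matches a direct Spearman of the pooled totals", {
  d <- small_dataset(seed = 14)
  env <- pooled_abundance_envelope(d$community, d$metadata, "LIG", "CIG",
                                   iterations = 10, seed = 2)
  ref <- spearman_cor(env$observed$count_a, env$observed$count_b)
  expect_equal(env$rho_observed, ref$rho)
  expect_equal(env$p_rho, ref$p_value)
})

test_that("homogeneous data fall inside their own envelope for most species", {
  spec <- scenario_spec("persistent", S = 15, m = c(LIG = 8, LG = 8, CIG = 8),
                        size_range = c(200, 400), seed = 3)
  d <- generate_dataset(spec)
  env <- pooled_abundance_envelope(d$community, d$metadata, "LIG", "CIG",
                                   iterations = 300, seed = 7)
  cov <- envelope_coverage(env, level = 0.95)
  expect_gte(attr(cov, "fraction_inside"), 0.85)
})

test_that("separated compositions are detected with high power", {
  # two intervals from compositions >= 0.3 apart in BC, moderate samples
  rej <- vapply(1:15, function(i) {
    spec <- scenario_spec("resilient", S = 25, m = c(LIG = 15, LG = 15, CIG = 2),
                          size_range = c(50, 200), seed = 300 + i)
    d <- generate_dataset(spec)
    stopifnot(bray_curtis(spec$theta$LIG, spec$theta$LG) >= 0.3)
    r <- bc_permutation_test(d$community, d$metadata, "LIG", "LG",
                             iterations = 99, seed = 400 + i)
    r$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})
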