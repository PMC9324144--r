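test_that("bray_curtis matches the direct formula on enumerated vectors", {
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(3, 2), c(3, 2)), 0)
  expect_equal(bray_curtis(c(2, 6, 0), c(1, 3, 4)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), class = "paleoresil_validation_error")
})

test_that("bray_curtis is symmetric, bounded, and scale-invariant", {
  set.seed(42)
  for (i in 1:25) {
    x <- rpois(8, 3)
    y <- rpois(8, 3)
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[1] <- 1
    bc <- bray_curtis(x, y)
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    expect_equal(bc, bray_curtis(y, x))
    expect_equal(bc, bray_curtis(3.7 * x, 3.7 * y))
  }
  expect_equal(bray_curtis(c(5, 1), c(5, 1)), 0)
})

test_that("distance_matrix agrees elementwise with scalar bray_curtis", {
  cm <- tiny_community()[1:3, ]
  d <- as.matrix(distance_matrix(cm))
  m <- community_matrix(cm)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d[i, j], bray_curtis(m[i, ], m[j, ]))
  }
  # relabeling invariance: permuting rows permutes the matrix consistently
  perm <- c(3, 1, 2)
  d2 <- as.matrix(distance_matrix(cm[perm, ]))
  expect_equal(unname(d2), unname(d[perm, perm]))
})

test_that("nmds embeds exactly embeddable configurations at ~zero stress", {
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                              dimnames = list(paste0("s", 1:3), paste0("s", 1:3))))
  ord <- suppressWarnings(nmds(d3, k = 2, restarts = 3, seed = 1))
  expect_lt(ord$stress, 0.01)

  set.seed(7)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  d <- stats::dist(pts)
  ord2 <- suppressWarnings(nmds(d, k = 2, restarts = 5, seed = 2))
  expect_lt(ord2$stress, 0.05)
})

test_that("nmds is reproducible under a fixed seed", {
  d <- distance_matrix(transform_composition(small_dataset(3)$community))
  o1 <- suppressWarnings(nmds(d, restarts = 3, seed = 11))
  o2 <- suppressWarnings(nmds(d, restarts = 3, seed = 11))
  expect_identical(o1$points, o2$points)
  expect_identical(o1$stress, o2$stress)
})

test_that("orient_nmds fixes the sign of axis 1 against a covariate", {
  d <- distance_matrix(transform_composition(small_dataset(5)$community))
  ord <- suppressWarnings(nmds(d, restarts = 3, seed = 1))
  cov <- -ord$points$NMDS1
  flipped <- orient_nmds(ord, cov)
  expect_equal(flipped$points$NMDS1, -ord$points$NMDS1)
  kept <- orient_nmds(ord, ord$points$NMDS1)
  expect_equal(kept$points$NMDS1, ord$points$NMDS1)
})

test_that("permanova pseudo-F matches the Gower-trace oracle and adonis2", {
  d <- small_dataset(seed = 21)
  dm <- distance_matrix(transform_composition(d$community))
  groups <- d$metadata$interval
  res <- permanova(dm, groups, permutations = 99, seed = 1)
  expect_equal(res$pseudo_F, oracle_pseudo_f(dm, groups))
  ad <- vegan::adonis2(dm ~ groups, permutations = 2)
  expect_equal(res$pseudo_F, ad$F[1])
  expect_equal(res$df_among, ad$Df[1])
})

test_that("permanova p-value equals exhaustive enumeration on tiny instances", {
  set.seed(5)
  m <- matrix(rpois(6 * 4, 4) + 1, 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("sp", 1:4)))
  cm <- tibble::tibble(sample_id = rownames(m), tibble::as_tibble(m))
  dm <- distance_matrix(cm)
  groups <- c("A", "A", "A", "B", "B", "B")
  res <- permanova(dm, groups, exact = TRUE)
  expect_equal(res$p_value, oracle_permanova_p(dm, groups))
  # random permutations approximate the exact answer
  res_mc <- permanova(dm, groups, permutations = 999, seed = 3)
  expect_lt(abs(res_mc$p_value - res$p_value), 0.12)
})

test_that("perfect group separation yields the smallest attainable p-value", {
  cm <- tibble::tibble(sample_id = paste0("s", 1:6),
                       spA = c(10, 10, 10, 0, 0, 0),
                       spB = c(0, 0, 0, 10, 10, 10))
  dm <- distance_matrix(cm)
  # only label permutations that reproduce the two-block partition reach the
  # observed (infinite) pseudo-F: 2 * 3! * 3! of the 6! arrangements
  res <- permanova(dm, rep(c("A", "B"), each = 3), exact = TRUE)
  expect_equal(res$p_value, 2 * 36 / 720)
  res_mc <- permanova(dm, rep(c("A", "B"), each = 3), permutations = 199, seed = 1)
  expect_lt(abs(res_mc$p_value - res$p_value), 0.06)
  expect_error(permanova(dm, c("A", rep("B", 5))),
               class = "paleoresil_validation_error")
})

test_that("pseudo-F is invariant to sample reordering", {
  d <- small_dataset(seed = 33)
  dm <- distance_matrix(transform_composition(d$community))
  groups <- d$metadata$interval
  perm <- sample(seq_along(groups))
  cm_perm <- transform_composition(d$community)[perm, ]
  f1 <- permanova(dm, groups, permutations = 9, seed = 1)$pseudo_F
  f2 <- permanova(distance_matrix(cm_perm), groups[perm],
                  permutations = 9, seed = 1)$pseudo_F
  expect_equal(f1, f2)
})

test_that("spearman_cor reproduces mid-rank Pearson and the classic limits", {
  expect_equal(spearman_cor(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_cor(1:8, rev(1:8))$rho, -1)
  x <- c(1, 2, 2, 4)
  y <- c(1, 3, 2, 4)
  expect_equal(spearman_cor(x, y)$rho, stats::cor(rank(x), rank(y)))
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)),
               class = "paleoresil_validation_error")
})
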