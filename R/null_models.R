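# The two bespoke randomization procedures used to compare time intervals:
#
# 1. bc_permutation_test(): is the observed mean between-interval
#    Bray-Curtis dissimilarity larger than expected if all specimens came
#    from one homogeneous system? Specimens are pooled and randomly
#    reassigned (without replacement) into synthetic samples that keep the
#    exact per-sample sizes and interval labels of the real data.
#
# 2. pooled_abundance_envelope(): if samples of both intervals were drawn
#    from the pooled species-abundance distribution, where should each
#    species' per-interval total abundances fall? Multinomial draws per
#    sample build a two-dimensional null cloud per species.

#' Mean between-interval Bray-Curtis dissimilarity
#'
#' Applies the transform to the union of the two intervals' samples, then
#' averages Bray-Curtis over all between-interval sample pairs.
#'
#' @param cm A filtered community tibble (integer counts).
#' @param meta Sample metadata with `interval`.
#' @param a,b Interval labels to compare.
#' @param transform_kind Transform applied before the dissimilarity
#'   (default `"fourth_root"`, mirroring the ordination matrix).
#' @return The mean dissimilarity (scalar).
#' @export
mean_between_bc <- function(cm, meta, a, b, transform_kind = "fourth_root") {
  u <- interval_universe(cm, meta, a, b)
  tm <- transform_matrix(u$m / rowSums(u$m), transform_kind)
  mean_between_kernel(tm, which(u$group == 1L), which(u$group == 2L))
}

#' Permutation test of between-interval dissimilarity
#'
#' The observed statistic is [mean_between_bc()]. Each iteration pools all
#' specimens of the compared samples as a multiset of species identities,
#' randomly reassigns them without replacement into synthetic samples with
#' exactly the original per-sample sizes and interval labels, re-applies
#' the transform, and recomputes the mean between-interval dissimilarity.
#' The default one-sided p-value (tail `"greater"`) asks whether the
#' observed assemblages are more dissimilar than the homogeneous-system
#' null, using the (b+1)/(B+1) rule.
#'
#' @inheritParams mean_between_bc
#' @param iterations Number of randomizations (default 1000, so the
#'   smallest reportable p is about .001).
#' @param seed Integer seed; identical seeds give identical results.
#' @param tail `"greater"` (default), `"less"`, or `"two-sided"`.
#' @param pool `"pair"` pools specimens over the two compared intervals
#'   (default); `"all"` pools over every interval in `meta` while still
#'   measuring dissimilarity between `a` and `b`.
#' @param replace Reassign by resampling with replacement instead of
#'   permuting the specimen multiset (sensitivity variant; the default
#'   permutation conserves per-species totals exactly in every iteration).
#' @return An object of class `paleo_nulltest`: `observed`, `null_values`,
#'   `p_value`, `iterations`, `seed`, `tail`, plus bookkeeping fields.
#' @export
bc_permutation_test <- function(cm, meta, a, b, iterations = 1000, seed = 1,
                                transform_kind = "fourth_root",
                                tail = c("greater", "less", "two-sided"),
                                pool = c("pair", "all"), replace = FALSE) {
  tail <- match.arg(tail)
  pool <- match.arg(pool)
  stopifnot(iterations >= 1)
  observed <- mean_between_bc(cm, meta, a, b, transform_kind)

  universe_ints <- if (pool == "pair") c(a, b) else unique(validate_metadata(meta)$interval)
  u <- interval_universe(cm, meta, universe_ints[1], universe_ints[2],
                         extra = setdiff(universe_ints, c(universe_ints[1:2])),
                         focus = c(a, b))
  assert_integer_counts(u$m)
  m <- round(u$m)
  S <- ncol(m)
  sizes <- rowSums(m)
  sp_totals <- colSums(m)
  probs <- sp_totals / sum(sp_totals)
  ia <- which(u$group == 1L)
  ib <- which(u$group == 2L)

  # Random reassignment of the pooled specimen multiset into samples of
  # fixed size is exactly the multivariate hypergeometric distribution of
  # contingency tables with both margins fixed, which r2dtable() samples
  # directly (Patefield's algorithm); the with-replacement variant redraws
  # every sample as a multinomial from the pooled composition.
  null_values <- withr::with_seed(seed, {
    if (replace) {
      vapply(seq_len(iterations), function(i) {
        cnt <- t(vapply(sizes, function(s) rmultinom(1, s, probs)[, 1],
                        numeric(S)))
        tm <- transform_matrix(cnt / sizes, transform_kind)
        mean_between_kernel(tm, ia, ib)
      }, numeric(1))
    } else {
      tables <- stats::r2dtable(iterations, sizes, sp_totals)
      vapply(tables, function(cnt) {
        tm <- transform_matrix(cnt / sizes, transform_kind)
        mean_between_kernel(tm, ia, ib)
      }, numeric(1))
    }
  })

  eps <- 1e-12
  p_greater <- (1 + sum(null_values >= observed - eps)) / (iterations + 1)
  p_less <- (1 + sum(null_values <= observed + eps)) / (iterations + 1)
  p <- switch(tail, greater = p_greater, less = p_less,
              `two-sided` = min(1, 2 * min(p_greater, p_less)))
  structure(
    list(observed = observed, null_values = null_values, p_value = p,
         iterations = iterations, seed = seed, tail = tail,
         intervals = c(a, b), n_pairs = u$n_pairs, transform = transform_kind,
         pool = pool, replace = replace),
    class = "paleo_nulltest")
}

#' @exportS3Method generics::tidy
tidy.paleo_nulltest <- function(x, ...) {
  tibble(iteration = seq_along(x$null_values), mean_bc = x$null_values)
}

#' @exportS3Method generics::glance
glance.paleo_nulltest <- function(x, ...) {
  tibble(comparison = paste(x$intervals, collapse = "-"),
         observed = x$observed, p_value = x$p_value,
         null_mean = mean(x$null_values), iterations = x$iterations,
         n_pairs = x$n_pairs, tail = x$tail, seed = x$seed)
}

#' @export
print.paleo_nulltest <- function(x, ...) {
  cat("Between-interval BC permutation test (", paste(x$intervals, collapse = " vs "),
      "): observed mean BC = ", signif(x$observed, 4),
      ", null mean = ", signif(mean(x$null_values), 4),
      ", p = ", signif(x$p_value, 4), " (", x$tail, ", ",
      x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Pooled-abundance multinomial envelope for per-species totals
#'
#' Pools the two intervals' specimens into one species-abundance
#' distribution and repeatedly redraws every original sample as a
#' multinomial of its observed size from that pooled composition. Each
#' iteration yields one simulated (interval-a total, interval-b total) pair
#' per species — the null cloud against which observed per-species totals
#' are compared. The observed Spearman correlation between the two
#' intervals' per-species totals (all species in the union, zeros
#' included) is attached.
#'
#' @inheritParams bc_permutation_test
#' @return An object of class `paleo_envelope`: `observed` (tibble of
#'   `species_id`, `count_a`, `count_b`), simulated totals (`sims_a`,
#'   `sims_b`, species-by-iteration matrices), `rho_observed`, `p_rho`,
#'   `iterations`, `seed`, `intervals`.
#' @export
pooled_abundance_envelope <- function(cm, meta, a, b, iterations = 1000, seed = 1) {
  stopifnot(iterations >= 1)
  u <- interval_universe(cm, meta, a, b)
  assert_integer_counts(u$m)
  m <- round(u$m)
  present <- colSums(m) > 0
  m <- m[, present, drop = FALSE]
  S <- ncol(m)
  pi_pool <- colSums(m) / sum(m)
  in_a <- u$group == 1L
  tot_a <- colSums(m[in_a, , drop = FALSE])
  tot_b <- colSums(m[!in_a, , drop = FALSE])

  sims <- withr::with_seed(seed, {
    sims_a <- matrix(0, S, iterations)
    sims_b <- matrix(0, S, iterations)
    for (i in seq_len(nrow(m))) {
      draw <- rmultinom(iterations, size = sum(m[i, ]), prob = pi_pool)
      if (in_a[i]) sims_a <- sims_a + draw else sims_b <- sims_b + draw
    }
    list(a = sims_a, b = sims_b)
  })
  rownames(sims$a) <- rownames(sims$b) <- colnames(m)

  # degenerate systems (fewer than three species, or tied ranks throughout)
  # have no defined rank correlation; report NA rather than fail
  rho <- tryCatch(spearman_cor(tot_a, tot_b),
                  error = function(e) tibble(rho = NA_real_, p_value = NA_real_))
  structure(
    list(observed = tibble(species_id = colnames(m), count_a = unname(tot_a),
                           count_b = unname(tot_b)),
         sims_a = sims$a, sims_b = sims$b,
         rho_observed = rho$rho, p_rho = rho$p_value,
         iterations = iterations, seed = seed, intervals = c(a, b)),
    class = "paleo_envelope")
}

#' @exportS3Method generics::tidy
tidy.paleo_envelope <- function(x, ...) {
  xa <- as.vector(x$sims_a)
  yb <- as.vector(x$sims_b)
  tibble(species_id = rep(rownames(x$sims_a), times = x$iterations),
         iteration = rep(seq_len(x$iterations), each = nrow(x$sims_a)),
         x = xa, y = yb)
}

#' @exportS3Method generics::glance
glance.paleo_envelope <- function(x, ...) {
  tibble(comparison = paste(x$intervals, collapse = "-"),
         rho = x$rho_observed, p_value = x$p_rho,
         n_species = nrow(x$observed), iterations = x$iterations,
         seed = x$seed)
}

#' @export
print.paleo_envelope <- function(x, ...) {
  cat("Pooled-abundance envelope (", paste(x$intervals, collapse = " vs "),
      "): ", nrow(x$observed), " species, rho = ", signif(x$rho_observed, 3),
      ", p = ", signif(x$p_rho, 4), " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Fraction of species inside the central envelope
#'
#' For each species, checks whether the observed (a, b) total lies within
#' the central `level` quantile box of its simulated pairs.
#'
#' @param x A `paleo_envelope`.
#' @param level Central coverage level (default 0.95).
#' @return A tibble with per-species `inside` plus the overall fraction as
#'   attribute `fraction_inside`.
#' @export
envelope_coverage <- function(x, level = 0.95) {
  stopifnot(inherits(x, "paleo_envelope"))
  lo <- (1 - level) / 2
  qa <- t(apply(x$sims_a, 1, quantile, probs = c(lo, 1 - lo)))
  qb <- t(apply(x$sims_b, 1, quantile, probs = c(lo, 1 - lo)))
  inside <- x$observed$count_a >= qa[, 1] & x$observed$count_a <= qa[, 2] &
    x$observed$count_b >= qb[, 1] & x$observed$count_b <= qb[, 2]
  out <- tibble(species_id = x$observed$species_id, inside = inside)
  attr(out, "fraction_inside") <- mean(inside)
  out
}

# -- internal -----------------------------------------------------------------

# Mean Bray-Curtis over all between-group row pairs of a transformed
# matrix, via the identity BC(x, y) = sum|x - y| / (sum x + sum y).
# Loops over the smaller group with the other group held as a transposed
# matrix so each step is one vectorized column operation.
mean_between_kernel <- function(tm, ia, ib) {
  if (length(ib) < length(ia)) {
    tmp <- ia
    ia <- ib
    ib <- tmp
  }
  tB <- t(tm[ib, , drop = FALSE])
  sB <- colSums(tB)
  acc <- 0
  for (i in ia) {
    x <- tm[i, ]
    acc <- acc + sum(colSums(abs(tB - x)) / (sum(x) + sB))
  }
  acc / (length(ia) * length(ib))
}

# Assemble the sample universe for a pairwise interval comparison: count
# matrix (original sample order), group indicator (1 = first focus
# interval, 2 = second, 0 = pooled-only extras), and the dist-vector
# positions of all between-focus pairs.
interval_universe <- function(cm, meta, a, b, extra = character(), focus = c(a, b)) {
  cm <- as_community(cm)
  meta <- validate_metadata(meta, cm)
  ints <- unique(c(a, b, extra))
  keep_ids <- cm$sample_id[cm$sample_id %in%
                             meta$sample_id[meta$interval %in% ints]]
  for (lev in focus) {
    n_lev <- sum(meta$interval[match(keep_ids, meta$sample_id)] == lev)
    if (n_lev < 1) {
      abort(paste0("interval '", lev, "' has no retained samples"),
            class = "paleoresil_validation_error")
    }
  }
  m <- community_matrix(cm[match(keep_ids, cm$sample_id), ])
  if (any(rowSums(m) <= 0)) {
    abort("sample with zero specimens in comparison universe",
          class = "paleoresil_validation_error")
  }
  iv <- meta$interval[match(keep_ids, meta$sample_id)]
  group <- ifelse(iv == focus[1], 1L, ifelse(iv == focus[2], 2L, 0L))
  n <- length(keep_ids)
  ia <- which(group == 1L)
  ib <- which(group == 2L)
  pairs <- expand.grid(i = ia, j = ib)
  lo <- pmin(pairs$i, pairs$j)
  hi <- pmax(pairs$i, pairs$j)
  between_idx <- n * (lo - 1) - lo * (lo - 1) / 2 + (hi - lo)
  list(m = m, group = group, between_idx = between_idx,
       n_pairs = length(between_idx))
}
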