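# Distance, ordination, group testing, and rank correlation.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC = 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`: 0 for identical
#' composition, 1 for disjoint support. Scale-invariant under common
#' rescaling of both vectors.
#'
#' @param x,y Equal-length non-negative numeric vectors, not both all-zero.
#' @return A number in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 6, 0), c(1, 3, 4)) # 0.5
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  s <- sum(x) + sum(y)
  if (s == 0) {
    abort("Bray-Curtis undefined for two all-zero vectors",
          class = "paleoresil_validation_error")
  }
  1 - 2 * sum(pmin(x, y)) / s
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Computes all pairwise dissimilarities over the rows of a (transformed)
#' community tibble via [vegan::vegdist()]; agrees elementwise with
#' [bray_curtis()].
#'
#' @param pm A community tibble or `processed_matrix`.
#' @return A `dist` object labelled by sample id.
#' @export
distance_matrix <- function(pm) {
  m <- community_matrix(pm)
  if (nrow(m) < 2) abort("need at least two samples", class = "paleoresil_validation_error")
  if (any(rowSums(m) == 0)) {
    abort("all-zero sample row; Bray-Curtis undefined", class = "paleoresil_validation_error")
  }
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Embeds samples in `k` dimensions minimising Kruskal stress-1, taking the
#' best of `restarts` starts (classical metric scaling plus random starts,
#' via [vegan::metaMDS()]). Coordinates are centred and rotated to
#' principal axes; the solution is reproducible given `seed`.
#'
#' @param dm A `dist` of Bray-Curtis dissimilarities.
#' @param k Number of dimensions (default 2).
#' @param restarts Number of random starts (default 20).
#' @param seed Integer seed governing all starts.
#' @param max_iter,tol Convergence controls passed to the optimiser.
#' @return An object of class `paleo_nmds`: list with `points` (tibble of
#'   `sample_id` and `NMDS1..NMDSk`), `stress` (in \[0, 1\]), `k`,
#'   `restarts`, `seed`, `converged`.
#' @export
nmds <- function(dm, k = 2, restarts = 20, seed = 1, max_iter = 500, tol = 1e-7) {
  stopifnot(inherits(dm, "dist"), k >= 1, restarts >= 1)
  ord <- withr::with_seed(seed,
    vegan::metaMDS(dm, k = k, try = restarts, trymax = restarts,
                   maxit = max_iter, sfgrmin = tol, trace = 0,
                   autotransform = FALSE, wascores = FALSE))
  if (!isTRUE(ord$converged) && is.numeric(ord$converged) && ord$converged == 0) {
    warn("NMDS did not converge within the allotted restarts; best solution returned")
  }
  pts <- ord$points
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(
    list(points = tibble(sample_id = rownames(as.matrix(dm)), as_tibble(pts)),
         stress = ord$stress, k = k, restarts = restarts, seed = seed,
         converged = isTRUE(ord$converged) || (is.numeric(ord$converged) && ord$converged > 0),
         engine = ord),
    class = "paleo_nmds")
}

#' Fix the sign of NMDS1 against a covariate
#'
#' NMDS axis signs are arbitrary; by convention the first axis is flipped,
#' if needed, so it correlates positively with a chosen covariate (the
#' warm-water Mediterranean-Lusitanian specimen fraction in the headline
#' analysis).
#'
#' @param ord A `paleo_nmds` object.
#' @param covariate Numeric vector aligned with `ord$points`.
#' @return `ord` with NMDS1 possibly negated.
#' @export
orient_nmds <- function(ord, covariate) {
  stopifnot(inherits(ord, "paleo_nmds"),
            length(covariate) == nrow(ord$points))
  r <- suppressWarnings(stats::cor(ord$points$NMDS1, covariate, method = "spearman"))
  if (is.finite(r) && r < 0) ord$points$NMDS1 <- -ord$points$NMDS1
  ord
}

#' @exportS3Method generics::tidy
tidy.paleo_nmds <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.paleo_nmds <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, restarts = x$restarts,
         converged = x$converged, seed = x$seed)
}

#' @export
print.paleo_nmds <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "samples, k =", x$k,
      "| stress-1 =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the squared dissimilarities into among- and within-group
#' components: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `pseudo-F = ((SS_total - SS_within)/(g-1)) / (SS_within/(N-g))`.
#' The p-value comes from random label permutations with the (b+1)/(B+1)
#' rule, or from exhaustive enumeration of all label arrangements when
#' `exact = TRUE` (feasible for small N).
#'
#' @param dm A `dist` object.
#' @param groups Group labels aligned with the rows of `dm`; at least two
#'   groups with two samples each.
#' @param permutations Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param exact Enumerate all `N!` label permutations instead of sampling.
#' @return An object of class `paleo_permanova` with `pseudo_F`, `p_value`,
#'   `df_among`, `df_within`, `permutations`, `seed`.
#' @export
permanova <- function(dm, groups, permutations = 999, seed = 1, exact = FALSE) {
  stopifnot(inherits(dm, "dist"))
  groups <- as.character(groups)
  n <- attr(dm, "Size")
  stopifnot(length(groups) == n)
  if (length(unique(groups)) < 2 || any(table(groups) < 2)) {
    abort("need at least two groups with at least two samples each",
          class = "paleoresil_validation_error")
  }
  d2 <- as.matrix(dm)^2
  f_obs <- permanova_f(d2, groups)
  g <- length(unique(groups))
  if (exact) {
    perms <- all_permutations(n)
    f_null <- vapply(seq_len(nrow(perms)),
                     function(i) permanova_f(d2, groups[perms[i, ]]), numeric(1))
    p <- mean(f_null >= f_obs - 1e-12)
    B <- nrow(perms)
  } else {
    f_null <- withr::with_seed(seed, vapply(seq_len(permutations), function(i) {
      permanova_f(d2, groups[sample.int(n)])
    }, numeric(1)))
    p <- (1 + sum(f_null >= f_obs - 1e-12)) / (permutations + 1)
    B <- permutations
  }
  structure(
    list(pseudo_F = f_obs, p_value = p, df_among = g - 1, df_within = n - g,
         permutations = B, seed = seed, exact = exact, null_values = f_null),
    class = "paleo_permanova")
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- unique(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(g, function(lev) {
    idx <- which(groups == lev)
    sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
  }, numeric(1)))
  ((ss_total - ss_within) / (length(g) - 1)) / (ss_within / (n - length(g)))
}

# All permutations of 1..n as a matrix (n! rows); n is expected small.
all_permutations <- function(n) {
  if (n > 9) abort("exhaustive enumeration limited to n <= 9")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @exportS3Method generics::tidy
tidy.paleo_permanova <- function(x, ...) {
  tibble(term = c("among groups", "within groups"),
         df = c(x$df_among, x$df_within),
         pseudo_F = c(x$pseudo_F, NA_real_),
         p_value = c(x$p_value, NA_real_))
}

#' @exportS3Method generics::glance
glance.paleo_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, p_value = x$p_value,
         df_among = x$df_among, df_within = x$df_within,
         permutations = x$permutations)
}

#' @export
print.paleo_permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", signif(x$pseudo_F, 4),
      "on", x$df_among, "and", x$df_within, "df; p =", signif(x$p_value, 4),
      if (x$exact) "(exhaustive)" else sprintf("(%d permutations)", x$permutations), "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the p-value
#' uses the exact null distribution for small untied samples and the
#' t-approximation otherwise, via [stats::cor.test()].
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    abort("zero variance in ranks; Spearman undefined",
          class = "paleoresil_validation_error")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
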