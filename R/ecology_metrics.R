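# Rarefied richness, dominance, biogeographic profiles, top-k rank
# overlap, and abundance-weighted bathymetric estimation.

#' Rarefied (sample-standardized) species richness
#'
#' Analytic hypergeometric expectation of the number of species in a
#' random subsample of `n` specimens drawn without replacement:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))` with
#' `N = sum(counts)`.
#'
#' @param counts Non-negative species count vector.
#' @param n Subsample size, `1 <= n <= sum(counts)`.
#' @return Expected species count (scalar).
#' @examples
#' rarefied_richness(c(3, 1), 2) # 1.5
#' @export
rarefied_richness <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (length(counts) == 0) abort("empty sample", class = "paleoresil_validation_error")
  if (n < 1 || n > N) {
    abort(paste0("subsample size n = ", n, " outside [1, ", N, "]"),
          class = "paleoresil_validation_error")
  }
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Rarefied richness for every sample of a community tibble
#'
#' Samples with fewer than `n` specimens are excluded from that
#' rarefaction level (returned as `NA` and reported in a message) rather
#' than extrapolated.
#'
#' @param cm A community tibble.
#' @param n Subsample size(s), e.g. `c(25, 60)`.
#' @return A tibble with `sample_id`, `n_specimens`, and one `rarefied_<n>`
#'   column per level.
#' @export
rarefy_samples <- function(cm, n = c(25, 60)) {
  m <- community_matrix(cm)
  tot <- rowSums(m)
  out <- tibble(sample_id = rownames(m), n_specimens = unname(tot))
  for (lev in n) {
    vals <- rep(NA_real_, nrow(m))
    ok <- tot >= lev
    vals[ok] <- apply(m[ok, , drop = FALSE], 1, rarefied_richness, n = lev)
    if (any(!ok)) {
      inform(paste0(sum(!ok), " sample(s) below ", lev,
                    " specimens excluded from rarefaction to ", lev))
    }
    out[[paste0("rarefied_", lev)]] <- vals
  }
  out
}

#' Dominance: share of the most abundant species
#'
#' @param counts Non-negative species count vector with positive total.
#' @return `max(counts) / sum(counts)`.
#' @export
dominance <- function(counts) {
  if (length(counts) == 0 || sum(counts) <= 0) {
    abort("dominance undefined for an empty sample", class = "paleoresil_validation_error")
  }
  max(counts) / sum(counts)
}

#' Biogeographic-affinity profile of an interval
#'
#' Pools specimens over the interval's samples and reports the fraction
#' belonging to each biogeographic class (`MED/LUS`, `WAF`, `BOR`, `COS`);
#' the classes proxy the thermal affinity of the fauna.
#'
#' @param cm A community tibble.
#' @param meta Sample metadata.
#' @param traits Species trait table covering every species in `cm`.
#' @param interval Interval label to pool (or `NULL` for all samples).
#' @return A tibble with `interval`, `biogeo_class`, `proportion`
#'   (proportions sum to one over the four classes).
#' @export
biogeo_profile <- function(cm, meta, traits, interval = NULL) {
  cm <- as_community(cm)
  traits <- validate_traits(traits)
  if (!is.null(interval)) {
    meta <- validate_metadata(meta, cm)
    ids <- meta$sample_id[meta$interval == interval]
    cm <- cm[cm$sample_id %in% ids, ]
    if (nrow(cm) == 0) {
      abort(paste0("no samples in interval '", interval, "'"),
            class = "paleoresil_validation_error")
    }
  } else {
    interval <- "all"
  }
  m <- community_matrix(cm)
  sp <- colnames(m)
  missing <- setdiff(sp[colSums(m) > 0], traits$species_id)
  if (length(missing)) {
    abort(paste0("species without trait rows: ", paste(missing, collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  cls <- traits$biogeo_class[match(sp, traits$species_id)]
  tot <- tapply(colSums(m), factor(cls, levels = BIOGEO_LEVELS), sum, default = 0)
  tibble(interval = interval, biogeo_class = BIOGEO_LEVELS,
         proportion = as.numeric(tot / sum(tot)))
}

#' Fraction of warm-water specimens per sample
#'
#' Per-sample relative abundance of specimens whose species belong to the
#' given biogeographic classes (default the warm-water Mediterranean-
#' Lusitanian plus West African group used as an NMDS covariate).
#'
#' @inheritParams biogeo_profile
#' @param classes Character vector of classes to pool.
#' @return A tibble with `sample_id` and `fraction`.
#' @export
biogeo_fraction <- function(cm, traits, classes = c("MED/LUS", "WAF")) {
  m <- community_matrix(cm)
  traits <- validate_traits(traits)
  cls <- traits$biogeo_class[match(colnames(m), traits$species_id)]
  in_set <- !is.na(cls) & cls %in% classes
  tibble(sample_id = rownames(m),
         fraction = unname(rowSums(m[, in_set, drop = FALSE]) / rowSums(m)))
}

#' Top-k rank overlap between two intervals
#'
#' Species are ranked by pooled specimen abundance within each interval
#' (descending, ties broken by species id). The overlap is the number of
#' interval-`a` top-k species that also rank in interval-`b`'s top k. The
#' rank table lists each top-k(`a`) species with its rank in both
#' intervals (`NA` = absent from `b`).
#'
#' @inheritParams mean_between_bc
#' @param k Number of top species (default 10).
#' @return An object of class `paleo_rank_overlap`: list with `overlap`,
#'   `k`, `intervals`, and `rank_table`.
#' @export
topk_overlap <- function(cm, meta, a, b, k = 10) {
  stopifnot(k >= 1)
  cm <- as_community(cm)
  meta <- validate_metadata(meta, cm)
  pooled <- function(interval) {
    ids <- meta$sample_id[meta$interval == interval]
    m <- community_matrix(cm[cm$sample_id %in% ids, , drop = FALSE])
    colSums(m)
  }
  tot_a <- pooled(a)
  tot_b <- pooled(b)
  rank_in <- function(tot) {
    present <- tot[tot > 0]
    ord <- order(-present, names(present))
    setNames(seq_along(ord), names(present)[ord])
  }
  ra <- rank_in(tot_a)
  rb <- rank_in(tot_b)
  k_eff <- min(k, length(ra))
  if (k_eff < k) {
    warn(paste0("only ", k_eff, " species with nonzero abundance in '", a, "'"))
  }
  top_a <- names(ra)[seq_len(k_eff)]
  tab <- tibble(species_id = top_a,
                rank_a = unname(ra[top_a]),
                rank_b = unname(rb[top_a]))
  overlap <- sum(!is.na(tab$rank_b) & tab$rank_b <= k)
  structure(list(overlap = overlap, k = k, intervals = c(a, b), rank_table = tab),
            class = "paleo_rank_overlap")
}

#' @exportS3Method generics::tidy
tidy.paleo_rank_overlap <- function(x, ...) x$rank_table

#' @export
print.paleo_rank_overlap <- function(x, ...) {
  cat("Top-", x$k, " overlap ", x$intervals[1], " vs ", x$intervals[2], ": ",
      x$overlap, " shared species\n", sep = "")
  invisible(x)
}

#' Overlap count from a printed rank table
#'
#' Given the ranks that one interval's top-k species attain in another
#' interval (with `NA` for species absent there), counts how many also
#' fall in the other interval's top k — the overlap statistic implied by a
#' published rank table.
#'
#' @param ranks_in_b Integer ranks (or `NA`) of interval-a's top-k species
#'   within interval b.
#' @param k Top-k threshold (defaults to `length(ranks_in_b)`).
#' @return Integer overlap count.
#' @examples
#' overlap_from_ranks(c(1, 5, 7, 2, 8, 16, 6, 10, 14, 32)) # 7
#' @export
overlap_from_ranks <- function(ranks_in_b, k = length(ranks_in_b)) {
  sum(!is.na(ranks_in_b) & ranks_in_b <= k)
}

#' Preferred water depth per species
#'
#' Abundance-weighted average depth over a species' census records, with
#' abundance = live + dead individuals (set `live_only = TRUE` to weight
#' by living individuals alone).
#'
#' @param census A validated bathymetric census tibble.
#' @param live_only Use only live abundances as weights.
#' @return A tibble with `species_id`, `depth_m`, `n_records`.
#' @examples
#' census <- tibble::tibble(species_id = "spA", depth_m = c(2, 5),
#'                          live = c(2, 1), dead = c(0, 0))
#' preferred_depths(census) # 3 m
#' @export
preferred_depths <- function(census, live_only = FALSE) {
  census <- validate_census(census)
  w <- if (live_only) census$live else census$live + census$dead
  keep <- w > 0
  census <- census[keep, ]
  w <- w[keep]
  if (nrow(census) == 0) {
    abort("no census records with positive abundance",
          class = "paleoresil_validation_error")
  }
  census |>
    mutate(w = w) |>
    group_by(species_id = factor(.data$species_id, levels = unique(.data$species_id))) |>
    summarise(depth_m = sum(.data$w * .data$depth_m) / sum(.data$w),
              n_records = dplyr::n(), .groups = "drop") |>
    mutate(species_id = as.character(.data$species_id))
}

#' @rdname preferred_depths
#' @param species_id A single species to look up.
#' @return `species_preferred_depth()`: the preferred depth in meters.
#' @export
species_preferred_depth <- function(census, species_id, live_only = FALSE) {
  pd <- preferred_depths(census, live_only = live_only)
  hit <- pd$depth_m[pd$species_id == species_id]
  if (length(hit) == 0) {
    abort(paste0("no census records for species '", species_id, "'"),
          class = "paleoresil_validation_error")
  }
  hit
}

#' Abundance-weighted water-depth estimate per sample
#'
#' Each sample's depth is the mean of its species' preferred depths
#' weighted by specimen abundance. Species without census support are
#' excluded and the weights renormalized; `coverage` reports the fraction
#' of specimens that contributed. Samples with zero coverage get `NA` with
#' a warning (an error if no sample has coverage).
#'
#' @param cm A community tibble.
#' @param depths A tibble from [preferred_depths()] (or any table with
#'   `species_id`, `depth_m`).
#' @return A tibble with `sample_id`, `depth_m`, `coverage`.
#' @export
sample_depths <- function(cm, depths) {
  m <- community_matrix(cm)
  d <- depths$depth_m[match(colnames(m), depths$species_id)]
  covered <- !is.na(d)
  if (!any(covered)) {
    abort("no species in the community has census depth data",
          class = "paleoresil_validation_error")
  }
  wsum <- rowSums(m[, covered, drop = FALSE])
  est <- as.vector(m[, covered, drop = FALSE] %*% d[covered]) / wsum
  cov <- wsum / rowSums(m)
  if (any(wsum == 0)) {
    warn(paste0("no depth estimate (zero coverage) for sample(s): ",
                paste(rownames(m)[wsum == 0], collapse = ", ")))
    est[wsum == 0] <- NA_real_
  }
  if (all(is.na(est))) {
    abort("no sample has census-covered specimens",
          class = "paleoresil_validation_error")
  }
  tibble(sample_id = rownames(m), depth_m = unname(est), coverage = unname(cov))
}
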