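# Data-selection and transformation rules producing the analysis-ready
# matrix: valve resolution, habitat exclusion, minimum-sample-size filter,
# rare-species removal, and relative-abundance transforms.

#' Resolve isolated valves to individuals
#'
#' Disarticulated bivalves are counted as single valves in the field; two
#' valves represent one individual. Valve counts are divided by two and
#' rounded up per (sample, species) cell, so a single valve still counts as
#' one individual. Whole-individual counts pass through unchanged.
#'
#' @param occ A long occurrence tibble with columns `sample_id`,
#'   `species_id`, `count` and `element` (`"whole"` or `"valve"`; missing
#'   element is treated as `"whole"`).
#' @return A long occurrence tibble with integer `count` summed per
#'   (sample, species); the `element` column is consumed.
#' @examples
#' occ <- tibble::tibble(sample_id = "s1", species_id = "spA",
#'                       count = 5, element = "valve")
#' resolve_valves(occ) # 3 individuals
#' @export
resolve_valves <- function(occ) {
  occ <- as_tibble(occ)
  if (!"element" %in% names(occ)) occ$element <- "whole"
  occ$element[is.na(occ$element)] <- "whole"
  bad <- setdiff(unique(occ$element), c("whole", "valve"))
  if (length(bad)) {
    abort(paste0("unknown element label(s): ", paste(bad, collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  occ$count <- parse_count_column(occ$count, "count")
  occ$count <- ifelse(occ$element == "valve", ceiling(occ$count / 2), occ$count)
  if (max(abs(occ$count - round(occ$count))) > 1e-9) {
    abort("whole-individual counts must be integers", class = "paleoresil_validation_error")
  }
  # factor levels pin aggregation to first-appearance order, which the
  # readers preserve so that seeded permutations reproduce exactly
  occ |>
    mutate(sample_id = factor(.data$sample_id, levels = unique(.data$sample_id)),
           species_id = factor(.data$species_id, levels = unique(.data$species_id))) |>
    group_by(.data$sample_id, .data$species_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(sample_id = as.character(.data$sample_id),
           species_id = as.character(.data$species_id))
}

#' Apply habitat and sample-size selection rules
#'
#' Non-marine (freshwater/terrestrial) species are removed first; sample
#' totals are then evaluated on the remaining marine specimens and samples
#' with fewer than `min_n` specimens are dropped ("at least `min_n`" is
#' inclusive). The removal order is fixed and recorded in the provenance
#' attribute.
#'
#' @param cm A community tibble.
#' @param meta Optional sample metadata (validated against `cm` if given).
#' @param traits A species trait table with `habitat`; species absent from
#'   the table are assumed marine.
#' @param min_n Minimum number of (marine) specimens per retained sample;
#'   default 25, with 60 as the conservative sensitivity setting.
#' @return The filtered community tibble with attribute `provenance`, a
#'   list recording dropped species and samples and the rule responsible.
#' @export
filter_samples <- function(cm, meta = NULL, traits = NULL, min_n = 25) {
  stopifnot(min_n >= 1)
  cm <- as_community(cm)
  if (!is.null(meta)) validate_metadata(meta, cm)
  dropped_species <- character()
  if (!is.null(traits)) {
    traits <- validate_traits(traits)
    nonmarine <- traits$species_id[traits$habitat != "marine"]
    dropped_species <- intersect(names(cm)[-1], nonmarine)
    if (length(dropped_species)) cm <- cm[, !names(cm) %in% dropped_species]
  }
  tot <- rowSums(community_matrix(cm))
  keep <- tot >= min_n
  if (!any(keep)) {
    abort("no samples survive filtering", class = "paleoresil_validation_error")
  }
  dropped_samples <- cm$sample_id[!keep]
  out <- cm[keep, ]
  attr(out, "provenance") <- list(
    habitat_excluded_species = dropped_species,
    min_n = min_n,
    min_n_evaluated_on = "marine specimens after habitat exclusion",
    dropped_samples = dropped_samples
  )
  out
}

#' Remove species occurring in a single sample
#'
#' Species present (count > 0) in at most one retained sample are removed
#' in a single pass; sample-size thresholds are deliberately not re-applied
#' afterwards, so the retained-sample set is unchanged.
#'
#' @param cm A community tibble.
#' @return The community tibble without single-occurrence species; dropped
#'   species are appended to the `provenance` attribute.
#' @export
drop_rare_species <- function(cm) {
  prov <- attr(cm, "provenance") %||% list()
  cm <- as_community(cm)
  m <- community_matrix(cm)
  occ <- colSums(m > 0)
  rare <- names(occ)[occ <= 1]
  out <- cm[, !names(cm) %in% rare]
  prov$rare_species_removed <- rare
  attr(out, "provenance") <- prov
  out
}

#' Convert counts to relative abundances and transform
#'
#' Each retained sample's counts are converted to relative abundances
#' (summing to one) and then transformed: `fourth_root` takes x^(1/4) to
#' damp hyperabundant taxa (the headline setting), `log1p` takes ln(1+x),
#' `wisconsin` applies double relativization (each species divided by its
#' maximum, then each sample by its total), and `none` leaves relative
#' abundances untouched. `log1p` and `wisconsin` are sensitivity options.
#'
#' @param cm A community tibble (already filtered).
#' @param kind One of `"fourth_root"`, `"log1p"`, `"wisconsin"`, `"none"`.
#' @return A community-shaped tibble of transformed values, class
#'   `processed_matrix`, with attributes `transform` and `provenance`.
#' @examples
#' cm <- tibble::tibble(sample_id = "s1", spA = 1, spB = 3)
#' transform_composition(cm, "fourth_root") # 0.25^0.25 = 1/sqrt(2), 0.75^0.25
#' @export
transform_composition <- function(cm, kind = c("fourth_root", "log1p", "wisconsin", "none")) {
  kind <- match.arg(kind)
  prov <- attr(cm, "provenance") %||% list()
  m <- community_matrix(cm)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort("cannot form relative abundances for empty sample(s)",
          class = "paleoresil_validation_error")
  }
  rel <- m / tot
  tm <- transform_matrix(rel, kind)
  prov$transform <- kind
  out <- tibble(sample_id = rownames(m), as_tibble(tm))
  attr(out, "transform") <- kind
  attr(out, "provenance") <- prov
  class(out) <- c("processed_matrix", class(out))
  out
}

# kind is assumed validated; operates on a relative-abundance matrix.
transform_matrix <- function(rel, kind) {
  switch(kind,
    fourth_root = rel^0.25,
    log1p = log1p(rel),
    wisconsin = {
      mx <- apply(rel, 2, max)
      w <- sweep(rel, 2, ifelse(mx > 0, mx, 1), "/")
      w / rowSums(w)
    },
    none = rel
  )
}

#' Provenance report of the filtering steps
#'
#' @param cm A community tibble carrying a `provenance` attribute.
#' @return The provenance list (JSON-serializable).
#' @export
provenance <- function(cm) {
  attr(cm, "provenance") %||% list()
}
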