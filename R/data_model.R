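# Core tabular data types and their delimited-text I/O.
#
# A "community tibble" is the pipeline's central object: one row per sample,
# a `sample_id` character column first, then one non-negative numeric column
# per species. Sample and species order is preserved exactly as read so that
# seeded permutations reproduce bit-identically.

#' Validate and coerce a data frame to a community tibble
#'
#' @param x A data frame whose first column holds sample identifiers and
#'   whose remaining columns hold non-negative specimen counts per species.
#' @return A tibble with a `sample_id` character column followed by numeric
#'   species columns, in the input order.
#' @examples
#' as_community(data.frame(sample_id = c("s1", "s2"), spA = c(1, 0), spB = c(0, 1)))
#' @export
as_community <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("a community table needs a sample-id column and at least one species column",
          class = "paleoresil_validation_error")
  }
  out <- as_tibble(x, .name_repair = "minimal")
  names(out)[1] <- "sample_id"
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) {
    abort(paste0("duplicated sample identifiers: ",
                 paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  sp <- names(out)[-1]
  if (anyDuplicated(sp)) {
    abort(paste0("duplicated species identifiers: ",
                 paste(unique(sp[duplicated(sp)]), collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  for (j in sp) {
    v <- out[[j]]
    if (!is.numeric(v)) {
      abort(paste0("non-numeric counts in species column '", j, "'"),
            class = "paleoresil_parse_error")
    }
    v[is.na(v)] <- 0
    if (any(v < 0)) {
      bad <- out$sample_id[which(v < 0)[1]]
      abort(paste0("negative count for species '", j, "' in sample '", bad, "'"),
            class = "paleoresil_parse_error")
    }
    out[[j]] <- v
  }
  out
}

#' Extract the numeric sample-by-species matrix from a community tibble
#'
#' @param cm A community tibble (see [as_community()]).
#' @return A numeric matrix with sample ids as row names and species ids as
#'   column names.
#' @export
community_matrix <- function(cm) {
  cm <- as_community(cm)
  m <- as.matrix(cm[-1])
  rownames(m) <- cm$sample_id
  storage.mode(m) <- "double"
  m
}

#' Per-sample specimen totals
#'
#' @inheritParams community_matrix
#' @return A tibble with `sample_id` and `n_specimens`.
#' @export
sample_totals <- function(cm) {
  m <- community_matrix(cm)
  tibble(sample_id = rownames(m), n_specimens = unname(rowSums(m)))
}

#' Read a sample-by-species count table
#'
#' Two dialects are accepted: `"wide"` (header row of species ids, first
#' column sample ids) and `"long"` occurrence triplets with columns
#' `sample_id`, `species_id`, `count` and an optional `element` column
#' (`whole` or `valve`). When an `element` column is present, isolated
#' valves are resolved to individuals via [resolve_valves()] before
#' widening. Missing cells are read as zero.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the extension;
#'   `.tsv`/`.txt` are read as tab-separated).
#' @param dialect `"wide"` or `"long"`.
#' @return A community tibble.
#' @export
read_community_matrix <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- read_delimited(path)
  if (dialect == "wide") {
    return(as_community(raw))
  }
  need <- c("sample_id", "species_id", "count")
  if (!all(need %in% names(raw))) {
    abort(paste0("long dialect needs columns ", paste(need, collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  raw$count <- parse_count_column(raw$count, "count")
  if ("element" %in% names(raw)) raw <- resolve_valves(raw)
  pivot_community(raw)
}

#' Widen long-format occurrences into a community tibble
#'
#' @param occ A tibble with `sample_id`, `species_id`, `count`. Repeated
#'   (sample, species) rows are summed. Sample and species order follow
#'   first appearance.
#' @return A community tibble.
#' @export
pivot_community <- function(occ) {
  occ <- as_tibble(occ)
  occ$sample_id <- as.character(occ$sample_id)
  occ$species_id <- as.character(occ$species_id)
  samples <- unique(occ$sample_id)
  species <- unique(occ$species_id)
  m <- matrix(0, nrow = length(samples), ncol = length(species),
              dimnames = list(samples, species))
  i <- match(occ$sample_id, samples)
  j <- match(occ$species_id, species)
  for (k in seq_len(nrow(occ))) m[i[k], j[k]] <- m[i[k], j[k]] + occ$count[k]
  as_community(tibble(sample_id = samples, as_tibble(m)))
}

#' Write a community tibble as wide CSV
#'
#' Round-trips exactly through [read_community_matrix()]: counts and the
#' order of samples and species are preserved.
#'
#' @inheritParams community_matrix
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path) {
  readr::write_csv(as_community(cm), path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path CSV/TSV with columns `sample_id`, `interval` (one of
#'   `LIG`, `LG`, `CIG`), and optionally `core_id`, `environment`,
#'   `volume_dm3`.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  validate_metadata(read_delimited(path))
}

#' Validate sample metadata (optionally against a community tibble)
#'
#' @param meta A data frame with at least `sample_id` and `interval`.
#' @param cm Optional community tibble; if given, every sample must have
#'   exactly one metadata row.
#' @return `meta` as a tibble, invisibly validated.
#' @export
validate_metadata <- function(meta, cm = NULL) {
  meta <- as_tibble(meta)
  if (!all(c("sample_id", "interval") %in% names(meta))) {
    abort("metadata needs columns sample_id and interval",
          class = "paleoresil_validation_error")
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$interval <- as.character(meta$interval)
  bad <- setdiff(unique(meta$interval), INTERVAL_LEVELS)
  if (length(bad)) {
    abort(paste0("unknown interval label(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(INTERVAL_LEVELS, collapse = "/"), ")"),
          class = "paleoresil_validation_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicated sample_id in metadata", class = "paleoresil_validation_error")
  }
  if (!is.null(cm)) {
    missing <- setdiff(as_community(cm)$sample_id, meta$sample_id)
    if (length(missing)) {
      abort(paste0("samples without metadata: ", paste(missing, collapse = ", ")),
            class = "paleoresil_validation_error")
    }
  }
  meta
}

#' Read a species trait table
#'
#' @param path CSV/TSV with columns `species_id`, `biogeo_class` (one of
#'   `MED/LUS`, `WAF`, `BOR`, `COS`) and `habitat` (`marine`,
#'   `freshwater`, `terrestrial`).
#' @return A validated tibble.
#' @export
read_traits <- function(path) {
  tr <- read_delimited(path)
  validate_traits(tr)
}

#' @rdname read_traits
#' @param traits A data frame of traits to validate in place.
#' @export
validate_traits <- function(traits) {
  traits <- as_tibble(traits)
  need <- c("species_id", "biogeo_class", "habitat")
  if (!all(need %in% names(traits))) {
    abort(paste0("trait table needs columns ", paste(need, collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  traits$species_id <- as.character(traits$species_id)
  bad <- unique(traits$species_id[!traits$biogeo_class %in% BIOGEO_LEVELS])
  if (length(bad)) {
    abort(paste0("unknown biogeo_class for species: ", paste(bad, collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  bad <- unique(traits$species_id[!traits$habitat %in% HABITAT_LEVELS])
  if (length(bad)) {
    abort(paste0("unknown habitat for species: ", paste(bad, collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  if (anyDuplicated(traits$species_id)) {
    abort("duplicated species_id in trait table", class = "paleoresil_validation_error")
  }
  traits
}

#' Read a bathymetric census table
#'
#' Records of live/dead specimen abundance of extant species at known water
#' depths, used for abundance-weighted preferred-depth estimation.
#' Records with zero total abundance are dropped with a message.
#'
#' @param path CSV/TSV with columns `species_id`, `depth_m`, `live`, `dead`.
#' @return A validated tibble with attribute `dropped` giving the number of
#'   zero-abundance records removed.
#' @export
read_bathymetry_census <- function(path) {
  validate_census(read_delimited(path))
}

#' @rdname read_bathymetry_census
#' @param census A data frame of census records to validate in place.
#' @export
validate_census <- function(census) {
  census <- as_tibble(census)
  need <- c("species_id", "depth_m", "live", "dead")
  if (!all(need %in% names(census))) {
    abort(paste0("census needs columns ", paste(need, collapse = ", ")),
          class = "paleoresil_validation_error")
  }
  census$species_id <- as.character(census$species_id)
  for (col in c("depth_m", "live", "dead")) {
    census[[col]] <- parse_count_column(census[[col]], col, allow_negative = FALSE)
  }
  if (any(!is.finite(census$depth_m))) {
    abort("non-finite depth_m in census", class = "paleoresil_validation_error")
  }
  zero <- census$live + census$dead <= 0
  if (any(zero)) {
    inform(paste0("dropping ", sum(zero), " zero-abundance census record(s)"))
    census <- census[!zero, ]
  }
  attr(census, "dropped") <- sum(zero)
  census
}

# -- internal helpers ---------------------------------------------------------

read_delimited <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

parse_count_column <- function(v, name, allow_negative = FALSE) {
  if (is.character(v)) {
    parsed <- suppressWarnings(as.numeric(v))
    if (any(is.na(parsed) & !is.na(v) & v != "")) {
      abort(paste0("non-numeric value in column '", name, "'"),
            class = "paleoresil_parse_error")
    }
    v <- parsed
  }
  if (!is.numeric(v)) {
    abort(paste0("column '", name, "' is not numeric"),
          class = "paleoresil_parse_error")
  }
  v[is.na(v)] <- 0
  if (!allow_negative && any(v < 0)) {
    abort(paste0("negative value in column '", name, "'"),
          class = "paleoresil_parse_error")
  }
  v
}

# Integer-count check shared by the randomization tests.
assert_integer_counts <- function(m, what = "counts") {
  if (max(abs(m - round(m))) > 1e-9) {
    abort(paste0(what, " are not integers; run resolve_valves() before ",
                 "randomization tests"),
          class = "paleoresil_validation_error")
  }
  invisible(m)
}
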