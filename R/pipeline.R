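# End-to-end orchestration: ingest -> preprocess -> ordination/PERMANOVA ->
# randomization null models -> per-sample metrics -> scenario call, with a
# machine-readable manifest when an output directory is given.

#' Pipeline configuration
#'
#' Defaults reproduce the headline analysis settings: minimum 25 specimens
#' per sample (60 as sensitivity), fourth-root transform, k = 2 NMDS,
#' 1000 randomization iterations, alpha = .05.
#'
#' @param min_n Minimum marine specimens per retained sample.
#' @param transform Transform kind for the multivariate matrix.
#' @param k NMDS dimensions.
#' @param restarts NMDS restarts.
#' @param iterations Randomization iterations for the null models and
#'   PERMANOVA permutations.
#' @param alpha Significance level for the scenario call.
#' @param rarefaction_levels Subsample sizes for rarefied richness.
#' @param topk Rank-table depth.
#' @param seed Master seed; per-stage seeds are derived from it (see
#'   [derive_seed()]) so stages are independently re-runnable.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_n = 25, transform = "fourth_root", k = 2,
                            restarts = 20, iterations = 1000, alpha = 0.05,
                            rarefaction_levels = c(25, 60), topk = 10,
                            seed = 1) {
  structure(list(min_n = min_n, transform = transform, k = k,
                 restarts = restarts, iterations = iterations, alpha = alpha,
                 rarefaction_levels = rarefaction_levels, topk = topk,
                 seed = seed),
            class = "pipeline_config")
}

#' Derive a reproducible per-stage seed from the master seed
#'
#' `(seed + 104729 * offset) mod (2^31 - 1)`: deterministic, stays within
#' integer range, and gives distinct streams per stage.
#'
#' @param seed Master integer seed.
#' @param offset Stage offset (small integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483647)
}

#' Run the full glacial-interglacial analysis pipeline
#'
#' Applies the selection rules, builds the transformed matrix and its
#' Bray-Curtis distances, runs NMDS and PERMANOVA, the three pairwise
#' specimen-permutation tests and pooled-abundance envelopes, per-sample
#' metrics (rarefied richness, dominance, biogeographic fractions, depth
#' estimates), the top-k rank table, and classifies the community-response
#' pattern. With `out_dir` set, all tables are written as CSV/JSON plus a
#' manifest with file checksums; identical inputs, config and seed give a
#' byte-identical manifest.
#'
#' @param community A community tibble (integer counts after valve
#'   resolution).
#' @param metadata Sample metadata.
#' @param traits Species trait table.
#' @param census Optional bathymetric census for depth estimation.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `paleo_run` collecting every stage result.
#' @export
run_pipeline <- function(community, metadata, traits, census = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  community <- as_community(community)
  metadata <- validate_metadata(metadata, community)
  traits <- validate_traits(traits)

  cm_f <- filter_samples(community, metadata, traits, min_n = config$min_n)
  cm_mv <- drop_rare_species(cm_f)
  pm <- transform_composition(cm_mv, config$transform)
  dm <- distance_matrix(pm)

  meta_f <- metadata[match(cm_f$sample_id, metadata$sample_id), ]
  groups <- metadata$interval[match(cm_mv$sample_id, metadata$sample_id)]

  ord <- nmds(dm, k = config$k, restarts = config$restarts,
              seed = derive_seed(config$seed, 1))
  warm <- biogeo_fraction(cm_mv, traits)
  ord <- orient_nmds(ord, warm$fraction)

  perm <- permanova(dm, groups, permutations = config$iterations,
                    seed = derive_seed(config$seed, 2))

  pairs <- list(ig = c("LIG", "CIG"), g_ig1 = c("LG", "LIG"), g_ig2 = c("LG", "CIG"))
  bc_tests <- purrr::imap(pairs, function(pr, nm) {
    bc_permutation_test(cm_mv, meta_f, pr[1], pr[2],
                        iterations = config$iterations,
                        seed = derive_seed(config$seed, 10 + match(nm, names(pairs))),
                        transform_kind = config$transform)
  })
  envelopes <- purrr::imap(pairs, function(pr, nm) {
    pooled_abundance_envelope(cm_f, meta_f, pr[1], pr[2],
                              iterations = config$iterations,
                              seed = derive_seed(config$seed, 20 + match(nm, names(pairs))))
  })

  metrics <- rarefy_samples(cm_f, config$rarefaction_levels)
  metrics$dominance <- apply(community_matrix(cm_f), 1, dominance)
  metrics <- left_join(metrics, biogeo_fraction(cm_f, traits), by = "sample_id")
  if (!is.null(census)) {
    pd <- preferred_depths(census)
    metrics <- left_join(metrics, sample_depths(cm_f, pd), by = "sample_id")
  }
  metrics <- left_join(metrics, meta_f[c("sample_id", "interval")], by = "sample_id")

  profiles <- bind_rows(lapply(INTERVAL_LEVELS, function(iv) {
    biogeo_profile(cm_f, meta_f, traits, iv)
  }))
  interval_dominance <- tibble(
    interval = INTERVAL_LEVELS,
    dominance = vapply(INTERVAL_LEVELS, function(iv) {
      ids <- meta_f$sample_id[meta_f$interval == iv]
      dominance(colSums(community_matrix(cm_f[cm_f$sample_id %in% ids, ])))
    }, numeric(1)))

  rank_cig_lig <- topk_overlap(cm_f, meta_f, "CIG", "LIG", k = config$topk)
  rank_cig_lg <- topk_overlap(cm_f, meta_f, "CIG", "LG", k = config$topk)

  evidence <- scenario_evidence(
    p_ig = bc_tests$ig$p_value,
    p_g_ig1 = bc_tests$g_ig1$p_value,
    p_g_ig2 = bc_tests$g_ig2$p_value,
    rho = vapply(envelopes, function(e) e$rho_observed, numeric(1)),
    p_rho = vapply(envelopes, function(e) e$p_rho, numeric(1)),
    permanova_p = perm$p_value)
  call <- classify_pattern(evidence, alpha = config$alpha)

  axis_cors <- correlate_ordination(ord, metrics)

  run <- structure(
    list(config = config, community_filtered = cm_f, community_multivar = cm_mv,
         processed = pm, distances = dm, ordination = ord, permanova = perm,
         bc_tests = bc_tests, envelopes = envelopes, metrics = metrics,
         biogeo_profiles = profiles, interval_dominance = interval_dominance,
         rank_overlap = list(cig_lig = rank_cig_lig, cig_lg = rank_cig_lg),
         scenario = call, axis_correlations = axis_cors,
         provenance = provenance(cm_mv)),
    class = "paleo_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

#' Correlate ordination axes with sample covariates
#'
#' Spearman rank correlation of every NMDS axis against every numeric
#' covariate column of `metrics` (rarefied richness, warm-water specimen
#' fraction, depth estimate, ...), reported for both axes.
#'
#' @param ord A `paleo_nmds` object.
#' @param metrics A tibble with `sample_id` and numeric covariates,
#'   covering exactly the ordinated samples.
#' @return A tibble with `axis`, `covariate`, `rho`, `p_value`, `n`.
#' @export
correlate_ordination <- function(ord, metrics) {
  stopifnot(inherits(ord, "paleo_nmds"))
  pts <- ord$points
  if (!all(pts$sample_id %in% metrics$sample_id)) {
    abort("metrics do not cover all ordinated samples",
          class = "paleoresil_validation_error")
  }
  metrics <- metrics[match(pts$sample_id, metrics$sample_id), ]
  covs <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  covs <- setdiff(covs, "n_specimens")
  axes <- grep("^NMDS", names(pts), value = TRUE)
  purrr::map_dfr(axes, function(ax) {
    purrr::map_dfr(covs, function(cv) {
      ok <- !is.na(metrics[[cv]])
      if (sum(ok) < 3 || sd(rank(metrics[[cv]][ok])) == 0) {
        return(tibble(axis = ax, covariate = cv, rho = NA_real_,
                      p_value = NA_real_, n = sum(ok)))
      }
      sc <- spearman_cor(pts[[ax]][ok], metrics[[cv]][ok])
      tibble(axis = ax, covariate = cv, rho = sc$rho, p_value = sc$p_value,
             n = sc$n)
    })
  })
}

#' @export
print.paleo_run <- function(x, ...) {
  cat("Glacial-interglacial pipeline run\n")
  cat("  samples retained:", nrow(x$community_filtered),
      "| species (multivariate):", ncol(x$community_multivar) - 1, "\n")
  cat("  NMDS stress:", signif(x$ordination$stress, 3),
      "| PERMANOVA p:", signif(x$permanova$p_value, 4), "\n")
  for (nm in names(x$bc_tests)) {
    t <- x$bc_tests[[nm]]
    cat(sprintf("  BC test %s-%s: observed %.3f, p = %.4g\n",
                t$intervals[1], t$intervals[2], t$observed, t$p_value))
  }
  print(x$scenario)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.paleo_run <- function(x, ...) {
  tibble(label = x$scenario$label,
         p_ig = x$bc_tests$ig$p_value,
         p_g_ig1 = x$bc_tests$g_ig1$p_value,
         p_g_ig2 = x$bc_tests$g_ig2$p_value,
         permanova_F = x$permanova$pseudo_F,
         permanova_p = x$permanova$p_value,
         stress = x$ordination$stress,
         n_samples = nrow(x$community_filtered))
}

# Write all run artifacts and return the manifest (also written as JSON).
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    readr::write_csv(x, file.path(out_dir, f))
    f
  }
  files <- c(
    w(run$community_filtered, "community_filtered.csv"),
    w(as_tibble(run$processed), "processed_matrix.csv"),
    w(tibble(sample_id = labels(run$distances),
             as_tibble(as.matrix(run$distances))), "distance_matrix.csv"),
    w(run$ordination$points, "ordination.csv"),
    w(run$metrics, "sample_metrics.csv"),
    w(run$biogeo_profiles, "biogeo_profiles.csv"),
    w(run$interval_dominance, "interval_dominance.csv"),
    w(run$rank_overlap$cig_lig$rank_table, "rank_table_cig_lig.csv"),
    w(run$rank_overlap$cig_lg$rank_table, "rank_table_cig_lg.csv"),
    w(run$axis_correlations, "axis_correlations.csv"))
  for (nm in names(run$bc_tests)) {
    files <- c(files, w(tidy(run$bc_tests[[nm]]), paste0("null_bc_", nm, ".csv")))
  }
  for (nm in names(run$envelopes)) {
    files <- c(files, w(tidy(run$envelopes[[nm]]), paste0("envelope_", nm, ".csv")))
  }
  jw <- function(x, f) {
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    f
  }
  files <- c(files,
    jw(list(stress = run$ordination$stress, k = run$ordination$k,
            restarts = run$ordination$restarts,
            converged = run$ordination$converged), "ordination_stress.json"),
    jw(glance(run$permanova), "permanova.json"),
    jw(lapply(run$bc_tests, function(t) {
      list(comparison = paste(t$intervals, collapse = "-"),
           observed = t$observed, p_value = t$p_value,
           iterations = t$iterations, seed = t$seed, tail = t$tail)
    }), "null_tests.json"),
    jw(list(label = run$scenario$label, alpha = run$scenario$alpha,
            confidence = run$scenario$confidence,
            p = as.list(run$scenario$evidence$p),
            rho = as.list(run$scenario$evidence$rho),
            p_rho = as.list(run$scenario$evidence$p_rho),
            permanova_p = run$scenario$evidence$permanova_p), "scenario.json"),
    jw(run$provenance, "provenance.json"))

  manifest <- list(
    config = unclass(run$config),
    package_version = as.character(utils::packageVersion("paleoresil")),
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$hash <- unname(tools::md5sum(file.path(out_dir, "manifest.json")))
  manifest
}
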