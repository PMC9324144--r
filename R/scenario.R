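# Explicit decision rule rendering the conceptual framework of community
# response to a glacial-interglacial cycle: persistent (no comparison
# departs from the homogeneous-system null), resilient (the two
# interglacials match while both glacial comparisons depart), stochastic
# (every comparison departs). Mixed outcomes with exactly one significant
# glacial comparison have no cell in the framework and are labelled
# indeterminate.

#' Bundle the evidence for a scenario call
#'
#' @param p_ig P-value of the interglacial-interglacial BC permutation
#'   test (LIG vs CIG).
#' @param p_g_ig1,p_g_ig2 P-values of the two glacial-interglacial tests
#'   (LG vs LIG, LG vs CIG).
#' @param rho Optional named numeric vector of pooled-abundance Spearman
#'   correlations (`ig`, `g_ig1`, `g_ig2`).
#' @param p_rho Optional named numeric vector of their p-values.
#' @param permanova_p Optional PERMANOVA p-value, carried as context.
#' @return A list of class `scenario_evidence`.
#' @export
scenario_evidence <- function(p_ig, p_g_ig1, p_g_ig2,
                              rho = NULL, p_rho = NULL, permanova_p = NULL) {
  ps <- c(p_ig = p_ig, p_g_ig1 = p_g_ig1, p_g_ig2 = p_g_ig2)
  if (any(is.na(ps)) || length(ps) != 3) {
    abort("all three pairwise BC-test p-values are required",
          class = "paleoresil_validation_error")
  }
  structure(list(p = ps, rho = rho, p_rho = p_rho, permanova_p = permanova_p),
            class = "scenario_evidence")
}

#' Classify the community-response pattern
#'
#' Deterministic rule over the three pairwise dissimilarity tests at level
#' `alpha`: *persistent* if no test rejects; *resilient* if the
#' interglacial pair does not reject while both glacial comparisons do;
#' *stochastic* if all three reject; *indeterminate* otherwise. The
#' pooled-abundance correlations, when supplied, only corroborate: a
#' resilient call additionally expects a significant positive interglacial
#' rho and non-significant glacial rhos; mismatches downgrade the
#' `confidence` flag, never the label.
#'
#' @param evidence A [scenario_evidence()] object (or a list coercible to
#'   one).
#' @param alpha Significance level (default .05, uncorrected across the
#'   three tests).
#' @return An object of class `scenario_call`: `label`, `alpha`,
#'   `confidence` (`"corroborated"`, `"mixed"`, or `NA` when no
#'   correlation evidence was supplied), and the evidence.
#' @examples
#' classify_pattern(scenario_evidence(.45, .001, .001)) # resilient
#' @export
classify_pattern <- function(evidence, alpha = 0.05) {
  if (!inherits(evidence, "scenario_evidence")) {
    evidence <- do.call(scenario_evidence, as.list(evidence))
  }
  p <- evidence$p
  rej <- p < alpha
  label <- if (!any(rej)) "persistent"
    else if (!rej["p_ig"] && rej["p_g_ig1"] && rej["p_g_ig2"]) "resilient"
    else if (all(rej)) "stochastic"
    else "indeterminate"

  confidence <- NA_character_
  if (!is.null(evidence$rho) && !is.null(evidence$p_rho)) {
    rho <- evidence$rho
    prho <- evidence$p_rho
    sig_pos <- function(which) isTRUE(rho[[which]] > 0 && prho[[which]] < alpha)
    ok <- switch(label,
      persistent = sig_pos("ig") && sig_pos("g_ig1") && sig_pos("g_ig2"),
      resilient = sig_pos("ig") && !sig_pos("g_ig1") && !sig_pos("g_ig2"),
      stochastic = !sig_pos("ig") && !sig_pos("g_ig1") && !sig_pos("g_ig2"),
      indeterminate = NA)
    confidence <- if (is.na(ok)) NA_character_
                  else if (ok) "corroborated" else "mixed"
  }
  structure(list(label = label, alpha = alpha, confidence = confidence,
                 evidence = evidence),
            class = "scenario_call")
}

#' @exportS3Method generics::tidy
tidy.scenario_call <- function(x, ...) {
  tibble(comparison = c("interglacial pair", "glacial vs interglacial 1",
                        "glacial vs interglacial 2"),
         p_value = unname(x$evidence$p),
         rejected = unname(x$evidence$p < x$alpha))
}

#' @exportS3Method generics::glance
glance.scenario_call <- function(x, ...) {
  tibble(label = x$label, alpha = x$alpha, confidence = x$confidence,
         permanova_p = x$evidence$permanova_p %||% NA_real_)
}

#' @export
print.scenario_call <- function(x, ...) {
  cat("Community-response pattern:", toupper(x$label),
      sprintf("(alpha = %g)", x$alpha), "\n")
  cat("  p (interglacial pair):", signif(x$evidence$p[["p_ig"]], 4), "\n")
  cat("  p (glacial comparisons):", signif(x$evidence$p[["p_g_ig1"]], 4),
      "/", signif(x$evidence$p[["p_g_ig2"]], 4), "\n")
  if (!is.na(x$confidence)) {
    cat("  abundance-correlation corroboration:", x$confidence, "\n")
  }
  invisible(x)
}
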