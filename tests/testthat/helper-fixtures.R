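# Shared fixture builders and independent oracles.

tiny_community <- function() {
  tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                 spA = c(30, 0, 2, 10),
                 spB = c(5, 20, 1, 10),
                 spC = c(0, 10, 25, 10))
}

tiny_meta <- function(ids = c("s1", "s2", "s3", "s4"),
                      intervals = c("LIG", "LG", "CIG", "CIG")) {
  tibble::tibble(sample_id = ids, interval = intervals,
                 core_id = "c1", environment = "nearshore")
}

tiny_traits <- function(species = c("spA", "spB", "spC"),
                        classes = c("MED/LUS", "COS", "BOR"),
                        habitat = "marine") {
  tibble::tibble(species_id = species, biogeo_class = classes,
                 habitat = habitat)
}

# A small three-interval dataset with exchangeable samples, cheap enough
# for repeated randomization tests.
small_dataset <- function(seed = 1, scenario = "resilient") {
  generate_dataset(scenario_spec(scenario, S = 20, m = c(LIG = 5, LG = 6, CIG = 7),
                                 size_range = c(30, 120), seed = seed))
}

# Monte-Carlo oracle for rarefied richness: mean observed species count
# over subsamples drawn without replacement.
mc_rarefaction <- function(counts, n, reps = 1000) {
  ids <- rep.int(seq_along(counts), counts)
  draws <- vapply(seq_len(reps),
                  function(i) length(unique(sample(ids, n))), numeric(1))
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(reps))
}

# Independent pseudo-F via the Gower-centered inner-product matrix:
# SS_total = trace(G), SS_within = sum of traces of group-centered blocks.
oracle_pseudo_f <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ss_total <- sum(diag(G))
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    ni <- length(idx)
    Ai <- -0.5 * dm[idx, idx]^2
    Ji <- diag(ni) - matrix(1 / ni, ni, ni)
    ss_within <- ss_within + sum(diag(Ji %*% Ai %*% Ji))
  }
  g <- length(unique(groups))
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

# All permutations of a vector, built independently of the package.
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Exhaustive permutation p-value for the one-way pseudo-F.
oracle_permanova_p <- function(d, groups) {
  f_obs <- oracle_pseudo_f(d, groups)
  fs <- vapply(oracle_perms(seq_along(groups)),
               function(p) oracle_pseudo_f(d, groups[p]), numeric(1))
  mean(fs >= f_obs - 1e-12)
}
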