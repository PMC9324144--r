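#' Published Adriatic top-10 rank table
#'
#' The ten most abundant species of the current-interglacial (CIG)
#' Adriatic nearshore record together with their abundance ranks in the
#' last late glacial (LG) and last interglacial (LIG) intervals, as
#' published for the study system (`NA` = absent from that interval).
#' Feeding these ranks to [overlap_from_ranks()] reproduces the headline
#' top-10 overlaps between intervals.
#'
#' @return A tibble with `species_id`, `rank_cig`, `rank_lg`, `rank_lig`.
#' @examples
#' r <- adriatic_top10_ranks()
#' overlap_from_ranks(r$rank_lig) # 7 of the CIG top 10 are in the LIG top 10
#' overlap_from_ranks(r$rank_lg)  # 4 shared with the LG top 10
#' @export
adriatic_top10_ranks <- function() {
  path <- system.file("extdata", "adriatic_top10_ranks.csv",
                      package = "paleoresil", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
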