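#' Tile counts and relative tumor-microenvironment metrics
#'
#' Comparison-model inputs: the per-compartment tile histogram and five
#' relative metrics built from it — tumor-stroma ratio (TSR), intratumoral
#' and stromal TIL ratios (iTR, sTR), TIL-to-invasive-region share (TISR)
#' and lymphocyte density (LD).
#'
#' @name baseline_metrics
NULL

#' Count tiles per compartment
#'
#' @param ts A `ts_image`.
#' @return Named list `n_tumor`, `n_stroma`, `n_necrosis`, `n_itil`,
#'   `n_stil`, `n_excluded`; the counts sum to the grid size.
#' @export
count_tiles <- function(ts) {
  stopifnot(inherits(ts, "ts_image"))
  lab <- ts$labels
  list(n_tumor = sum(lab == 1L), n_stroma = sum(lab == 2L),
       n_necrosis = sum(lab == 3L), n_itil = sum(lab == 4L),
       n_stil = sum(lab == 5L), n_excluded = sum(lab == 0L))
}

#' Relative TME metrics from tile counts
#'
#' Definitions (each `NA` when its denominator is zero):
#' * `tsr` = stroma / (tumor + stroma)
#' * `itr` = iTIL / (tumor + iTIL)
#' * `str_ratio` = sTIL / (stroma + sTIL)
#' * `tisr` = (iTIL + sTIL) / (tumor + stroma + iTIL + sTIL)
#' * `ld` = (iTIL + sTIL) / (grid size - excluded)
#'
#' @param counts Output of [count_tiles()].
#' @return Named numeric vector of the five ratios, each in `[0, 1]` or
#'   `NA`.
#' @export
relative_metrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, {
    total <- n_tumor + n_stroma + n_necrosis + n_itil + n_stil + n_excluded
    c(tsr = ratio(n_stroma, n_tumor + n_stroma),
      itr = ratio(n_itil, n_tumor + n_itil),
      str_ratio = ratio(n_stil, n_stroma + n_stil),
      tisr = ratio(n_itil + n_stil, n_tumor + n_stroma + n_itil + n_stil),
      ld = ratio(n_itil + n_stil, total - n_excluded))
  })
}
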