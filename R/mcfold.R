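#' Export SHAPE reactivities as MC-Fold-style constraints
#'
#' Converts reactivities to unpaired probabilities with the linear map
#' `p = 0.68 * reactivity + 0.2` (clipped to `[0, 1]`, since the raw map
#' exceeds 1 above reactivity ~1.18) and bins them into the categories a
#' motif-based folding engine consumes: `high` for `p > 0.85`, `medium` for
#' `0.65 < p <= 0.85`, otherwise `none`. Missing reactivities yield no
#' constraint.
#'
#' @param profile A `shape_profile`.
#' @param slope,intercept Linear-map coefficients (defaults 0.68 and 0.2).
#' @param high_cut,medium_cut Category boundaries (defaults 0.85 and 0.65).
#' @return A tibble: `position`, `reactivity`, `probability`, `category`.
#' @export
#' @examples
#' export_mcfold_constraints(shape_profile(c(0, 1, NA, 0.75)))
export_mcfold_constraints <- function(profile, slope = 0.68, intercept = 0.2,
                                      high_cut = 0.85, medium_cut = 0.65) {
  x <- as.numeric(profile)
  p <- pmin(pmax(slope * x + intercept, 0), 1)
  category <- dplyr::case_when(
    is.na(x) ~ "none",
    p > high_cut ~ "high",
    p > medium_cut ~ "medium",
    TRUE ~ "none"
  )
  tibble::tibble(position = seq_along(x), reactivity = x,
                 probability = p, category = category)
}
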