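#' Base-pair accuracy of a predicted structure
#'
#' Compares predicted against native base pairs. Sensitivity is the
#' fraction of native pairs that are predicted; PPV the fraction of
#' predicted pairs that are native. The default MCC is the geometric mean
#' `sqrt(sensitivity * PPV)` — the usual approximation in RNA structure
#' scoring; `exact_mcc = TRUE` instead computes the full confusion-matrix
#' Matthews coefficient with true negatives counted over all unordered
#' position pairs in neither structure. With `allow_slip`, a predicted pair
#' `(i, j)` may match a native `(i±1, j)` or `(i, j±1)`, each native pair
#' being consumed at most once (exact matches claimed first).
#'
#' @param native,predicted [rna_structure] objects over the same sequence
#'   length.
#' @param allow_slip Allow one-nucleotide slippage when matching pairs.
#' @param exact_mcc Use the full confusion-matrix MCC.
#' @return One-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `ppv`, `mcc`,
#'   `ppv_defined` (FALSE when nothing was predicted; `ppv` then reported
#'   as 0).
#' @export
score_structure <- function(native, predicted, allow_slip = FALSE,
                            exact_mcc = FALSE) {
  if (rna_length(native) != rna_length(predicted)) {
    stop("native length (", rna_length(native),
         ") != predicted length (", rna_length(predicted), ")")
  }
  np <- native$pairs; pp <- predicted$pairs
  nkey <- paste(np$i, np$j)
  pkey <- paste(pp$i, pp$j)
  if (!allow_slip) {
    tp <- sum(pkey %in% nkey)
  } else {
    taken <- logical(length(nkey))
    tp <- 0L
    # exact matches first so slips never steal an exact partner
    for (k in seq_along(pkey)) {
      hit <- which(!taken & nkey == pkey[k])
      if (length(hit)) { taken[hit[1]] <- TRUE; tp <- tp + 1L }
    }
    for (k in seq_along(pkey)) {
      if (pkey[k] %in% nkey[taken]) next
      i <- pp$i[k]; j <- pp$j[k]
      slips <- paste(c(i - 1L, i + 1L, i, i),
                     c(j, j, j - 1L, j + 1L))
      hit <- which(!taken & nkey %in% slips)
      if (length(hit)) { taken[hit[1]] <- TRUE; tp <- tp + 1L }
    }
  }
  fp <- nrow(pp) - tp
  fn <- nrow(np) - tp
  sens <- if (nrow(np) > 0) tp / (tp + fn) else NA_real_
  ppv_defined <- nrow(pp) > 0
  ppv <- if (ppv_defined) tp / (tp + fp) else 0
  mcc <- if (exact_mcc) {
    L <- rna_length(native)
    tn <- choose(L, 2) - tp - fp - fn
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  } else {
    sqrt(max(sens, 0, na.rm = TRUE) * max(ppv, 0))
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 sensitivity = sens, ppv = ppv, mcc = mcc,
                 ppv_defined = ppv_defined)
}

#' Shuffle a fraction of SHAPE reactivities
#'
#' Simulates probing noise: exactly `round(fraction * m)` of the `m`
#' non-missing positions are chosen uniformly without replacement and their
#' reactivities are permuted among themselves. Missing entries and all
#' unselected positions are untouched, so the value multiset is preserved.
#'
#' @param profile A `shape_profile`.
#' @param fraction Fraction of non-missing positions to shuffle, in [0, 1].
#' @param seed Integer seed (the global RNG state is left untouched).
#' @return A `shape_profile`.
#' @export
shuffle_noise <- function(profile, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  obs <- which(!is.na(profile))
  k <- round(fraction * length(obs))
  if (k < 2L) return(profile)
  out <- as.numeric(profile)
  withr::with_seed(seed, {
    sel <- sample(obs, k)
    out[sel] <- out[sample(sel)]
  })
  shape_profile(out)
}

#' Noise-robustness protocol
#'
#' For each shuffle fraction, repeats `repeats` times: shuffle the SHAPE
#' profile with [shuffle_noise()], re-run structure selection on the fixed
#' candidate ensemble with the shuffled profile, and score the chosen
#' structure against the native one. Reports per-fraction means and
#' standard errors.
#'
#' @param native Native (reference) [rna_structure].
#' @inheritParams select_structure
#' @param fractions Numeric vector of shuffle fractions.
#' @param repeats Replicates per fraction (default 10).
#' @param seed Base seed; replicate r at fraction index f uses seed
#'   `seed + 1000 * f + r`.
#' @return A tibble with one row per fraction: `fraction`, `repeats`,
#'   `mean_sensitivity`, `se_sensitivity`, `mean_ppv`, `se_ppv`,
#'   `mean_mcc`, `se_mcc`.
#' @export
robustness_run <- function(native, guidance, candidates, profile, patterns,
                           model, fractions, repeats = 10L, seed = 1L) {
  purrr::imap_dfr(as.numeric(fractions), function(f, fi) {
    runs <- purrr::map_dfr(seq_len(repeats), function(r) {
      prof <- shuffle_noise(profile, f, seed + 1000L * fi + r)
      sel <- select_structure(guidance, candidates, prof, patterns, model)
      score_structure(native, sel$chosen)
    })
    tibble::tibble(
      fraction = f, repeats = repeats,
      mean_sensitivity = mean(runs$sensitivity),
      se_sensitivity = stats::sd(runs$sensitivity) / sqrt(repeats),
      mean_ppv = mean(runs$ppv),
      se_ppv = stats::sd(runs$ppv) / sqrt(repeats),
      mean_mcc = mean(runs$mcc),
      se_mcc = stats::sd(runs$mcc) / sqrt(repeats)
    )
  })
}
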