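#' Build per-motif reactivity matrices
#'
#' Collects, for every hairpin/bulge/internal loop motif in a benchmark set,
#' a matrix of SHAPE reactivities with one row per loop instance and one
#' column per motif position (counted from the 5' end of the motif; see
#' [motif_positions()]). Multibranch loops are skipped: their geometry is too
#' heterogeneous for position-wise statistics.
#'
#' @param benchmark A tibble with columns `rna_id` (character), `structure`
#'   (list of [rna_structure]) and `profile` (list of `shape_profile`), e.g.
#'   from [generate_benchmark()].
#' @param exclude_rna Optional RNA id(s) omitted from the matrices (the
#'   leave-one-out strategy: the RNA under prediction is removed from the
#'   training data).
#' @return Named list of numeric matrices (motif label -> matrix); row names
#'   are `<rna_id>:<loop_id>`. Missing reactivities are `NA`.
#' @export
build_motif_matrices <- function(benchmark, exclude_rna = NULL) {
  stopifnot(all(c("rna_id", "structure", "profile") %in% names(benchmark)))
  benchmark <- dplyr::filter(benchmark, !(.data$rna_id %in% exclude_rna))
  acc <- list()
  for (k in seq_len(nrow(benchmark))) {
    s <- benchmark$structure[[k]]
    prof <- benchmark$profile[[k]]
    loops <- extract_loops(s)
    loops <- dplyr::filter(loops, .data$loop_type != "multibranch")
    if (nrow(loops) == 0L) next
    for (l in seq_len(nrow(loops))) {
      pos <- motif_positions(loops$loop_type[l], loops$sides[[l]])
      row <- as.numeric(prof[pos])
      m <- loops$motif[l]
      acc[[m]] <- rbind(acc[[m]], row)
      rownames(acc[[m]])[nrow(acc[[m]])] <-
        paste0(benchmark$rna_id[k], ":", loops$loop_id[l])
    }
  }
  acc
}

#' Identify characteristic SHAPE patterns of a loop motif
#'
#' Tests every ordered position pair of a motif matrix with the paired
#' Wilcoxon signed-rank test. A pair is retained as a characteristic pattern
#' when its two-sided p-value is below `alpha` *and* ranks among the
#' `top_k` smallest p-values for the motif. The direction (which position is
#' `high_pos`) is set by the larger mean reactivity over the rows used.
#'
#' @param matrices Named list of motif matrices from
#'   [build_motif_matrices()], or a single matrix (then `motif` names it).
#' @param alpha Significance level (default 0.05).
#' @param top_k Number of best-ranked pairs retained per motif (default 2).
#' @param min_n Position pairs with fewer complete rows than this are
#'   skipped (the exact test is powerless below ~5 pairs).
#' @param motif Motif label when a bare matrix is supplied.
#' @return A pattern tibble: `motif`, `high_pos`, `low_pos`, `p_value`, `n`
#'   (rows used), `mean_diff` (mean reactivity at `high_pos` minus
#'   `low_pos`).
#' @export
identify_patterns <- function(matrices, alpha = 0.05, top_k = 2L,
                              min_n = 5L, motif = "motif") {
  if (is.matrix(matrices)) {
    matrices <- stats::setNames(list(matrices), motif)
  }
  res <- purrr::imap(matrices, function(mat, m) {
    if (is.null(mat) || nrow(mat) < 2L || ncol(mat) < 2L) return(NULL)
    combs <- utils::combn(ncol(mat), 2L)
    rows <- purrr::map(seq_len(ncol(combs)), function(c0) {
      i <- combs[1, c0]; j <- combs[2, c0]
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (sum(ok) < min_n) return(NULL)
      # exact p-values keep saturated (all-one-sign) pairs exactly tied, so
      # the effect-size tie-break below can order them; the DP stays cheap
      # well past the usual exact-mode cutoff
      wt <- wilcoxon_signed_rank(mat[ok, i], mat[ok, j],
                                 mode = if (sum(ok) <= 100) "exact" else "auto")
      mi <- mean(mat[ok, i]); mj <- mean(mat[ok, j])
      hi <- if (mi >= mj) i else j
      tibble::tibble(
        motif = m,
        high_pos = hi, low_pos = if (hi == i) j else i,
        p_value = wt$p_value, n = sum(ok), mean_diff = abs(mi - mj),
        # saturated = every difference has one sign: the smallest p this
        # sample size can produce, so p comparisons among such pairs are
        # meaningless (and scale only with n through 2^(1-n))
        .saturated = is.finite(wt$p_value) &&
          wt$p_value <= 2.000001 * 2^(-wt$n)
      )
    })
    dplyr::bind_rows(rows)
  })
  tab <- dplyr::bind_rows(res)
  if (nrow(tab) == 0L) return(empty_pattern_table())
  # saturated pairs rank first, ordered by effect size; the rest by p-value
  tab <- dplyr::group_by(tab, .data$motif)
  tab <- dplyr::arrange(tab, !.data$.saturated,
                        dplyr::if_else(.data$.saturated,
                                       -.data$mean_diff, .data$p_value),
                        dplyr::desc(.data$mean_diff),
                        .data$high_pos, .data$low_pos, .by_group = TRUE)
  tab <- dplyr::mutate(tab, .rank = dplyr::row_number())
  tab <- dplyr::ungroup(tab)
  tab <- dplyr::filter(tab, .data$p_value < alpha, .data$.rank <= top_k)
  dplyr::select(tab, -".rank", -".saturated")
}

empty_pattern_table <- function() {
  tibble::tibble(motif = character(), high_pos = integer(),
                 low_pos = integer(), p_value = numeric(),
                 n = integer(), mean_diff = numeric())
}

#' Discover characteristic patterns from a benchmark set
#'
#' Convenience wrapper: [build_motif_matrices()] then [identify_patterns()].
#'
#' @inheritParams build_motif_matrices
#' @inheritParams identify_patterns
#' @return A pattern tibble (see [identify_patterns()]).
#' @export
discover_patterns <- function(benchmark, exclude_rna = NULL, alpha = 0.05,
                              top_k = 2L, min_n = 5L) {
  identify_patterns(build_motif_matrices(benchmark, exclude_rna),
                    alpha = alpha, top_k = top_k, min_n = min_n)
}

#' Read / write pattern tables
#'
#' Tab-separated columns `motif`, `high_pos`, `low_pos`, `p_value` (plus any
#' extra columns, preserved). Round-trips losslessly.
#'
#' @param patterns A pattern tibble.
#' @param path File path.
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(patterns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @return `read_patterns()`: a pattern tibble.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) <= 1L) return(empty_pattern_table())
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("motif", "high_pos", "low_pos", "p_value")
  if (!all(need %in% names(tab))) {
    stop("pattern table must have columns ", paste(need, collapse = ", "))
  }
  bad <- !grepl("^(hairpin|bulge)-[0-9]+$|^internal-[0-9]+x[0-9]+$", tab$motif)
  if (any(bad)) {
    stop("line ", which(bad)[1] + 1L, ": unknown motif string '",
         tab$motif[which(bad)[1]], "'")
  }
  tibble::as_tibble(tab)
}
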