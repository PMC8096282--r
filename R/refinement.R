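#' Classify loops of a guidance structure
#'
#' Scores every extracted loop of the guidance structure with
#' [loop_penalties()] and divides them into `good` (penalty 0), `fair`
#' (penalty in (0, 1], or no characteristic pattern for the motif) and
#' `poor` (penalty > 1). Each loop also gets its *region*: every side run
#' extended by `region_pad` nucleotides on both ends (clipped to the
#' sequence), the interval scanned when judging replacement loops.
#'
#' @param guidance An [rna_structure] (the structure to refine, typically an
#'   MFE prediction under SHAPE restraints).
#' @inheritParams loop_penalties
#' @param fair_threshold Penalty bound separating fair from poor (default 1).
#' @param region_pad Region extension in nucleotides (default 4).
#' @return The penalty tibble with added `category` and `region`
#'   (list-column of two-column interval matrices).
#' @export
classify_loops <- function(guidance, profile, patterns, model,
                           fair_threshold = 1, region_pad = 4L,
                           posterior_cutoff = 0.5) {
  pen <- loop_penalties(guidance, profile, patterns, model,
                        posterior_cutoff = posterior_cutoff)
  L <- rna_length(guidance)
  dplyr::mutate(
    pen,
    category = penalty_category(.data$penalty, .data$patterns_available,
                                fair_threshold),
    region = purrr::map(.data$sides, loop_region, pad = region_pad, L = L)
  )
}

#' Penalty category of a loop
#'
#' `good`: penalty exactly 0; `fair`: penalty in (0, `fair_threshold`] or
#' patterns unavailable; `poor`: penalty above `fair_threshold`.
#'
#' @param penalty Numeric penalties (`NA` when patterns unavailable).
#' @param patterns_available Logical vector.
#' @param fair_threshold Fair/poor boundary (default 1).
#' @return Character vector of categories.
#' @export
penalty_category <- function(penalty, patterns_available,
                             fair_threshold = 1) {
  dplyr::case_when(
    !patterns_available ~ "fair",
    penalty == 0 ~ "good",
    penalty <= fair_threshold ~ "fair",
    TRUE ~ "poor"
  )
}

# union of per-side padded intervals, merged when overlapping
loop_region <- function(sides, pad, L) {
  iv <- purrr::map(sides[lengths(sides) > 0L], function(run) {
    c(max(1L, min(run) - pad), min(L, max(run) + pad))
  })
  if (length(iv) == 0L) return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (r in seq_len(nrow(m))[-1]) {
    if (m[r, 1] <= out[nrow(out), 2] + 1L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[r, 2])
    } else {
      out <- rbind(out, m[r, ])
    }
  }
  out
}

positions_in_region <- function(positions, region) {
  if (nrow(region) == 0L) return(FALSE)
  any(purrr::map_lgl(seq_len(nrow(region)), function(r) {
    any(positions >= region[r, 1] & positions <= region[r, 2])
  }))
}

#' Check a candidate against the selection criteria
#'
#' Evaluates a candidate structure against the classified loops of the
#' guidance structure:
#' * (i) every `good` guidance loop is retained (identical type, unpaired
#'   positions and closing pairs);
#' * (ii) no candidate loop overlapping a `fair` loop region carries a
#'   penalty above `fair_threshold`;
#' * (iii) every `poor` guidance loop is absent from the candidate and every
#'   candidate loop overlapping its region has a strictly lower penalty
#'   (vacuously satisfied when the region became fully paired);
#' * the total penalty sums the penalties of all candidate loops whose
#'   motifs have characteristic patterns.
#' Candidate loops without patterns have no penalty and can violate neither
#' (ii) nor (iii).
#'
#' @param candidate An [rna_structure] over the same sequence as the
#'   guidance.
#' @param assessments Output of [classify_loops()] for the guidance.
#' @inheritParams classify_loops
#' @return One-row tibble: `c_i`, `c_ii`, `c_iii`, `total_penalty`,
#'   `n_loops`, plus a `loops` list-column with the candidate's scored
#'   loops.
#' @export
candidate_satisfies <- function(candidate, assessments, profile, patterns,
                                model, fair_threshold = 1,
                                posterior_cutoff = 0.5) {
  if (length(profile) != rna_length(candidate)) {
    stop("candidate length (", rna_length(candidate),
         ") does not match profile length (", length(profile), ")")
  }
  cand <- loop_penalties(candidate, profile, patterns, model,
                         posterior_cutoff = posterior_cutoff)
  cand_keys <- loop_keys(cand)
  good <- assessments[assessments$category == "good", , drop = FALSE]
  fair <- assessments[assessments$category == "fair", , drop = FALSE]
  poor <- assessments[assessments$category == "poor", , drop = FALSE]

  c_i <- all(loop_keys(good) %in% cand_keys)

  scored <- !is.na(cand$penalty)
  c_ii <- TRUE
  for (r in seq_len(nrow(fair))) {
    reg <- fair$region[[r]]
    over <- scored & purrr::map_lgl(cand$positions, positions_in_region, reg)
    if (any(cand$penalty[over] > fair_threshold)) { c_ii <- FALSE; break }
  }

  c_iii <- TRUE
  poor_keys <- loop_keys(poor)
  for (r in seq_len(nrow(poor))) {
    if (poor_keys[r] %in% cand_keys) { c_iii <- FALSE; break }
    reg <- poor$region[[r]]
    over <- scored & purrr::map_lgl(cand$positions, positions_in_region, reg)
    if (any(cand$penalty[over] >= poor$penalty[r])) { c_iii <- FALSE; break }
  }

  tibble::tibble(
    c_i = c_i, c_ii = c_ii, c_iii = c_iii,
    total_penalty = sum(cand$penalty[scored]),
    n_loops = nrow(cand),
    loops = list(cand)
  )
}

#' Select the structure most consistent with the SHAPE patterns
#'
#' Scores the guidance structure, evaluates every candidate against
#' criteria (i)-(iii) of [candidate_satisfies()], and returns the candidate
#' with the lowest total penalty among those meeting all three (criterion
#' iv). If none does, the candidate with the lowest total penalty overall
#' is returned (`fallback_used = TRUE`). Ties break on input order; the
#' guidance structure is appended to the pool (it may legitimately win)
#' unless already present.
#'
#' @param guidance The guidance [rna_structure].
#' @param candidates List of candidate [rna_structure] objects over the
#'   same sequence.
#' @inheritParams classify_loops
#' @return A `refinement_result`: `chosen` (structure), `chosen_index`
#'   (into the audited pool), `fallback_used`, `satisfied` (logical triple
#'   of the chosen candidate), `total_penalty`, `assessments` (guidance
#'   classification) and `audit` (per-candidate tibble).
#' @export
select_structure <- function(guidance, candidates, profile, patterns, model,
                             fair_threshold = 1, region_pad = 4L,
                             posterior_cutoff = 0.5) {
  if (length(candidates) == 0L) stop("empty candidate list")
  assess <- classify_loops(guidance, profile, patterns, model,
                           fair_threshold = fair_threshold,
                           region_pad = region_pad,
                           posterior_cutoff = posterior_cutoff)
  pool <- candidates
  is_guidance <- rep(FALSE, length(pool))
  if (!any(purrr::map_lgl(pool, structure_equal, guidance))) {
    pool <- c(pool, list(guidance))
    is_guidance <- c(is_guidance, TRUE)
  } else {
    is_guidance[which(purrr::map_lgl(pool, structure_equal, guidance))] <- TRUE
  }
  audit <- purrr::map_dfr(pool, candidate_satisfies, assess, profile,
                          patterns, model, fair_threshold = fair_threshold,
                          posterior_cutoff = posterior_cutoff)
  audit <- dplyr::mutate(audit, candidate = dplyr::row_number(),
                         is_guidance = is_guidance,
                         meets_all = .data$c_i & .data$c_ii & .data$c_iii,
                         .before = 1)
  eligible <- which(audit$meets_all)
  fallback <- length(eligible) == 0L
  cand_set <- if (fallback) seq_len(nrow(audit)) else eligible
  chosen_index <- cand_set[which.min(audit$total_penalty[cand_set])]
  audit$selected <- seq_len(nrow(audit)) == chosen_index
  structure(list(
    chosen = pool[[chosen_index]],
    chosen_index = chosen_index,
    fallback_used = fallback,
    satisfied = unlist(audit[chosen_index, c("c_i", "c_ii", "c_iii")]),
    total_penalty = audit$total_penalty[chosen_index],
    assessments = assess,
    audit = audit
  ), class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("<refinement_result> candidate ", x$chosen_index, " of ",
      nrow(x$audit), " chosen (total penalty ",
      signif(x$total_penalty, 4),
      if (x$fallback_used) ", fallback: no candidate met all criteria" else "",
      ")\n", sep = "")
  cat(write_dotbracket(x$chosen), "\n")
  invisible(x)
}

#' Centroid of a candidate ensemble
#'
#' The ensemble member minimizing the summed base-pair symmetric-difference
#' distance to all other members; ties break on the lowest index.
#'
#' @param candidates Non-empty list of [rna_structure] objects.
#' @return The centroid [rna_structure].
#' @export
centroid_structure <- function(candidates) {
  n <- length(candidates)
  if (n == 0L) stop("empty candidate list")
  keys <- purrr::map(candidates, ~ paste(.x$pairs$i, .x$pairs$j))
  tot <- numeric(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      tot[a] <- tot[a] + length(setdiff(keys[[a]], keys[[b]])) +
        length(setdiff(keys[[b]], keys[[a]]))
    }
  }
  candidates[[which.min(tot)]]
}

#' Compare per-loop penalties across alternative structures
#'
#' Scores the loops of each supplied structure under the same profile,
#' patterns and model — the workhorse for hypothesis tests such as
#' tetraloop-vs-heptaloop folding states or kissing-loop formation, where
#' the structure whose distinctive loop carries the lower penalty is the
#' better-supported fold.
#'
#' @param structures Named list of [rna_structure] objects.
#' @inheritParams loop_penalties
#' @return A tibble of per-structure, per-loop penalties.
#' @export
compare_structures <- function(structures, profile, patterns, model,
                               posterior_cutoff = 0.5) {
  if (is.null(names(structures))) {
    names(structures) <- paste0("structure_", seq_along(structures))
  }
  purrr::imap_dfr(structures, function(s, nm) {
    pen <- loop_penalties(s, profile, patterns, model,
                          posterior_cutoff = posterior_cutoff)
    dplyr::mutate(
      dplyr::select(pen, "loop_id", "loop_type", "motif", "n_unpaired",
                    "patterns_available", "penalty"),
      structure = nm, .before = 1)
  })
}
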