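# Plain-loop re-implementation of the selection criteria, used as the
# brute-force cross-check for select_structure(). Regions are expanded to
# explicit position sets instead of interval arithmetic.
oracle_criteria <- function(cand, assessments, profile, patterns, model, L) {
  pen <- loop_penalties(cand, profile, patterns, model)
  keys <- loop_keys(pen)
  scored <- which(!is.na(pen$penalty))

  region_set <- function(row) {
    out <- integer(0)
    for (side in row$sides[[1]][lengths(row$sides[[1]]) > 0]) {
      out <- c(out, max(1, min(side) - 4):min(L, max(side) + 4))
    }
    unique(out)
  }

  good <- assessments[assessments$category == "good", ]
  ci <- TRUE
  for (r in seq_len(nrow(good))) {
    if (!(loop_keys(good[r, ]) %in% keys)) ci <- FALSE
  }

  fair <- assessments[assessments$category == "fair", ]
  cii <- TRUE
  for (r in seq_len(nrow(fair))) {
    reg <- region_set(fair[r, ])
    for (q in scored) {
      if (any(pen$positions[[q]] %in% reg) && pen$penalty[q] > 1) cii <- FALSE
    }
  }

  poor <- assessments[assessments$category == "poor", ]
  ciii <- TRUE
  for (r in seq_len(nrow(poor))) {
    if (loop_keys(poor[r, ]) %in% keys) ciii <- FALSE
    reg <- region_set(poor[r, ])
    for (q in scored) {
      if (any(pen$positions[[q]] %in% reg) &&
          pen$penalty[q] >= poor$penalty[r]) ciii <- FALSE
    }
  }

  list(meets = ci && cii && ciii,
       total = sum(pen$penalty[scored]))
}

oracle_select <- function(guidance, pool, profile, patterns, model) {
  assessments <- classify_loops(guidance, profile, patterns, model)
  L <- nchar(guidance$sequence)
  if (!any(vapply(pool, structure_equal, logical(1), guidance))) {
    pool <- c(pool, list(guidance))
  }
  rows <- lapply(pool, oracle_criteria, assessments, profile, patterns,
                 model, L)
  meets <- vapply(rows, `[[`, logical(1), "meets")
  totals <- vapply(rows, `[[`, numeric(1), "total")
  cand_set <- if (any(meets)) which(meets) else seq_along(pool)
  list(index = cand_set[which.min(totals[cand_set])],
       fallback = !any(meets))
}
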