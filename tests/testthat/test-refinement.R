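test_that("penalty categories follow the printed thresholds", {
  expect_equal(penalty_category(0, TRUE), "good")
  expect_equal(penalty_category(0.7, TRUE), "fair")
  expect_equal(penalty_category(1.0, TRUE), "fair")
  expect_equal(penalty_category(1.0001, TRUE), "poor")
  expect_equal(penalty_category(NA_real_, FALSE), "fair")
  expect_equal(penalty_category(5, FALSE), "fair")
})

test_that("loop regions extend sides by four nucleotides, clipped and merged", {
  expect_equal(loop_region(list(10:13), pad = 4, L = 50),
               matrix(c(6L, 17L), 1))
  expect_equal(loop_region(list(2:3), pad = 4, L = 50),
               matrix(c(1L, 7L), 1))
  # two sides of an internal loop merge when their padded intervals touch
  reg <- loop_region(list(10L, 16L), pad = 4, L = 50)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg[1, ], c(6L, 20L))
  reg2 <- loop_region(list(5L, 40L), pad = 4, L = 50)
  expect_equal(nrow(reg2), 2L)
})

test_that("candidate criteria detect retained, broken and replaced loops", {
  fx <- shared_fixture()
  trials <- generate_benchmark(1, refinement_spec(), seed = 900)
  truth <- trials$structure[[1]]
  prof <- trials$profile[[1]]
  g <- plant_wrong_loop(truth, seed = 901)$guidance
  ass <- classify_loops(g, prof, fx$patterns, fx$model)
  expect_true(any(ass$category == "poor"))

  # guidance against itself: good loops retained, poor loop kept -> iii fails
  self <- candidate_satisfies(g, ass, prof, fx$patterns, fx$model)
  expect_true(self$c_i)
  expect_false(self$c_iii)

  # the truth replaces the poor loop with a lower-penalty one
  tr <- candidate_satisfies(truth, ass, prof, fx$patterns, fx$model)
  expect_true(tr$c_i)

  # breaking a good loop's helix violates (i)
  good_rows <- ass[ass$category == "good", ]
  if (nrow(good_rows) > 0) {
    runs <- helix_runs(g)
    gi <- good_rows$closing_pairs[[1]][1, 1]
    hit <- which(purrr::map_lgl(runs, ~ gi %in% .x$i))
    broken <- shift_helix(g, hit[1], 2)
    br <- candidate_satisfies(broken, ass, prof, fx$patterns, fx$model)
    expect_false(br$c_i)
  }

  # pairing the whole poor region satisfies (iii) vacuously
  poor <- ass[ass$category == "poor", ][1, ]
  reg <- poor$region[[1]]
  cand <- truth
  keep <- !purrr::map_lgl(seq_len(nrow(cand$pairs)), function(r) FALSE)
  vac <- candidate_satisfies(
    parse_dotbracket(strrep(".", rna_length(g)), g$sequence),
    ass, prof, fx$patterns, fx$model)
  expect_true(vac$c_iii) # no loops at all -> nothing overlaps the region
  expect_false(vac$c_i) # but the good loops are gone

  expect_error(
    candidate_satisfies(parse_dotbracket("....", "ACGU"), ass, prof,
                        fx$patterns, fx$model),
    "length")
})

test_that("selection agrees with brute-force criteria evaluation", {
  fx <- shared_fixture()
  withr::with_seed(61, {
    for (rep in 1:8) {
      trials <- generate_benchmark(1, refinement_spec(), seed = 920 + rep)
      truth <- trials$structure[[1]]
      prof <- trials$profile[[1]]
      g <- plant_wrong_loop(truth, seed = 940 + rep)$guidance
      pool <- c(list(truth),
                generate_ensemble(g, 10, 0.3, seed = 960 + rep,
                                  include_true = FALSE))
      sel <- select_structure(g, pool, prof, fx$patterns, fx$model)
      # brute force: evaluate every pool member independently
      ass <- classify_loops(g, prof, fx$patterns, fx$model)
      full_pool <- pool
      if (!any(purrr::map_lgl(pool, structure_equal, g))) {
        full_pool <- c(pool, list(g))
      }
      rows <- purrr::map_dfr(full_pool, candidate_satisfies, ass, prof,
                             fx$patterns, fx$model)
      meets <- rows$c_i & rows$c_ii & rows$c_iii
      expected <- if (any(meets)) {
        which(meets)[which.min(rows$total_penalty[meets])]
      } else {
        which.min(rows$total_penalty)
      }
      expect_equal(sel$chosen_index, expected)
      expect_equal(sel$fallback_used, !any(meets))
    }
  })
})

test_that("selection handles degenerate pools and documented tie-breaks", {
  fx <- shared_fixture()
  trials <- generate_benchmark(1, refinement_spec(), seed = 970)
  truth <- trials$structure[[1]]
  prof <- trials$profile[[1]]
  expect_error(select_structure(truth, list(), prof, fx$patterns, fx$model),
               "empty")
  # guidance with only good/fair loops wins against worse candidates
  sel <- select_structure(truth, list(plant_wrong_loop(truth, seed = 971)$guidance),
                          prof, fx$patterns, fx$model)
  expect_true(structure_equal(sel$chosen, truth))
  # duplication does not change the outcome
  g <- plant_wrong_loop(truth, seed = 972)$guidance
  pool <- c(list(truth), generate_ensemble(g, 6, 0.3, seed = 973,
                                           include_true = FALSE))
  s1 <- select_structure(g, pool, prof, fx$patterns, fx$model)
  s2 <- select_structure(g, c(pool, pool), prof, fx$patterns, fx$model)
  expect_true(structure_equal(s1$chosen, s2$chosen))
})

test_that("fallback fires when no candidate can replace the poor loop", {
  fx <- shared_fixture()
  trials <- generate_benchmark(1, refinement_spec(), seed = 980)
  truth <- trials$structure[[1]]
  prof <- trials$profile[[1]]
  g <- plant_wrong_loop(truth, seed = 981)$guidance
  ass <- classify_loops(g, prof, fx$patterns, fx$model)
  expect_true(any(ass$category == "poor"))
  poor_keys <- loop_keys(ass[ass$category == "poor", ])
  # candidates that all retain the poor loop
  raw <- generate_ensemble(g, 40, 0.25, seed = 982, include_true = FALSE)
  keep <- purrr::keep(raw, function(cand) {
    all(poor_keys %in% loop_keys(extract_loops(cand)))
  })
  expect_gt(length(keep), 0)
  sel <- select_structure(g, keep, prof, fx$patterns, fx$model)
  expect_true(sel$fallback_used)
  expect_equal(sel$chosen_index, which.min(tidy(sel)$total_penalty))
})

test_that("the centroid minimizes total base-pair distance", {
  a <- parse_dotbracket("((((....))))....", "GGGGAAAACCCCAAAA")
  b <- parse_dotbracket("....((((....))))", "AAAAGGGGAAAACCCC")
  expect_true(structure_equal(centroid_structure(list(a, a, a)), a))
  expect_true(structure_equal(centroid_structure(list(a, a, b)), a))
  expect_true(structure_equal(centroid_structure(list(b, a, a)), a))
  # two-candidate tie: first wins
  expect_true(structure_equal(centroid_structure(list(b, a)), b))
  expect_error(centroid_structure(list()), "empty")
})

test_that("structure comparison tabulates per-loop penalties", {
  fx <- shared_fixture()
  trials <- generate_benchmark(1, refinement_spec(), seed = 990)
  truth <- trials$structure[[1]]
  g <- plant_wrong_loop(truth, seed = 991)$guidance
  cmp <- compare_structures(list(native = truth, predicted = g),
                            trials$profile[[1]], fx$patterns, fx$model)
  expect_setequal(unique(cmp$structure), c("native", "predicted"))
  # the displaced loop carries a higher penalty in the wrong structure
  tot <- tapply(cmp$penalty, cmp$structure, sum, na.rm = TRUE)
  expect_gte(tot[["predicted"]], tot[["native"]])
})
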