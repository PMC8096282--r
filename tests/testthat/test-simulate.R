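test_that("structure generation realizes the requested motif inventory", {
  spec <- synth_spec(rna_length = 60, motifs = c("hairpin-4" = 1),
                     planted = NULL)
  s <- generate_structure(spec, seed = 5)
  loops <- extract_loops(s)
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$motif, "hairpin-4")
  # determinism
  expect_true(structure_equal(s, generate_structure(spec, seed = 5)))
  expect_false(structure_equal(s, generate_structure(spec, seed = 6)))

  spec2 <- synth_spec(rna_length = 80,
                      motifs = c("internal-1x2" = 1, "bulge-2" = 1),
                      planted = NULL)
  loops2 <- extract_loops(generate_structure(spec2, seed = 7))
  expect_true("internal-1x2" %in% loops2$motif)
  expect_true("bulge-2" %in% loops2$motif)
  # every generated loop carries its two flanking pairs by construction
  expect_true(all(!is.na(purrr::map_int(loops2$flanking_pairs, ~ .x[1, 1]))))

  expect_error(generate_structure(synth_spec(rna_length = 10,
                                             motifs = c("hairpin-4" = 3))),
               "rna_length")
})

test_that("profiles separate paired and loop reactivities and plant offsets", {
  spec <- synth_spec(rna_length = 40, motifs = c("hairpin-4" = 1),
                     missing_rate = 0)
  ds <- purrr::map(1:200, function(k) {
    s <- generate_structure(spec, seed = k)
    prof <- generate_shape(s, spec, seed = 1000 + k)
    loop <- extract_loops(s)
    pos <- loop$positions[[1]]
    p <- partner_vector(s)
    c(col1 = prof[pos[1]], col2 = prof[pos[2]],
      paired = mean(prof[p > 0]))
  })
  m <- do.call(rbind, ds)
  # planted apex at position 2 (offset +0.8) against the depressed position 1
  expect_equal(mean(m[, "col2"]) - mean(m[, "col1"]),
               0.8 + 0.35, tolerance = 0.12)
  expect_lt(mean(m[, "paired"]), 0.3)
  # determinism
  s <- generate_structure(spec, seed = 3)
  expect_identical(generate_shape(s, spec, seed = 9),
                   generate_shape(s, spec, seed = 9))
})

test_that("missing values are injected at the requested rate", {
  spec <- synth_spec(rna_length = 1000, motifs = c("hairpin-4" = 1),
                     missing_rate = 0.1, planted = NULL)
  s <- generate_structure(spec, seed = 21)
  prof <- generate_shape(s, spec, seed = 22)
  expect_gt(sum(is.na(prof)), 60) # binomial(1000, 0.1) comfortably
  expect_lt(sum(is.na(prof)), 145)
})

test_that("null profiles give no reproducible patterns above chance", {
  spec <- synth_spec(rna_length = 120, motifs = c("hairpin-4" = 2),
                     planted = NULL, missing_rate = 0)
  withr::with_seed(71, {
    hits <- 0
    for (rep in 1:40) {
      bench <- generate_benchmark(8, spec, seed = 3000 + rep)
      pats <- discover_patterns(bench)
      hits <- hits + (nrow(pats) > 0)
    }
    # 6 position pairs at alpha 0.05; with the top-2 rule some runs retain
    # a pattern by chance, but planted signal retains one essentially always
    expect_lte(hits, 16)
  })
})

test_that("ensembles stay valid and respect the include-true flag", {
  spec <- refinement_spec()
  truth <- generate_structure(spec, seed = 31)
  ens0 <- generate_ensemble(truth, 5, 0, seed = 32)
  expect_true(all(purrr::map_lgl(ens0, structure_equal, truth)))

  ens <- generate_ensemble(truth, 30, 0.5, seed = 33)
  expect_true(structure_equal(ens[[1]], truth))
  for (cand in ens) {
    p <- partner_vector(cand)
    # symmetric partner map, no self pairs
    idx <- which(p > 0)
    expect_true(all(p[p[idx]] == idx))
    expect_false(any(p[idx] == idx))
    # nested layer writes and re-parses cleanly (validity sweep)
    rt <- parse_dotbracket(write_dotbracket(cand), cand$sequence)
    expect_equal(nrow(rt$pairs), nrow(cand$pairs))
    # no lonely helices: every nested pair has a stacked neighbour
    runs <- helix_runs(cand)
    expect_true(all(purrr::map_int(runs, nrow) >= 2))
  }
  ens2 <- generate_ensemble(truth, 10, 0.5, seed = 34, include_true = FALSE)
  expect_false(any(purrr::map_lgl(ens2, structure_equal, truth)))
})

test_that("training differences split by reference membership", {
  fx <- shared_fixture()
  bench <- fx$bench[1, ]
  ref <- bench$structure[[1]]
  # ensemble equal to the reference -> no false observations
  td0 <- make_training_differences(bench, setNames(list(list(ref)),
                                                   bench$rna_id), fx$patterns)
  expect_equal(length(td0$false), 0L)
  expect_gt(length(td0$true), 0L)
  expect_equal(td0$n_false_pairs, 0L)

  # a loop present in both reference and candidate counts as true only
  cand <- plant_wrong_loop(ref, seed = 55)$guidance
  td <- make_training_differences(bench, setNames(list(list(ref, cand)),
                                                  bench$rna_id), fx$patterns)
  ref_keys <- loop_keys(extract_loops(ref))
  cand_loops <- extract_loops(cand)
  shared <- sum(loop_keys(cand_loops) %in% ref_keys)
  novel <- cand_loops[!(loop_keys(cand_loops) %in% ref_keys), ]
  # brute-force count of false observations: pattern pairs with data in
  # novel candidate loops
  prof <- bench$profile[[1]]
  n_false <- 0L
  for (k in seq_len(nrow(novel))) {
    pats <- fx$patterns[fx$patterns$motif == novel$motif[k], ]
    if (nrow(pats) == 0) next
    mp <- motif_positions(novel$loop_type[k], novel$sides[[k]])
    d <- prof[mp[pats$high_pos]] - prof[mp[pats$low_pos]]
    n_false <- n_false + sum(!is.na(d))
  }
  expect_equal(length(td$false), n_false)
  expect_gt(shared, 0)
})
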