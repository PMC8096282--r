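test_that("loop extraction classifies hairpin, internal and bulge faces", {
  s <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
  l <- extract_loops(s)
  expect_equal(nrow(l), 1L)
  expect_equal(l$loop_type, "hairpin")
  expect_equal(l$positions[[1]], 5:8)
  expect_equal(l$closing_pairs[[1]][1, ], c(4L, 9L))
  expect_equal(l$flanking_pairs[[1]][1, ], c(3L, 10L))

  l2 <- extract_loops(parse_dotbracket("((.((....)).))", "GGAGGAAAACCACC"))
  expect_setequal(l2$motif, c("internal-1x1", "hairpin-4"))
  int <- l2[l2$loop_type == "internal", ]
  expect_equal(int$positions[[1]], c(3L, 12L))
  expect_equal(int$closing_pairs[[1]][1, ], c(2L, 13L))
  expect_equal(int$closing_pairs[[1]][2, ], c(4L, 11L))

  l3 <- extract_loops(parse_dotbracket("((.((....))))", "GGAGGAAAACCCC"))
  expect_setequal(l3$motif, c("bulge-1", "hairpin-4"))
  expect_equal(l3$positions[[which(l3$loop_type == "bulge")]], 3L)
})

test_that("loops without two flanking pairs on every helix are dropped", {
  # single closing pair: hairpin ineligible
  all_loops <- extract_loops(parse_dotbracket("(....)", "GAAAAC"),
                             keep_dropped = TRUE)
  expect_false(all_loops$eligible[1])
  expect_equal(nrow(extract_loops(parse_dotbracket("(....)", "GAAAAC"))), 0L)
  # internal loop with a 1-pair inner helix
  l <- extract_loops(parse_dotbracket("((.(....).))", "GGAGAAAACACC"),
                     keep_dropped = TRUE)
  expect_true(all(!l$eligible[l$loop_type == "internal"]))
})

test_that("loops touching pseudoknot pairs are removed", {
  # hairpin whose residues pair into a pk layer
  s <- parse_dotbracket("(((..[[...)))..]]", "GGGAAGGAAACCCAACC")
  kept <- extract_loops(s)
  expect_false(any(kept$loop_type == "hairpin" &
                     purrr::map_lgl(kept$positions, ~ any(.x %in% c(6, 7)))))
  dropped <- extract_loops(s, keep_dropped = TRUE)
  expect_true(any(dropped$pk_involved))
})

test_that("motif signatures canonicalize internal loops idempotently", {
  s <- parse_dotbracket("((((..((((....)))).))))", "GGGGAAGGGGAAAACCCCACCCC")
  l <- extract_loops(s)
  int <- l[l$loop_type == "internal", ]
  expect_equal(int$motif, "internal-1x2")
  # mirror: 5' side longer -> enumeration starts on the (reversed) 3' side
  mp <- motif_positions("internal", list(c(5L, 6L), 18L))
  expect_equal(mp, c(18L, 6L, 5L))
  # already canonical: unchanged
  mp2 <- motif_positions("internal", list(5L, c(17L, 18L)))
  expect_equal(mp2, c(5L, 17L, 18L))
  expect_equal(motif_string("hairpin", list(1:4)), "hairpin-4")
  expect_equal(motif_string("bulge", list(1:5)), "bulge-5")
  expect_equal(motif_string("internal", list(1:2, 4:4)), "internal-1x2")
  expect_equal(motif_string("internal", list(1, 3:4)), "internal-1x2")
})

test_that("extraction agrees with a brute-force face oracle on random structures", {
  withr::with_seed(31, {
    for (rep in 1:60) {
      len <- sample(30:80, 1)
      db <- random_nested_db(len)
      s <- parse_dotbracket(db, random_sequence(len))
      expect_identical(package_loop_sigs(s), oracle_loops(db))
    }
  })
})

test_that("faces plus helices cover every position exactly once", {
  withr::with_seed(32, {
    for (rep in 1:25) {
      len <- sample(30:70, 1)
      db <- random_nested_db(len)
      s <- parse_dotbracket(db, random_sequence(len))
      l <- extract_loops(s, keep_dropped = TRUE)
      paired <- c(s$pairs$i, s$pairs$j)
      face_pos <- unlist(l$positions)
      exterior <- setdiff(seq_len(len), c(paired, face_pos))
      # no overlaps, full coverage
      expect_equal(sort(unname(c(paired, face_pos, exterior))), seq_len(len))
      expect_equal(anyDuplicated(c(paired, face_pos)), 0L)
      # exterior positions are genuinely outside every pair
      p <- integer(len); p[s$pairs$i] <- s$pairs$j; p[s$pairs$j] <- s$pairs$i
      for (e in exterior) {
        expect_false(any(s$pairs$i < e & e < s$pairs$j & !s$pairs$pk))
      }
    }
  })
})
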