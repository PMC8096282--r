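test_that("dot-bracket parsing handles nesting, pseudoknot layers and errors", {
  s <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
  expect_equal(s$pairs$i, 1:4)
  expect_equal(s$pairs$j, c(12, 11, 10, 9))
  expect_false(any(s$pairs$pk))

  s2 <- parse_dotbracket("((..[[..))..]]", "GGAAGGAACCAACC")
  pk <- s2$pairs[s2$pairs$pk, ]
  # LIFO bracket matching: the pseudoknot helix is (5,14),(6,13)
  expect_equal(pk$i, c(5, 6))
  expect_equal(pk$j, c(14, 13))
  # brute-force crossing check: pk pairs cross some nested pair
  nested <- s2$pairs[!s2$pairs$pk, ]
  crosses <- function(a, b) a[1] < b[1] && b[1] < a[2] && a[2] < b[2]
  for (r in seq_len(nrow(pk))) {
    expect_true(any(sapply(seq_len(nrow(nested)), function(q) {
      crosses(c(nested$i[q], nested$j[q]), c(pk$i[r], pk$j[r])) ||
        crosses(c(pk$i[r], pk$j[r]), c(nested$i[q], nested$j[q]))
    })))
  }

  expect_equal(nrow(parse_dotbracket(".....", "AAAAA")$pairs), 0L)
  expect_error(parse_dotbracket("((..)", "AAAAA"), "position 1")
  expect_error(parse_dotbracket("(..))", "AAAAA"), "position 5")
  expect_error(parse_dotbracket("...", "AAAA"), "length")
  expect_error(parse_dotbracket("..x.", "AAAA"), "position 3")
})

test_that("dot-bracket writing round-trips random nested structures", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      len <- sample(20:80, 1)
      db <- random_nested_db(len)
      s <- parse_dotbracket(db, random_sequence(len))
      expect_identical(write_dotbracket(s), db)
    }
  })
})

test_that("CT parsing follows the 6-column convention and round-trips", {
  ct <- c("10 demo",
          sprintf("%d %s %d %d %d %d", 1:10,
                  strsplit("GGAAAAACCU", "")[[1]],
                  0:9, c(2:10, 0), c(9, 8, 0, 0, 0, 0, 0, 2, 1, 0), 1:10))
  s <- parse_ct(ct)
  expect_equal(s$sequence, "GGAAAAACCU")
  expect_equal(s$pairs$i, c(1, 2))
  expect_equal(s$pairs$j, c(9, 8))

  # "5 A 4 6 10 5": position 5 pairs with 10
  ct2 <- c("10", sprintf("%d A %d %d %d %d", 1:10, 0:9, c(2:10, 0),
                         c(0, 0, 0, 0, 10, 0, 0, 0, 0, 5), 1:10))
  expect_true(any(parse_ct(ct2)$pairs$i == 5 & parse_ct(ct2)$pairs$j == 10))

  withr::with_seed(8, {
    for (rep in 1:20) {
      len <- sample(20:60, 1)
      s0 <- parse_dotbracket(random_nested_db(len), random_sequence(len))
      s1 <- parse_ct(write_ct(s0))
      expect_equal(s1$pairs$i, s0$pairs$i)
      expect_equal(s1$pairs$j, s0$pairs$j)
    }
  })

  expect_error(parse_ct(c("3", "1 A 0 2 0 1", "1 A 0 2 0 1", "3 A 2 0 0 3")),
               "duplicate index")
  expect_error(parse_ct(c("2", "1 A 0 2 9 1", "2 A 1 0 0 2")), "out of range")
  expect_error(parse_ct(c("2", "1 A 0 2 x 1", "2 A 1 0 0 2")), "non-numeric")
})

test_that("CT input with crossing pairs lands them in the pseudoknot layer", {
  # pairs (1,8),(2,7) nested; (5,12),(6,11) cross them
  pair_of <- integer(14)
  pair_of[c(1, 2, 5, 6)] <- c(8, 7, 12, 11)
  pair_of[c(8, 7, 12, 11)] <- c(1, 2, 5, 6)
  ct <- c("14", sprintf("%d A %d %d %d %d", 1:14, 0:13, c(2:14, 0),
                        pair_of, 1:14))
  s <- parse_ct(ct)
  expect_equal(sum(s$pairs$pk), 2L)
  expect_setequal(s$pairs$i[s$pairs$pk], c(5, 6))
})

test_that("SHAPE profiles parse with the -999 missing sentinel", {
  p <- parse_shape(c("1 0.8", "2 -999", "3 0.1"))
  expect_equal(as.numeric(p), c(0.8, NA, 0.1))
  # absent index -> missing
  p2 <- parse_shape(c("1 0.5", "3 0.2"), length = 4)
  expect_equal(which(is.na(p2)), c(2L, 4L))
  expect_error(parse_shape(c("1 0.5", "1 0.2")), "line 2.*duplicate")
  expect_error(parse_shape(c("1 0.5", "2 abc")), "line 2.*non-numeric")
  expect_error(parse_shape("0 0.5"), "out of range")

  tmp <- withr::local_tempfile(fileext = ".shape")
  write_shape(p, tmp)
  expect_equal(as.numeric(read_shape(tmp)), as.numeric(p))
})

test_that("multi-structure dot-bracket files read and write", {
  tmp <- withr::local_tempfile(fileext = ".db")
  a <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
  b <- parse_dotbracket("....((((....))))", "AAAAGGGGAAAACCCC")
  write_structures(list(first = a, second = b), tmp)
  got <- read_structures(tmp)
  expect_named(got, c("first", "second"))
  expect_true(all(got$first$pairs$i == a$pairs$i))
  # sequence line optional after the first record
  writeLines(c(">x", "GGGGAAAACCCC", "((((....))))",
               ">y", "(((......)))"), tmp)
  got2 <- read_structures(tmp)
  expect_equal(got2$y$sequence, "GGGGAAAACCCC")
  expect_equal(nrow(got2$y$pairs), 3L)
})

test_that("structure invariants are enforced", {
  expect_error(rna_structure("ACGU", cbind(1, 1)), "itself")
  expect_error(rna_structure("ACGU", cbind(1, 9)), "out of range")
  expect_error(rna_structure("ACGUACGU", rbind(c(1, 8), c(1, 5))),
               "more than one pair")
  expect_warning(rna_structure("AAAAAAAA", cbind(1, 8)), "non-canonical")
})
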