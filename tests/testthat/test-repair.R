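# Levenshtein distance and closest-match repair

test_that("edit distance matches the base-R DP oracle and the metric axioms", {
  expect_equal(edit_distance("", "XO"), 2L)
  expect_equal(edit_distance("XOX", "XOO"), 1L)
  set.seed(421)
  alphabet <- c("X", "O", ".")
  rand_str <- function(n) paste(sample(alphabet, n, replace = TRUE), collapse = "")
  a <- vapply(sample(0:30, 400, replace = TRUE), rand_str, character(1))
  b <- vapply(sample(0:30, 400, replace = TRUE), rand_str, character(1))
  c3 <- vapply(sample(0:30, 400, replace = TRUE), rand_str, character(1))
  dab <- mapply(edit_distance, a, b)
  expect_equal(unname(dab), as.integer(mapply(function(x, y) adist(x, y), a, b)))
  # identity, symmetry, triangle inequality
  expect_true(all(mapply(edit_distance, a, a) == 0L))
  expect_equal(unname(mapply(edit_distance, b, a)), unname(dab))
  dac <- mapply(edit_distance, a, c3)
  dcb <- mapply(edit_distance, c3, b)
  expect_true(all(dab <= dac + dcb))
  expect_true(all(dab[a != b] > 0L))
})

test_that("lexicon members repair to themselves", {
  lex <- assay_lexicon("mouse")
  for (e in lex$entries[seq(1, length(lex$entries), by = 5)]) {
    out <- repair_table(e, lex)
    expect_equal(out$corrected, e)
    expect_equal(out$distance, 0L)
    expect_false(out$ambiguous)
    expect_true(out$accepted)
  }
})

test_that("single-cell corruptions with a unique nearest neighbour are restored", {
  lex <- assay_lexicon("human_mdt")  # smallest lexicon keeps this quick
  entries <- lex$entries
  set.seed(77)
  restored <- 0L; unique_cases <- 0L
  for (e in entries[seq(1, length(entries), by = 3)]) {
    ch <- strsplit(e, "")[[1]]
    pos <- sample(seq_along(ch), 8)  # sampled positions; full sweep in acceptance
    for (p in pos) for (alt in setdiff(c("X", "O", "."), ch[p])) {
      corrupted <- ch; corrupted[p] <- alt
      cs <- paste(corrupted, collapse = "")
      if (cs %in% entries) next
      out <- repair_table(cs, lex)
      expect_lte(out$distance, 1L)
      expect_true(out$accepted)
      if (!out$ambiguous) {
        unique_cases <- unique_cases + 1L
        expect_equal(out$corrected, e)
        restored <- restored + 1L
      }
    }
  }
  expect_gt(unique_cases, 50L)
  expect_equal(restored, unique_cases)
})

test_that("ties are flagged ambiguous and resolved deterministically", {
  lex <- assay_lexicon("mouse")
  entries <- lex$entries
  # brute-force search for an observed string equidistant from >= 2 entries
  found <- NULL
  for (e in entries) {
    ch <- strsplit(e, "")[[1]]
    for (p in which(ch != ".")) {
      cand <- ch; cand[p] <- "."
      cs <- paste(cand, collapse = "")
      if (cs %in% entries) next
      out <- repair_table(cs, lex)
      if (out$ambiguous) { found <- cs; break }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  o1 <- repair_table(found, lex)
  o2 <- repair_table(found, lex)
  expect_true(o1$ambiguous)
  expect_identical(o1, o2)
  expect_true(o1$corrected %in% entries)
})

test_that("confidence steers tie-breaking toward uncertain cells", {
  lex <- assay_lexicon("mouse")
  e <- lex$entries[1]
  n <- nchar(e)
  # corrupt one cell; claim the corrupted position is the least confident
  ch <- strsplit(e, "")[[1]]
  p <- which(ch == "X")[1]
  ch[p] <- "O"
  cs <- paste(ch, collapse = "")
  conf <- rep(1, n); conf[p] <- 0
  out <- repair_table(cs, lex, confidence = conf)
  expect_true(out$accepted)
  expect_lte(out$distance, 1L)
})

test_that("the acceptance cutoff rejects garbage", {
  lex <- assay_lexicon("mouse")
  junk <- strrep("X", 45)
  out <- repair_table(junk, lex, cutoff = 3L)
  expect_false(out$accepted)
  expect_gt(out$distance, 3L)
  expect_error(repair_table("X", structure(list(entries = character(0)),
                                           class = "valid_lexicon")),
               class = "updown_config")
})
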