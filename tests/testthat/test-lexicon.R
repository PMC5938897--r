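# enumeration of legal tables and its invariants

test_that("encoding round-trips and trivial encodings", {
  expect_equal(encode_table(response_table("mouse")), strrep(".", 45))
  tb <- response_table("mouse")
  tb$cells[1, 5] <- "X"
  expect_equal(encode_table(tb),
               paste0(strrep(".", 4), "X", strrep(".", 40)))
  for (a in c("mouse", "human_mdt")) {
    lex <- assay_lexicon(a)
    for (e in lex$entries[seq(1, length(lex$entries), by = 7)])
      expect_equal(encode_table(decode_table(e, a)), e)
  }
})

test_that("enumeration equals the protocol image over all outcome vectors", {
  for (a in updown_assays()) {
    lex <- enumerate_valid_tables(build_ladder(a))
    expect_identical(lex$entries, protocol_image(build_ladder(a)), label = a)
  }
})

test_that("lexicon sizes are stable (regression fixture)", {
  sizes <- vapply(updown_assays(),
                  function(a) length(assay_lexicon(a)$entries), integer(1))
  expect_equal(unname(sizes), c(122L, 122L, 106L, 121L))
})

test_that("every lexicon entry is grammatical and within the mark budget", {
  for (a in updown_assays()) {
    lex <- assay_lexicon(a)
    marks <- nchar(gsub(".", "", lex$entries, fixed = TRUE))
    expect_lte(max(marks), 12L)  # the over-marking gate never rejects legal tables
    if (a == "mouse") expect_equal(range(marks), c(5L, 9L))
    for (e in lex$entries) {
      s <- table_to_sequence(decode_table(e, a))
      expect_s3_class(s, "trial_sequence")
    }
  }
})

test_that("thresholds over the full lexicon stay inside the kappa bounds", {
  kt <- load_kappa_table()
  kmax <- max(abs(kt))
  for (a in updown_assays()) {
    lad <- build_ladder(a)
    lex <- assay_lexicon(a)
    lo <- min(lad$forces_g) * 10^(-kmax * lad$delta)
    hi <- max(lad$forces_g) * 10^(kmax * lad$delta)
    for (e in lex$entries) {
      res <- compute_threshold(table_to_sequence(decode_table(e, a)), lad, kt)
      expect_gte(res$threshold_g, lo * (1 - 1e-12))
      expect_lte(res$threshold_g, hi * (1 + 1e-12))
    }
  }
})

test_that("complement symmetry: log thresholds differ by exactly 2*kappa*delta", {
  # complementing every response mirrors the staircase around the start
  # filament: kappa flips sign, and whenever the mirrored run is legal and
  # ends on the same (= start) filament, the two log thresholds must differ
  # by exactly 2*kappa*delta
  kt <- load_kappa_table()
  lad <- build_ladder("mouse")
  lex <- assay_lexicon("mouse")
  checked_kappa <- 0L; checked_diff <- 0L
  for (e in lex$entries) {
    s <- table_to_sequence(decode_table(e, "mouse"))
    if (!s$completed) next
    comp <- ifelse(s$trials$response == "X", FALSE, TRUE)
    res <- run_protocol(NULL, lad, responder = vector_responder(comp))
    sc <- res$sequence
    if (!sc$completed || nrow(sc$trials) != nrow(s$trials)) next
    expect_equal(sc$trials$response,
                 chartr("XO", "OX", s$trials$response))
    r <- compute_threshold(s, lad, kt)
    rc <- compute_threshold(sc, lad, kt)
    expect_equal(rc$kappa_used, -r$kappa_used, tolerance = 1e-6)
    checked_kappa <- checked_kappa + 1L
    if (identical(r$final_force_g, rc$final_force_g)) {
      expect_equal(log10(r$threshold_g) - log10(rc$threshold_g),
                   2 * r$kappa_used * lad$delta, tolerance = 1e-6)
      checked_diff <- checked_diff + 1L
    }
  }
  expect_gt(checked_kappa, 20L)
  expect_gt(checked_diff, 0L)
})

test_that("lexicon persists as plain text and round-trips", {
  lex <- assay_lexicon("rat")
  path <- tempfile(fileext = ".txt")
  save_lexicon(lex, path)
  back <- load_lexicon(path)
  expect_identical(back$entries, lex$entries)
  expect_identical(back$fingerprint, lex$fingerprint)
  # fingerprint guards against edited files
  lines <- readLines(path)
  lines[5] <- chartr("XO", "OX", lines[5])
  writeLines(lines, path)
  expect_error(load_lexicon(path), class = "updown_parse")
})
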