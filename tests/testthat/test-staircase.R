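# ladders, log-unit conversion and the Dixon formula

test_that("ladders match the published ranges, starts and deltas", {
  mouse <- build_ladder("mouse")
  expect_equal(range(mouse$forces_g), c(0.04, 4))
  expect_equal(mouse$forces_g[mouse$start_index], 0.6)
  expect_equal(mouse$delta, 0.25)
  expect_equal(mouse$delta_mean, 0.25, tolerance = 1e-9)

  rat <- build_ladder("rat")
  expect_equal(range(rat$forces_g), c(0.6, 15))
  expect_equal(rat$forces_g[rat$start_index], 4)
  expect_equal(rat$delta, 0.17)
  expect_equal(round(rat$delta_mean, 2), 0.17)

  mdt <- build_ladder("human_mdt")
  expect_equal(range(mdt$forces_g), c(0.02, 1.4))
  expect_equal(mdt$forces_g[mdt$start_index], 0.4)
  expect_equal(mdt$delta, 0.25)

  mpt <- build_ladder("human_mpt")
  expect_equal(range(mpt$forces_g), c(4, 180))
  expect_equal(mpt$forces_g[mpt$start_index], 8)
  expect_equal(mpt$delta, 0.21)
  expect_equal(round(mpt$delta_mean, 2), 0.21)

  for (a in updown_assays()) {
    lad <- build_ladder(a)
    expect_true(all(diff(lad$forces_g) > 0))
    expect_equal(lad$n_filaments, length(lad$forces_g))
    expect_equal(lad$log_units, log10(10000 * lad$forces_g), tolerance = 1e-9)
    expect_true(lad$start_index >= 1 && lad$start_index <= lad$n_filaments)
  }
  expect_error(build_ladder("gerbil"), class = "updown_unsupported_assay")
})

test_that("gram-force conversions", {
  expect_equal(grams_to_log_units(0.0001), 0)
  expect_equal(grams_to_log_units(1), 4)
  # closed form log10(6000), cross-checked against an independent
  # evaluation: 3.7781512503836436
  expect_equal(grams_to_log_units(0.6), 3.77815125, tolerance = 1e-8)
  expect_error(grams_to_log_units(0), class = "updown_domain")
  expect_error(grams_to_log_units(-1), class = "updown_domain")
  # printed mN endpoints: mouse 39.2, rat 5.88-147
  expect_equal(grams_to_mN(4), 39.2, tolerance = 1e-3)
  expect_equal(grams_to_mN(15), 147, tolerance = 2e-3)
  expect_equal(grams_to_mN(0.6), 5.88, tolerance = 1e-3)
})

test_that("kappa = 0 makes the threshold the final filament force", {
  for (a in updown_assays()) {
    lad <- build_ladder(a)
    for (f in lad$forces_g)
      expect_equal(dixon_threshold(f, 0, lad$delta), f, tolerance = 1e-12)
  }
})

test_that("thresholds for completed, out-of-range and invalid sequences", {
  kt <- load_kappa_table()
  s <- table_to_sequence(example_mouse_table())
  res <- compute_threshold(s)
  expect_equal(res$status, "OK")
  expect_equal(res$final_force_g, 0.4)
  expect_equal(res$pattern, "XOXOXO")
  expect_equal(res$kappa_used, 0.5, tolerance = 1e-6)
  # 0.4 x 10^(kappa("XOXOXO") * 0.25)
  expect_equal(res$threshold_g, 0.4 * 10^(kappa_lookup(kt, "XOXOXO") * 0.25),
               tolerance = 1e-12)

  oh <- compute_threshold(table_to_sequence(oor_high_mouse_table()))
  expect_equal(oh$status, "OOR_HIGH")
  expect_equal(oh$threshold_g, 4)

  tb <- response_table("mouse")
  tb$cells[1, 5:1] <- "X"  # sensitive beyond the weakest filament
  ol <- compute_threshold(table_to_sequence(tb))
  expect_equal(ol$status, "OOR_LOW")
  expect_equal(ol$threshold_g, 0.04)

  inv <- invalid_threshold("overmarked")
  expect_equal(inv$status, "INVALID")
  expect_true(is.na(inv$threshold_g))
})

test_that("missing kappa patterns are an error, not a silent default", {
  kt <- load_kappa_table()
  crippled <- kt[names(kt) != "XOXOXO"]
  class(crippled) <- "kappa_table"
  s <- table_to_sequence(example_mouse_table())
  expect_error(compute_threshold(s, kappa = crippled),
               class = "updown_missing_kappa")
})

test_that("validity gate: boundary at 12 marks, empty tables pass the gate", {
  tb <- response_table("mouse")
  cells <- which(matrix(TRUE, 5, 9))
  tb$cells[cells[1:12]] <- "X"
  expect_equal(count_marks(tb), 12L)
  expect_equal(validity_gate(tb), "VALID")
  tb$cells[cells[13]] <- "O"
  expect_equal(validity_gate(tb), "INVALID_OVERMARKED")
  empty <- response_table("mouse")
  expect_equal(count_marks(empty), 0L)
  expect_equal(validity_gate(empty), "VALID")
  full <- response_table("mouse", matrix("X", 5, 9))
  expect_equal(count_marks(full), 45L)
  expect_equal(validity_gate(full), "INVALID_OVERMARKED")
  # the grammar-minimal insensitive table of the figure example
  expect_equal(count_marks(oor_high_mouse_table()), 5L)
})
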