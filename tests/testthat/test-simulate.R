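# psychometric subjects, protocol execution, synthetic rendering

test_that("deterministic responders step at the threshold", {
  s <- simulated_subject(0.6, 0)
  expect_equal(respond(s, 0.6), "X")   # boundary convention: >= threshold
  expect_equal(respond(s, 0.59), "O")
  expect_equal(respond(s, 4), "X")
  expect_error(simulated_subject(-1), class = "updown_domain")
  expect_error(simulated_subject(1, -0.1), class = "updown_domain")
})

test_that("at threshold the positive rate converges to one half", {
  s <- simulated_subject(0.6, 0.2)
  hits <- with_seed(123,
    mean(vapply(1:10000, function(i) respond(s, 0.6) == "X", logical(1))))
  expect_equal(hits, 0.5, tolerance = 0.02)
})

test_that("deterministic staircases follow the hand-traced paths", {
  lad <- build_ladder("mouse")
  # insensitive mouse: threshold above the strongest filament
  res <- run_protocol(simulated_subject(10, 0, seed = 1), lad)
  expect_equal(res$sequence$termination, "OOR_HIGH")
  expect_equal(nrow(res$sequence$trials), 5L)
  expect_equal(res$table$cells[1, 5:9], rep("O", 5))
  expect_equal(sum(res$table$cells != "."), 5L)
  # threshold 0.5 g: X at 0.6, then alternation between 0.4 and 0.6
  res2 <- run_protocol(simulated_subject(0.5, 0, seed = 1), lad)
  expect_equal(res2$sequence$trials$index, c(5L, 4L, 5L, 4L, 5L, 4L))
  expect_equal(res2$sequence$trials$response, c("X", "O", "X", "O", "X", "O"))
  expect_equal(res2$sequence$termination, "COMPLETED")
})

test_that("sequence and table stay mutually consistent across random subjects", {
  lad <- build_ladder("mouse")
  lex <- assay_lexicon("mouse")
  for (i in 1:300) {
    thr <- with_seed(5000 + i, 10^runif(1, log10(0.02), log10(8)))
    res <- run_protocol(simulated_subject(thr, 0.15, seed = 5000 + i), lad)
    expect_true(encode_table(res$table) %in% lex$entries)
    s2 <- table_to_sequence(res$table, lad)
    expect_equal(s2$trials, res$sequence$trials)
    expect_equal(s2$termination, res$sequence$termination)
  }
})

test_that("deterministic subjects are recovered within one ladder step", {
  kt <- load_kappa_table()
  for (a in updown_assays()) {
    lad <- build_ladder(a)
    step <- max(diff(lad$log_units))
    # true thresholds strictly inside the ladder
    for (thr in exp(log(10) * seq(lad$log_units[2] - 4 + 0.02,
                                  lad$log_units[lad$n_filaments - 1] - 4 - 0.02,
                                  length.out = 17))) {
      res <- run_protocol(simulated_subject(thr, 0, seed = 1), lad)
      est <- compute_threshold(res$sequence, lad, kt)
      expect_lte(abs(log10(est$threshold_g) - log10(thr)), step + 1e-9,
                 label = sprintf("%s thr=%g", a, thr))
    }
  }
})

test_that("stochastic subjects are recovered within delta in the median", {
  kt <- load_kappa_table()
  lad <- build_ladder("mouse")
  for (thr in c(0.1, 0.3, 0.6, 1.2)) {
    est <- vapply(1:200, function(i) {
      res <- run_protocol(simulated_subject(thr, 0.1, seed = 20000 + i), lad)
      log10(compute_threshold(res$sequence, lad, kt)$threshold_g)
    }, numeric(1))
    expect_lte(abs(median(est) - log10(thr)), 0.25,
               label = sprintf("thr=%g", thr))
  }
})

test_that("rendered sheets are deterministic and confined to their boxes", {
  lay <- build_sheet_layout("mouse")
  lad <- build_ladder("mouse")
  tabs <- lapply(1:20, function(i)
    run_protocol(simulated_subject(0.15 * i, 0.1, seed = 100 + i), lad)$table)
  r1 <- render_filled_sheet(tabs, lay, seed = 5, dpi = 100, noise = "nominal")
  r2 <- render_filled_sheet(tabs, lay, seed = 5, dpi = 100, noise = "nominal")
  expect_identical(r1$page$img, r2$page$img)
  # zero-noise render: ink outside the frame-bounded content only where drawn
  r0 <- render_filled_sheet(tabs, lay, seed = 5, dpi = 100, noise = "none")
  base <- render_layout_raster(lay, 100)$img
  extra <- which(r0$page$img < 128 & base >= 128, arr.ind = TRUE)
  boxes <- do.call(rbind, lapply(lay$tables, function(tb) {
    rr <- updown:::px_range(tb$box_mm[["y0"]], tb$box_mm[["y1"]], 100, nrow(base))
    cc <- updown:::px_range(tb$box_mm[["x0"]], tb$box_mm[["x1"]], 100, ncol(base))
    c(rr, cc)
  }))
  inside <- vapply(seq_len(nrow(extra)), function(k)
    any(extra[k, 1] >= boxes[, 1] & extra[k, 1] <= boxes[, 2] &
        extra[k, 2] >= boxes[, 3] & extra[k, 2] <= boxes[, 4]), logical(1))
  expect_true(all(inside))
  expect_error(render_filled_sheet(c(tabs, tabs[1]), lay, seed = 1),
               class = "updown_domain")
})

test_that("struck-out tables are detected and neighbours unaffected", {
  lay <- build_sheet_layout("mouse")
  lad <- build_ladder("mouse")
  tabs <- lapply(1:20, function(i)
    run_protocol(simulated_subject(0.4, 0.1, seed = 300 + i), lad)$table)
  r <- render_filled_sheet(tabs, lay, seed = 9, dpi = 150, noise = "none",
                           strike = 7L)
  rows <- process_document(list(r$page), "mouse")
  expect_equal(rows$threshold_g[7], "N/A")
  expect_equal(rows$flags[7], "overmarked")
  # the classifier sees more than 12 marked boxes in the struck table
  w <- locate_frame(r$page, lay)
  ext <- extract_cells(w, lay)
  expect_gte(sum(ext[[7]]$ink >= 0.02), 13L)
  # every unstruck neighbour still reads back exactly
  truth <- truth_strings(r$truth)
  expect_equal(rows$threshold_g[-7], truth[-7])
})
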