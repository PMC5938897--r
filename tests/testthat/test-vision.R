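# rasterization, frame location, cell extraction

test_that("A4 raster dimensions at 300 dpi", {
  lay <- build_sheet_layout("mouse")
  img <- render_layout_raster(lay, 300)
  expect_true(abs(nrow(img$img) - 3508) <= 2)
  expect_true(abs(ncol(img$img) - 2480) <= 2)
})

test_that("raster PDF and PGM round-trips preserve pages and pixels", {
  lay <- build_sheet_layout("rat")
  img <- render_layout_raster(lay, 100)
  pdf <- tempfile(fileext = ".pdf")
  write_scan_pdf(list(img$img, 255 - img$img, img$img), pdf)
  pages <- rasterize(pdf, dpi = 100)
  expect_length(pages, 3L)
  expect_equal(pages[[1]]$img, img$img)
  expect_equal(pages[[2]]$img, 255 - img$img)
  expect_equal(pages[[1]]$page, 1L)

  pgm <- tempfile(fileext = ".pgm")
  write_pgm(img$img, pgm)
  back <- read_pgm(pgm)
  expect_equal(back, round(img$img))
  expect_error(rasterize(tempfile(fileext = ".pdf")), class = "updown_input")
  junk <- tempfile(fileext = ".pdf")
  writeLines("not a pdf", junk)
  expect_error(rasterize(junk), class = "updown_input")
})

test_that("clean template render yields an identity-like warp", {
  lay <- build_sheet_layout("mouse")
  pg <- render_layout_raster(lay, 150)
  w <- locate_frame(pg, lay)
  expect_gte(w$residual, 0)
  fm <- lay$frame_mm
  expected <- rbind(c(fm[["x0"]], fm[["y0"]]), c(fm[["x1"]], fm[["y0"]]),
                    c(fm[["x1"]], fm[["y1"]]), c(fm[["x0"]], fm[["y1"]])) / 25.4 * 150
  expect_lt(max(abs(w$corners_px - expected)), 2)
})

test_that("known rotation and translation are recovered within 2 px", {
  lay <- build_sheet_layout("mouse")
  pg <- render_layout_raster(lay, 150)
  th <- 3 * pi / 180; tx <- 10; ty <- 6
  cx <- (ncol(pg$img) - 1) / 2; cy <- (nrow(pg$img) - 1) / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Tc <- matrix(c(1, 0, cx + tx, 0, 1, cy + ty, 0, 0, 1), 3, 3, byrow = TRUE)
  Tn <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  F <- Tc %*% R %*% Tn
  rotated <- updown:::cpp_warp(pg$img, solve(F), nrow(pg$img), ncol(pg$img), 255)
  w <- locate_frame(page_image(rotated, 150), lay)
  fm <- lay$frame_mm
  src <- rbind(c(fm[["x0"]], fm[["y0"]]), c(fm[["x1"]], fm[["y0"]]),
               c(fm[["x1"]], fm[["y1"]]), c(fm[["x0"]], fm[["y1"]])) / 25.4 * 150
  truth <- t(F %*% rbind(t(src), 1))[, 1:2]
  expect_lt(max(abs(w$corners_px - truth)), 2)
})

test_that("blank and noise-only pages raise frame-not-found", {
  lay <- build_sheet_layout("mouse")
  blank <- page_image(matrix(255, 800, 600), 72)
  expect_error(locate_frame(blank, lay), class = "updown_frame")
  set.seed(8)
  noisy <- page_image(matrix(pmin(pmax(rnorm(800 * 600, 250, 8), 0), 255), 800), 72)
  expect_error(locate_frame(noisy, lay), class = "updown_frame")
})

test_that("cell extraction recovers the full grid with clean patches", {
  lay <- build_sheet_layout("mouse")
  pg <- render_layout_raster(lay, 150)
  w <- locate_frame(pg, lay)
  ext <- extract_cells(w, lay)
  expect_length(ext, 20L)
  expect_equal(sum(vapply(ext, function(e) length(e$bin), integer(1))), 900L)
  expect_lt(max(vapply(ext, function(e) max(e$ink), numeric(1))), 0.01)
})

test_that("ink fraction endpoints", {
  expect_equal(ink_fraction(matrix(0, 10, 10)), 0)
  expect_equal(ink_fraction(matrix(1, 10, 10)), 1)
  o <- with_seed(5, updown:::draw_glyph("O", 30, 30, 1))
  f <- ink_fraction((o < 128) * 1)
  expect_gt(f, 0); expect_lt(f, 1)
})

test_that("frame recovery survives the scan-noise envelope", {
  lay <- build_sheet_layout("mouse")
  pg <- render_layout_raster(lay, 100)
  ok <- 0L
  n <- 100L
  for (i in seq_len(n)) {
    noisy <- with_seed(4000 + i,
      updown:::apply_scan_noise(pg$img, scan_noise_preset("envelope"), 100))
    w <- tryCatch(locate_frame(page_image(noisy, 100), lay),
                  updown_error = function(e) NULL)
    if (!is.null(w)) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.99)
})
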