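# Subject simulation, protocol execution and synthetic scan rendering.
#
# Subjects respond through a psychometric function: P(response at force f)
# = Phi((log10 f - log10 threshold) / sigma), a cumulative Gaussian in log
# force; sigma = 0 is the deterministic step "respond iff f >= threshold".

#' Construct a simulated subject
#' @param threshold_g true 50% threshold in grams (> 0).
#' @param slope_sigma psychometric slope in log10 units (>= 0; 0 =
#'   deterministic responder).
#' @param seed integer seed driving this subject's responses.
#' @return object of class `sim_subject`.
#' @export
simulated_subject <- function(threshold_g, slope_sigma = 0, seed = NULL) {
  if (!is.numeric(threshold_g) || threshold_g <= 0)
    stop_updown("updown_domain", "threshold_g must be positive")
  if (!is.numeric(slope_sigma) || slope_sigma < 0)
    stop_updown("updown_domain", "slope_sigma must be >= 0")
  structure(list(threshold_g = threshold_g, slope_sigma = slope_sigma,
                 seed = seed), class = "sim_subject")
}

#' Draw one response from a subject
#'
#' Uses the session RNG (wrap in [with_seed()] or rely on
#' [run_protocol()], which seeds from the subject).
#'
#' @param subject a `sim_subject`.
#' @param force_g applied force in grams.
#' @return `"X"` (positive) or `"O"` (negative).
#' @export
respond <- function(subject, force_g) {
  if (force_g <= 0) stop_updown("updown_domain", "force must be positive")
  if (subject$slope_sigma == 0)
    return(if (force_g >= subject$threshold_g) "X" else "O")
  p <- pnorm((log10(force_g) - log10(subject$threshold_g)) / subject$slope_sigma)
  if (runif(1) < p) "X" else "O"
}

#' Run the up-down protocol on a subject
#'
#' Executes the exact recording grammar: first trial at the mid-range
#' start filament, weaker after a positive, stronger after a negative; the
#' run up to and including the first response change fills row 1, the next
#' four trials fill rows 2-5; a negative at the strongest filament (or a
#' positive at the weakest) concludes the test out of range.
#'
#' @param subject a `sim_subject` (ignored when `responder` is given).
#' @param ladder a `filament_ladder`.
#' @param responder optional deterministic override: a function
#'   `(force_g, trial)` returning `"X"`/`"O"`; used to sweep outcome
#'   vectors in tests.
#' @return list with `sequence` (a `trial_sequence`) and `table` (the
#'   matching `response_table`).
#' @export
run_protocol <- function(subject, ladder, responder = NULL) {
  ask <- if (!is.null(responder)) responder
         else function(force_g, trial) respond(subject, force_g)
  body <- function() {
    n <- ladder$n_filaments
    cells <- matrix(".", 5, n)
    idx <- ladder$start_index
    indices <- integer(0); resp <- character(0)
    trial <- 0L
    r0 <- NULL; fcp <- NA_integer_; row <- 1L
    termination <- NULL
    repeat {
      trial <- trial + 1L
      r <- ask(ladder$forces_g[idx], trial)
      indices <- c(indices, idx); resp <- c(resp, r)
      cells[row, idx] <- r
      if (row == 1L) {
        if (is.null(r0)) r0 <- r
        if (r != r0) {          # first change: row 1 is complete
          fcp <- trial
          row <- 2L
          idx <- idx + if (r == "X") -1L else 1L
          next
        }
        if (r == "O" && idx == n) { termination <- "OOR_HIGH"; break }
        if (r == "X" && idx == 1L) { termination <- "OOR_LOW"; break }
        idx <- idx + if (r == "X") -1L else 1L
      } else {
        if (row == 5L) { termination <- "COMPLETED"; break }
        if (r == "O" && idx == n) { termination <- "OOR_HIGH"; break }
        if (r == "X" && idx == 1L) { termination <- "OOR_LOW"; break }
        row <- row + 1L
        idx <- idx + if (r == "X") -1L else 1L
      }
    }
    list(sequence = new_trial_sequence(indices, resp, fcp, termination,
                                       ladder$assay),
         table = response_table(ladder$assay, cells))
  }
  if (is.null(responder)) with_seed(subject$seed, body()) else body()
}

#' Scan-noise presets
#'
#' `none` renders geometrically clean pages; `nominal` is the default
#' synthetic scan (rotation up to 3 degrees, 2 mm translation, 2% scale
#' jitter, sigma = 8 gray-level noise); `envelope` is the robustness limit
#' (5 degrees, 5% scale).
#'
#' @param name preset name.
#' @return list with `rot_deg`, `trans_mm`, `scale_sd`, `gray_sd`.
#' @export
scan_noise_preset <- function(name = c("nominal", "none", "envelope")) {
  switch(match.arg(name),
    none = list(rot_deg = 0, trans_mm = 0, scale = 0, gray_sd = 0),
    nominal = list(rot_deg = 3, trans_mm = 2, scale = 0.02, gray_sd = 8),
    envelope = list(rot_deg = 5, trans_mm = 2, scale = 0.05, gray_sd = 8))
}

# affine page transform (scale, rotate about centre, translate) + noise.
# The output canvas is padded like a scanner bed slightly larger than the
# page, so an enlarging scale does not clip the fiducial frame.
apply_scan_noise <- function(img, noise, dpi) {
  if (noise$rot_deg == 0 && noise$trans_mm == 0 &&
      noise$scale == 0 && noise$gray_sd == 0) return(img)
  th <- runif(1, -noise$rot_deg, noise$rot_deg) * pi / 180
  tr <- runif(2, -noise$trans_mm, noise$trans_mm) * dpi / 25.4
  sc <- 1 + runif(1, -noise$scale, noise$scale)
  cx <- (ncol(img) - 1) / 2; cy <- (nrow(img) - 1) / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE) * c(sc, sc, 1)
  R[3, 3] <- 1
  Tc <- matrix(c(1, 0, cx + tr[1], 0, 1, cy + tr[2], 0, 0, 1), 3, 3, byrow = TRUE)
  Tn <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  pad <- if (noise$rot_deg > 0 || noise$scale > 0 || noise$trans_mm > 0)
    ceiling(0.08 * dim(img)) else c(0, 0)
  Tp <- matrix(c(1, 0, -pad[2], 0, 1, -pad[1], 0, 0, 1), 3, 3, byrow = TRUE)
  M <- solve(Tc %*% R %*% Tn) %*% Tp   # padded output -> source
  out <- cpp_warp(img, M, nrow(img) + 2 * pad[1], ncol(img) + 2 * pad[2], 255)
  if (noise$gray_sd > 0)
    out <- pmin(pmax(out + rnorm(length(out), 0, noise$gray_sd), 0), 255)
  out
}

# draw one table's marks into the page raster; uses current RNG
draw_table_marks <- function(img, tb, cells, dpi, jitter) {
  nc <- dim(tb$cells_mm)[2]
  for (r in 1:5) for (c in seq_len(nc)) {
    mark <- cells[r, c]
    if (mark == ".") next
    box <- tb$cells_mm[r, c, ]
    rr <- px_range(box[["y0"]], box[["y1"]], dpi, nrow(img))
    cc <- px_range(box[["x0"]], box[["x1"]], dpi, ncol(img))
    h <- rr[2] - rr[1] + 1L; w <- cc[2] - cc[1] + 1L
    m <- runif(4, 0.14, 0.24)   # glyph inset per side, fraction of cell
    gr0 <- rr[1] + round(m[1] * h); gr1 <- rr[2] - round(m[2] * h)
    gc0 <- cc[1] + round(m[3] * w); gc1 <- cc[2] - round(m[4] * w)
    if (gr1 - gr0 < 4 || gc1 - gc0 < 4) { gr0 <- rr[1] + 1; gr1 <- rr[2] - 1
                                          gc0 <- cc[1] + 1; gc1 <- cc[2] - 1 }
    g <- draw_glyph(mark, gr1 - gr0 + 1L, gc1 - gc0 + 1L, jitter)
    img[gr0:gr1, gc0:gc1] <- pmin(img[gr0:gr1, gc0:gc1], g)
  }
  img
}

#' Cross out a rendered table
#'
#' Draws a large X over the whole table box, the recommended way of voiding
#' a mis-recorded table; downstream the over-marking gate reports it N/A.
#'
#' @param img page raster matrix.
#' @param tb one table entry of a `sheet_layout`.
#' @param dpi render resolution.
#' @return the modified raster. Uses the current RNG for stroke jitter.
#' @export
strike_out_table <- function(img, tb, dpi) {
  bx <- tb$box_mm
  x0 <- mm2px(bx[["x0"]] + 1, dpi); x1 <- mm2px(bx[["x1"]] - 1, dpi)
  y0 <- mm2px(bx[["y0"]] + 1, dpi); y1 <- mm2px(bx[["y1"]] - 1, dpi)
  thick <- max(2, mm2px(0.8, dpi))
  jx <- function() runif(1, -mm2px(1, dpi), mm2px(1, dpi))
  img <- draw_thick_path(img, c(x0 + jx(), x1 + jx()), c(y0 + jx(), y1 + jx()), thick)
  img <- draw_thick_path(img, c(x0 + jx(), x1 + jx()), c(y1 + jx(), y0 + jx()), thick)
  img
}

#' Render a filled scoring sheet with known ground truth
#'
#' Draws the given response tables into a template render with
#' handwriting-style glyphs, optionally crosses out tables, applies the
#' scan-noise transform, and returns the page with a per-table ground-truth
#' record. Deterministic for a given seed.
#'
#' @param tables list of `response_table` objects (at most the sheet
#'   capacity; fewer leaves trailing slots empty).
#' @param layout the `sheet_layout` to render on.
#' @param seed integer seed.
#' @param dpi render resolution (default 150; see the methods vignette).
#' @param jitter glyph style jitter level (1 = nominal).
#' @param noise a preset name or list from [scan_noise_preset()].
#' @param strike integer indices of tables to cross out.
#' @return list with `page` (a `page_image`) and `truth` (per-slot list of
#'   `index`, `table`, `struck`, `expected` threshold result or `NULL` for
#'   empty slots).
#' @export
render_filled_sheet <- function(tables, layout, seed, dpi = 150, jitter = 1,
                                noise = "none", strike = integer(0)) {
  if (length(tables) > length(layout$tables))
    stop_updown("updown_domain", "sheet capacity is %d tables", length(layout$tables))
  if (is.character(noise)) noise <- scan_noise_preset(noise)
  base <- render_layout_raster(layout, dpi)
  img <- base$img
  truth <- vector("list", length(layout$tables))
  with_seed(seed, {
    for (i in seq_along(layout$tables)) {
      tb <- layout$tables[[i]]
      if (i <= length(tables) && !is.null(tables[[i]])) {
        stopifnot(identical(tables[[i]]$assay, tb$assay))
        img <- draw_table_marks(img, tb, tables[[i]]$cells, dpi, jitter)
        struck <- i %in% strike
        if (struck) img <- strike_out_table(img, tb, dpi)
        expected <- if (struck) invalid_threshold("overmarked")
          else compute_threshold(table_to_sequence(tables[[i]]))
        truth[[i]] <- list(index = i, table = tables[[i]], struck = struck,
                           expected = expected)
      } else {
        truth[[i]] <- list(index = i, table = NULL, struck = FALSE,
                           expected = NULL)
      }
    }
    img <- apply_scan_noise(img, noise, dpi)
  })
  list(page = page_image(img, dpi), truth = truth)
}

#' Build a complete synthetic scanned document
#'
#' Simulates subjects, runs the protocol, renders filled sheets and writes
#' a multi-page raster PDF plus a ground-truth JSON sidecar.
#'
#' @param kind sheet kind (`"mouse"`, `"rat"`, `"human"`).
#' @param n_tables total number of filled tables.
#' @param seed master seed (drives subjects, glyphs and scan noise).
#' @param thresholds_g true thresholds to cycle over; default spans the
#'   mid-range of each assay ladder.
#' @param slope_sigma psychometric slope of the simulated subjects.
#' @param noise scan-noise preset name or list.
#' @param dpi render resolution.
#' @param jitter glyph jitter level.
#' @param strike_rate fraction of tables crossed out (default 0).
#' @param pdf optional output PDF path.
#' @param truth_json optional ground-truth JSON path.
#' @return list with `pages` (list of `page_image`), `truth` (per page),
#'   and `layout`.
#' @export
synth_scan_document <- function(kind, n_tables, seed, thresholds_g = NULL,
                                slope_sigma = 0.1, noise = "nominal",
                                dpi = 150, jitter = 1, strike_rate = 0,
                                pdf = NULL, truth_json = NULL) {
  layout <- build_sheet_layout(kind)
  cap <- length(layout$tables)
  slots <- lapply(layout$tables, `[[`, "assay")
  made <- with_seed(seed, {
    tabs <- vector("list", n_tables)
    for (i in seq_len(n_tables)) {
      assay <- slots[[((i - 1) %% cap) + 1]]
      ladder <- build_ladder(assay)
      thr <- if (!is.null(thresholds_g)) thresholds_g[((i - 1) %% length(thresholds_g)) + 1]
        else with_seed(NULL, 10^runif(1, ladder$log_units[2] - 4,
                                      ladder$log_units[ladder$n_filaments - 1] - 4))
      subj <- simulated_subject(thr, slope_sigma,
                                seed = sample.int(2^31 - 1, 1))
      tabs[[i]] <- run_protocol(subj, ladder)$table
    }
    strikes <- if (strike_rate > 0)
      which(runif(n_tables) < strike_rate) else integer(0)
    page_seeds <- sample.int(2^31 - 1, ceiling(n_tables / cap))
    list(tabs = tabs, strikes = strikes, page_seeds = page_seeds)
  })
  npages <- ceiling(n_tables / cap)
  pages <- vector("list", npages)
  truth <- vector("list", npages)
  for (p in seq_len(npages)) {
    lo <- (p - 1) * cap + 1
    hi <- min(p * cap, n_tables)
    page_tabs <- made$tabs[lo:hi]
    page_strikes <- made$strikes[made$strikes >= lo & made$strikes <= hi] - lo + 1L
    r <- render_filled_sheet(page_tabs, layout, seed = made$page_seeds[p],
                             dpi = dpi, jitter = jitter, noise = noise,
                             strike = page_strikes)
    r$page$page <- p
    pages[[p]] <- r$page
    truth[[p]] <- r$truth
  }
  if (!is.null(pdf)) {
    # the scan canvas may be padded beyond the page; size the media box to
    # the actual raster so round-tripped dpi stays exact
    first <- pages[[1]]$img
    write_scan_pdf(lapply(pages, `[[`, "img"), pdf,
                   page_mm = c(width = ncol(first) * 25.4 / dpi,
                               height = nrow(first) * 25.4 / dpi))
  }
  if (!is.null(truth_json)) {
    ser <- lapply(seq_along(truth), function(p) lapply(truth[[p]], function(t)
      if (is.null(t$table)) list(page = p, index = t$index, empty = TRUE)
      else list(page = p, index = t$index, empty = FALSE, struck = t$struck,
                assay = t$table$assay, encoded = encode_table(t$table),
                status = t$expected$status,
                threshold_g = if (is.na(t$expected$threshold_g)) "N/A"
                              else t$expected$threshold_g)))
    jsonlite::write_json(ser, truth_json, auto_unbox = TRUE, digits = NA)
  }
  list(pages = pages, truth = truth, layout = layout)
}
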