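# Locating the fiducial frame, perspective correction, cell extraction.

# 4-point DLT homography: maps src (x,y) to dst (x,y); h33 = 1
fit_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, xy) {
  p <- H %*% rbind(t(xy), 1)
  t(p[1:2, , drop = FALSE] / rep(p[3, ], each = 2))
}

# order 4 points TL, TR, BR, BL by the diagonal extremes
order_corners <- function(pts) {
  s <- pts[, 1] + pts[, 2]
  d <- pts[, 1] - pts[, 2]
  rbind(TL = pts[which.min(s), ], TR = pts[which.max(d), ],
        BR = pts[which.max(s), ], BL = pts[which.min(d), ])
}

# Sub-pixel corner refinement: least-squares lines through the outer edge
# pixels of the four border bands (rows/cols in the middle 80% of the
# frame, where a scan line crosses only the two opposite bands), then line
# intersections. Falls back to the extreme-pixel corners when a fit is
# degenerate.
refine_corners <- function(pts, rough) {
  yr <- range(pts[, 2]); xr <- range(pts[, 1])
  ymid <- pts[, 2] >= yr[1] + 0.1 * diff(yr) & pts[, 2] <= yr[2] - 0.1 * diff(yr)
  xmid <- pts[, 1] >= xr[1] + 0.1 * diff(xr) & pts[, 1] <= xr[2] - 0.1 * diff(xr)
  # extreme ink-pixel centres sit half a pixel inside the true border
  # edge; shift by 0.5 px so the fitted line is the outer edge itself
  fit_v <- function(side, off) {  # x = a + b*y over per-row extreme x
    p <- pts[ymid, , drop = FALSE]
    x <- tapply(p[, 1], p[, 2], side) + off
    y <- as.numeric(names(x))
    if (length(x) < 20) return(NULL)
    cf <- stats::lm.fit(cbind(1, y), as.numeric(x))$coefficients
    c(a = cf[1], b = cf[2])  # x = a + b*y
  }
  fit_h <- function(side, off) {  # y = a + b*x over per-col extreme y
    p <- pts[xmid, , drop = FALSE]
    y <- tapply(p[, 2], p[, 1], side) + off
    x <- as.numeric(names(y))
    if (length(y) < 20) return(NULL)
    cf <- stats::lm.fit(cbind(1, x), as.numeric(y))$coefficients
    c(a = cf[1], b = cf[2])  # y = a + b*x
  }
  L <- fit_v(min, -0.5); R <- fit_v(max, 0.5)
  T <- fit_h(min, -0.5); B <- fit_h(max, 0.5)
  if (is.null(L) || is.null(R) || is.null(T) || is.null(B)) return(rough)
  meet <- function(v, h) {  # x = va + vb*y with y = ha + hb*x
    x <- (v[1] + v[2] * h[1]) / (1 - v[2] * h[2])
    c(x, h[1] + h[2] * x)
  }
  ref <- rbind(TL = meet(L, T), TR = meet(R, T),
               BR = meet(R, B), BL = meet(L, B))
  colnames(ref) <- c("x", "y")
  if (any(!is.finite(ref)) || max(abs(ref - rough)) > 10) return(rough)
  ref
}

quad_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * y[c(2:4, 1)] - x[c(2:4, 1)] * y)) / 2
}

#' Locate the fiducial frame and fit the page homography
#'
#' Binarizes the page (Otsu), takes the largest connected ink component
#' (the solid template border), finds its corners by diagonal extremes, and
#' fits the homography mapping layout millimetres to scan pixels. The page
#' is then deskewed to the canonical layout at the page's dpi.
#'
#' @param page a `page_image`.
#' @param layout the `sheet_layout` the page was printed from.
#' @return object of class `warp_result`: `H` (3x3, mm to px), `warped`
#'   (deskewed `page_image`), `residual` (px), `corners_px`.
#' @export
locate_frame <- function(page, layout) {
  img <- page$img
  ot <- otsu_threshold(img)
  ink <- img <= ot$threshold
  # reject pages with no real foreground/background separation (blank
  # pages: Otsu splits sensor noise and "ink" covers about half the page)
  if (ot$mu1 - ot$mu0 < 40 || mean(ink) > 0.3 || mean(ink) < 1e-4)
    stop_updown("updown_frame", "no fiducial frame found (page %s)",
                page$page %||% NA)
  f <- max(1L, floor(min(dim(img)) / 400))
  dh <- floor(nrow(img) / f); dw <- floor(ncol(img) / f)
  down <- resize_area(ink * 1, dh, dw) > 0
  comp <- cpp_largest_component(down)
  if (sum(comp) < 0.002 * length(comp))
    stop_updown("updown_frame", "no fiducial frame found (page %s)",
                page$page %||% NA)
  # dilate the component one block and collect full-res ink inside it
  dil <- comp
  dil[-1, ] <- dil[-1, ] | comp[-nrow(comp), ]
  dil[-nrow(dil), ] <- dil[-nrow(dil), ] | comp[-1, ]
  dil[, -1] <- dil[, -1] | dil[, -ncol(dil), drop = FALSE]
  dil[, -ncol(dil)] <- dil[, -ncol(dil)] | dil[, -1, drop = FALSE]
  idx <- which(ink, arr.ind = TRUE)
  bi <- pmin(dh, ceiling(idx[, 1] / (nrow(img) / dh)))
  bj <- pmin(dw, ceiling(idx[, 2] / (ncol(img) / dw)))
  keep <- dil[cbind(bi, bj)]
  pts <- cbind(x = idx[keep, 2] - 0.5, y = idx[keep, 1] - 0.5)
  if (nrow(pts) < 100)
    stop_updown("updown_frame", "no fiducial frame found (page %s)",
                page$page %||% NA)
  corners <- refine_corners(pts, order_corners(pts))
  if (quad_area(corners) < 0.3 * nrow(img) * ncol(img))
    stop_updown("updown_frame",
                "fiducial quadrilateral covers < 30%% of page %s", page$page %||% NA)
  fm <- layout$frame_mm
  src <- rbind(c(fm[["x0"]], fm[["y0"]]), c(fm[["x1"]], fm[["y0"]]),
               c(fm[["x1"]], fm[["y1"]]), c(fm[["x0"]], fm[["y1"]]))
  H <- fit_homography(src, corners)
  residual <- sqrt(mean(rowSums((apply_homography(H, src) - corners)^2)))
  dpi <- page$dpi
  out_w <- round(mm2px(layout$page_mm[["width"]], dpi))
  out_h <- round(mm2px(layout$page_mm[["height"]], dpi))
  # cpp_warp output coords are 0-based pixel indices: continuous position
  # is index + 0.5; compose index->mm->source px->source index
  pre <- matrix(c(25.4 / dpi, 0, 0.5 * 25.4 / dpi,
                  0, 25.4 / dpi, 0.5 * 25.4 / dpi,
                  0, 0, 1), 3, 3, byrow = TRUE)
  post <- matrix(c(1, 0, -0.5, 0, 1, -0.5, 0, 0, 1), 3, 3, byrow = TRUE)
  M <- post %*% H %*% pre
  warped <- cpp_warp(img, M, out_h, out_w, 255)
  structure(list(H = H, warped = page_image(warped, dpi, page = page$page),
                 residual = residual, corners_px = corners),
            class = "warp_result")
}

#' @export
print.warp_result <- function(x, ...) {
  cat(sprintf("<warp_result: residual %.3g px>\n", x$residual))
  invisible(x)
}

#' Extract binarized cell patches from a deskewed page
#'
#' Every cell box of every table is cropped from the warped image with an
#' inner margin (default 12% per side, removing printed grid lines) and
#' binarized with an adaptive mean threshold.
#'
#' @param warp a `warp_result`.
#' @param layout the matching `sheet_layout`.
#' @param inner_margin fraction of each cell trimmed per side.
#' @return list (one element per table) of `list(index, assay, bin, ink)`
#'   where `bin` is a 5 x ncol list-matrix of binary patches and `ink` the
#'   matching matrix of ink fractions.
#' @export
extract_cells <- function(warp, layout, inner_margin = 0.12) {
  img <- warp$warped$img
  dpi <- warp$warped$dpi
  lapply(layout$tables, function(tb) {
    nc <- dim(tb$cells_mm)[2]
    bin <- matrix(vector("list", 5 * nc), nrow = 5)
    ink <- matrix(0, 5, nc)
    for (r in 1:5) for (c in seq_len(nc)) {
      cell <- tb$cells_mm[r, c, ]
      mx <- (cell[["x1"]] - cell[["x0"]]) * inner_margin
      my <- (cell[["y1"]] - cell[["y0"]]) * inner_margin
      rr <- px_range(cell[["y0"]] + my, cell[["y1"]] - my, dpi, nrow(img))
      cc <- px_range(cell[["x0"]] + mx, cell[["x1"]] - mx, dpi, ncol(img))
      patch <- img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
      b <- binarize_patch(patch)
      bin[[r, c]] <- b
      ink[r, c] <- ink_fraction(b)
    }
    list(index = tb$index, assay = tb$assay, bin = bin, ink = ink)
  })
}
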