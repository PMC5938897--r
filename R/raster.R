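# Grayscale raster primitives. Pages are numeric matrices in [0, 255]
# (255 = paper white), row = y, column = x, 1-based; the continuous centre
# of pixel (i, j) is (x = j - 0.5, y = i - 0.5) in pixel units.

#' Construct a page image
#' @param img numeric matrix in `[0, 255]`.
#' @param dpi dots per inch (> 0).
#' @param page source page index.
#' @return object of class `page_image`.
#' @export
page_image <- function(img, dpi, page = NA_integer_) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_updown("updown_domain", "img must be a numeric matrix")
  if (!is.numeric(dpi) || dpi <= 0)
    stop_updown("updown_domain", "dpi must be positive")
  structure(list(img = img, dpi = dpi, page = page), class = "page_image")
}

#' @export
print.page_image <- function(x, ...) {
  cat(sprintf("<page_image: %d x %d px at %g dpi>\n",
              nrow(x$img), ncol(x$img), x$dpi))
  invisible(x)
}

mm2px <- function(mm, dpi) mm / 25.4 * dpi

# pixel index range covered by a half-open mm interval
px_range <- function(mm0, mm1, dpi, nmax) {
  lo <- floor(mm2px(mm0, dpi)) + 1L
  hi <- floor(mm2px(mm1, dpi))
  c(max(1L, lo), min(nmax, hi))
}

fill_rect_px <- function(img, r0, r1, c0, c1, value = 0) {
  if (r1 >= r0 && c1 >= c0) img[r0:r1, c0:c1] <- value
  img
}

fill_rect_mm <- function(img, rect, dpi, value = 0) {
  rr <- px_range(rect[["y0"]], rect[["y1"]], dpi, nrow(img))
  cc <- px_range(rect[["x0"]], rect[["x1"]], dpi, ncol(img))
  fill_rect_px(img, rr[1], rr[2], cc[1], cc[2], value)
}

# mark all pixels within `thickness/2` of the polyline sampled at
# (xs, ys) (pixel units, continuous coords); cheap dilated-path drawing
draw_thick_path <- function(img, xs, ys, thickness, value = 0) {
  step <- max(0.5, thickness / 3)
  px <- numeric(0); py <- numeric(0)
  for (i in seq_len(length(xs) - 1)) {
    len <- sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2)
    m <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = m)
    px <- c(px, xs[i] + t * (xs[i + 1] - xs[i]))
    py <- c(py, ys[i] + t * (ys[i + 1] - ys[i]))
  }
  r <- thickness / 2
  off <- expand.grid(dx = seq(-ceiling(r), ceiling(r)),
                     dy = seq(-ceiling(r), ceiling(r)))
  off <- off[off$dx^2 + off$dy^2 <= max(r, 0.71)^2, , drop = FALSE]
  ci <- as.vector(outer(round(px + 0.5), off$dx, `+`))
  ri <- as.vector(outer(round(py + 0.5), off$dy, `+`))
  keep <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
  img[cbind(ri[keep], ci[keep])] <- value
  img
}

# 5x7 bitmap font for force labels (digits, dot, dash, g)
.font5x7 <- local({
  rows <- function(...) matrix(as.integer(strsplit(paste0(...), "")[[1]]) , 7, 5, byrow = TRUE)
  list(
    "0" = rows("01110","10001","10011","10101","11001","10001","01110"),
    "1" = rows("00100","01100","00100","00100","00100","00100","01110"),
    "2" = rows("01110","10001","00001","00110","01000","10000","11111"),
    "3" = rows("01110","10001","00001","00110","00001","10001","01110"),
    "4" = rows("00010","00110","01010","10010","11111","00010","00010"),
    "5" = rows("11111","10000","11110","00001","00001","10001","01110"),
    "6" = rows("00110","01000","10000","11110","10001","10001","01110"),
    "7" = rows("11111","00001","00010","00100","01000","01000","01000"),
    "8" = rows("01110","10001","10001","01110","10001","10001","01110"),
    "9" = rows("01110","10001","10001","01111","00001","00010","01100"),
    "." = rows("00000","00000","00000","00000","00000","01100","01100"),
    "-" = rows("00000","00000","00000","01110","00000","00000","00000"),
    "g" = rows("00000","00000","01111","10001","01111","00001","01110"))
})

# pixel rectangles (r0, r1, c0, c1) covering a string with top-left corner
# at (x_px, y_px); glyph cell is 6*scale x 7*scale px
text_rects <- function(x_px, y_px, text, scale = 1L) {
  chars <- strsplit(text, "")[[1]]
  x <- round(x_px)
  out <- list()
  for (ch in chars) {
    gl <- .font5x7[[ch]]
    if (!is.null(gl)) {
      on <- which(gl == 1L, arr.ind = TRUE)
      for (k in seq_len(nrow(on))) {
        r0 <- round(y_px) + (on[k, 1] - 1L) * scale + 1L
        c0 <- x + (on[k, 2] - 1L) * scale + 1L
        out[[length(out) + 1L]] <- c(r0, r0 + scale - 1L, c0, c0 + scale - 1L)
      }
    }
    x <- x + 6L * scale
  }
  out
}

format_force_label <- function(g) sub("^0\\.", ".", format(g, trim = TRUE))

#' Render a sheet layout as a page raster
#'
#' Draws the fiducial border, table grids and per-column force labels into
#' a white page at the requested resolution. This is both the printable
#' template content and the base canvas for synthetic filled sheets.
#'
#' @param layout a `sheet_layout`.
#' @param dpi resolution.
#' @return a `page_image`.
#' @export
render_layout_raster <- function(layout, dpi = 300) {
  w <- round(mm2px(layout$page_mm[["width"]], dpi))
  h <- round(mm2px(layout$page_mm[["height"]], dpi))
  f <- layout$frame_mm; b <- layout$border_mm
  rects <- list()
  add_mm <- function(x0, y0, x1, y1) {
    rr <- px_range(y0, y1, dpi, h); cc <- px_range(x0, x1, dpi, w)
    rects[[length(rects) + 1L]] <<- c(rr[1], rr[2], cc[1], cc[2])
  }
  # fiducial: solid border as four bands
  add_mm(f[["x0"]], f[["y0"]], f[["x1"]], f[["y0"]] + b)
  add_mm(f[["x0"]], f[["y1"]] - b, f[["x1"]], f[["y1"]])
  add_mm(f[["x0"]], f[["y0"]], f[["x0"]] + b, f[["y1"]])
  add_mm(f[["x1"]] - b, f[["y0"]], f[["x1"]], f[["y1"]])
  lw <- 0.3  # grid line width, mm
  for (tb in layout$tables) {
    bx <- tb$box_mm
    grid_y0 <- tb$header_mm[["y1"]]
    nc <- dim(tb$cells_mm)[2]
    # header separator and cell grid (row 0 doubles as the top outline)
    for (r in 0:5) {
      y <- grid_y0 + r * (bx[["y1"]] - grid_y0) / 5
      add_mm(bx[["x0"]], y - lw / 2, bx[["x1"]], y + lw / 2)
    }
    add_mm(bx[["x0"]], bx[["y0"]], bx[["x1"]], bx[["y0"]] + lw)
    for (c in 0:nc) {
      x <- bx[["x0"]] + c * (bx[["x1"]] - bx[["x0"]]) / nc
      add_mm(x - lw / 2, bx[["y0"]], x + lw / 2, bx[["y1"]])
    }
    # force labels centred in the header band
    cw_px <- mm2px((bx[["x1"]] - bx[["x0"]]), dpi) / nc
    hh_px <- mm2px(tb$header_mm[["y1"]] - tb$header_mm[["y0"]], dpi)
    for (c in seq_len(nc)) {
      lab <- format_force_label(tb$labels[c])
      scale <- max(1L, floor(min((cw_px - 2) / (6 * nchar(lab)), (hh_px - 2) / 7)))
      tw <- 6 * scale * nchar(lab); th <- 7 * scale
      x <- mm2px(bx[["x0"]], dpi) + (c - 1) * cw_px + (cw_px - tw) / 2
      y <- mm2px(tb$header_mm[["y0"]], dpi) + (hh_px - th) / 2
      rects <- c(rects, text_rects(x, y, lab, scale))
    }
  }
  img <- matrix(255, nrow = h, ncol = w)
  for (rc in rects) {
    r0 <- max(1L, rc[1]); r1 <- min(h, rc[2])
    c0 <- max(1L, rc[3]); c1 <- min(w, rc[4])
    if (r1 >= r0 && c1 >= c0) img[r0:r1, c0:c1] <- 0
  }
  page_image(img, dpi)
}

# averaging matrix mapping n_in samples to n_out (area/overlap weights)
make_avg_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * step; hi <- i * step
    j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) A[i, j] <- ov / step
    }
  }
  A
}

#' Area-average resize of a matrix
#' @param mat numeric matrix.
#' @param out_h,out_w target dimensions.
#' @return resized matrix.
#' @export
resize_area <- function(mat, out_h, out_w) {
  L <- make_avg_matrix(nrow(mat), out_h)
  R <- make_avg_matrix(ncol(mat), out_w)
  L %*% mat %*% t(R)
}

#' Otsu global threshold
#' @param img numeric matrix in `[0, 255]`.
#' @return list with `threshold` and the two class means `mu0`, `mu1`.
#' @export
otsu_threshold <- function(img) {
  v <- pmin(pmax(round(as.vector(img)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  t <- which.max(sb) - 1L
  omega0 <- omega[t + 1L]
  mu0 <- if (omega0 > 0) mu[t + 1L] / omega0 else 0
  mu1 <- if (omega0 < 1) (mu_t - mu[t + 1L]) / (1 - omega0) else 255
  list(threshold = t, mu0 = mu0, mu1 = mu1)
}

# adaptive-mean binarization of a cell patch: ink = darker than the patch
# mean by `offset`, floored so fully dark patches still register as ink
binarize_patch <- function(patch, offset = 40) {
  thr <- max(mean(patch) - offset, 60)
  (patch < thr) * 1
}

# 3x3 box blur with edge replication
blur3 <- function(m) {
  pad <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  nr <- nrow(m); nc <- ncol(m)
  (pad[1:nr, 1:nc] + pad[1:nr, 2:(nc + 1)] + pad[1:nr, 3:(nc + 2)] +
   pad[2:(nr + 1), 1:nc] + pad[2:(nr + 1), 2:(nc + 1)] + pad[2:(nr + 1), 3:(nc + 2)] +
   pad[3:(nr + 2), 1:nc] + pad[3:(nr + 2), 2:(nc + 1)] + pad[3:(nr + 2), 3:(nc + 2)]) / 9
}

#' Foreground (ink) fraction of a binarized patch
#' @param cell_image binary 0/1 matrix.
#' @return proportion of ink pixels in `[0, 1]`.
#' @export
ink_fraction <- function(cell_image) {
  if (length(cell_image) == 0) return(0)
  mean(cell_image != 0)
}
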