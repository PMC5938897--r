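# Geometry of the printable scoring sheets.
#
# A4 portrait, millimetres, origin top-left, y downward; all boxes are
# half-open [x0,x1) x [y0,y1). The fiducial frame is a 2 mm solid border
# whose *outer* rectangle is the reference for the reader's homography.
# Animal sheets carry a 4 x 5 grid of 20 tables; the human sheet carries
# 10 subject rows, each with an MDT table and an MPT table.

PAGE_MM <- c(width = 210, height = 297)
FRAME_MM <- c(x0 = 8, y0 = 8, x1 = 202, y1 = 289)
BORDER_MM <- 2
CONTENT_MM <- c(x0 = 12, y0 = 12, x1 = 198, y1 = 285)

sheet_kinds <- function() c("mouse", "rat", "human")

rect <- function(x0, y0, x1, y1) c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)

# one table: header band with force labels on top, 5 x ncol cell grid below
make_table <- function(index, assay, box, header_mm) {
  ladder <- build_ladder(assay)
  nc <- ladder$n_filaments
  gx0 <- box[["x0"]]; gy0 <- box[["y0"]] + header_mm
  cw <- (box[["x1"]] - box[["x0"]]) / nc
  ch <- (box[["y1"]] - gy0) / 5
  cells <- array(NA_real_, dim = c(5, nc, 4),
                 dimnames = list(NULL, NULL, c("x0", "y0", "x1", "y1")))
  for (r in 1:5) for (c in 1:nc)
    cells[r, c, ] <- c(gx0 + (c - 1) * cw, gy0 + (r - 1) * ch,
                       gx0 + c * cw, gy0 + r * ch)
  list(index = index, assay = assay, box_mm = box,
       header_mm = rect(box[["x0"]], box[["y0"]], box[["x1"]], gy0),
       labels = ladder$forces_g, cells_mm = cells)
}

#' Build the geometric layout of a template sheet
#'
#' @param kind `"mouse"` or `"rat"` (20 tables of that assay) or `"human"`
#'   (10 subject rows of one MDT plus one MPT table).
#' @return object of class `sheet_layout`.
#' @export
build_sheet_layout <- function(kind) {
  kind <- match.arg(kind, sheet_kinds())
  pad <- 1.5
  tables <- list()
  if (kind %in% c("mouse", "rat")) {
    ncol_t <- 4L; nrow_t <- 5L; header <- 6
    bw <- (CONTENT_MM[["x1"]] - CONTENT_MM[["x0"]]) / ncol_t
    bh <- (CONTENT_MM[["y1"]] - CONTENT_MM[["y0"]]) / nrow_t
    idx <- 0L
    for (r in seq_len(nrow_t)) for (c in seq_len(ncol_t)) {
      idx <- idx + 1L
      x0 <- CONTENT_MM[["x0"]] + (c - 1) * bw
      y0 <- CONTENT_MM[["y0"]] + (r - 1) * bh
      tables[[idx]] <- make_table(idx, kind,
                                  rect(x0 + pad, y0 + pad, x0 + bw - pad, y0 + bh - pad),
                                  header)
    }
    subjects <- 20L
  } else {
    nrow_t <- 10L; header <- 5
    bw <- (CONTENT_MM[["x1"]] - CONTENT_MM[["x0"]]) / 2
    bh <- (CONTENT_MM[["y1"]] - CONTENT_MM[["y0"]]) / nrow_t
    idx <- 0L
    for (r in seq_len(nrow_t)) {
      for (c in 1:2) {
        idx <- idx + 1L
        x0 <- CONTENT_MM[["x0"]] + (c - 1) * bw
        y0 <- CONTENT_MM[["y0"]] + (r - 1) * bh
        assay <- if (c == 1) "human_mdt" else "human_mpt"
        tb <- make_table(idx, assay,
                         rect(x0 + pad, y0 + pad, x0 + bw - pad, y0 + bh - pad),
                         header)
        tb$subject_row <- r
        tables[[idx]] <- tb
      }
    }
    subjects <- 10L
  }
  structure(list(kind = kind, version = "1", page_mm = PAGE_MM,
                 frame_mm = FRAME_MM, border_mm = BORDER_MM,
                 n_subjects = subjects, tables = tables),
            class = "sheet_layout")
}

#' @export
print.sheet_layout <- function(x, ...) {
  cat(sprintf("<sheet_layout: %s, %d tables on A4>\n", x$kind, length(x$tables)))
  invisible(x)
}

rects_overlap <- function(a, b) {
  !(a[["x1"]] <= b[["x0"]] || b[["x1"]] <= a[["x0"]] ||
    a[["y1"]] <= b[["y0"]] || b[["y1"]] <= a[["y0"]])
}

#' Validate layout invariants
#'
#' Table count per sheet kind, 5 rows and ladder-matching columns per
#' table, boxes inside the fiducial frame, pairwise non-overlap.
#'
#' @param layout a `sheet_layout`.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_layout <- function(layout) {
  expected <- if (layout$kind == "human") 20L else 20L
  if (length(layout$tables) != expected)
    stop_updown("updown_layout", "expected %d tables, found %d",
                expected, length(layout$tables))
  inner <- c(FRAME_MM[["x0"]] + BORDER_MM, FRAME_MM[["y0"]] + BORDER_MM,
             FRAME_MM[["x1"]] - BORDER_MM, FRAME_MM[["y1"]] - BORDER_MM)
  for (tb in layout$tables) {
    n <- build_ladder(tb$assay)$n_filaments
    if (!identical(dim(tb$cells_mm)[1:2], c(5L, n)))
      stop_updown("updown_layout", "table %d grid is not 5 x %d", tb$index, n)
    b <- tb$box_mm
    if (b[["x0"]] < inner[1] || b[["y0"]] < inner[2] ||
        b[["x1"]] > inner[3] || b[["y1"]] > inner[4])
      stop_updown("updown_layout", "table %d leaves the fiducial frame", tb$index)
  }
  boxes <- lapply(layout$tables, `[[`, "box_mm")
  for (i in seq_along(boxes)) for (j in seq_len(i - 1L))
    if (rects_overlap(boxes[[i]], boxes[[j]]))
      stop_updown("updown_layout", "tables %d and %d overlap", j, i)
  invisible(TRUE)
}

#' Save / load a layout sidecar (JSON)
#'
#' Lossless round trip of the layout geometry; malformed files raise an
#' `updown_parse` error naming the file.
#'
#' @param layout a `sheet_layout`.
#' @param path sidecar path.
#' @return `path` (save) or the `sheet_layout` (load).
#' @export
save_layout <- function(layout, path) {
  ser <- unclass(layout)
  ser$page_mm <- as.list(layout$page_mm)      # keep names in JSON objects
  ser$frame_mm <- as.list(layout$frame_mm)
  ser$tables <- lapply(layout$tables, function(tb) {
    tb$box_mm <- as.list(tb$box_mm)
    tb$header_mm <- as.list(tb$header_mm)
    tb$cells_mm <- list(dim = dim(tb$cells_mm), values = as.vector(tb$cells_mm))
    tb
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_layout
#' @export
load_layout <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_updown("updown_parse", "cannot parse layout sidecar %s: %s",
                                path, conditionMessage(e)))
  if (is.null(obj$kind) || is.null(obj$tables))
    stop_updown("updown_parse", "layout sidecar %s lacks required fields", path)
  num <- function(x) unlist(x, use.names = TRUE)
  tables <- lapply(obj$tables, function(tb) {
    if (is.null(tb$cells_mm$dim) || is.null(tb$cells_mm$values))
      stop_updown("updown_parse", "layout sidecar %s: table lacks cell grid", path)
    arr <- array(as.numeric(num(tb$cells_mm$values)),
                 dim = as.integer(num(tb$cells_mm$dim)),
                 dimnames = list(NULL, NULL, c("x0", "y0", "x1", "y1")))
    out <- list(index = as.integer(tb$index), assay = tb$assay,
                box_mm = as.numeric(num(tb$box_mm)),
                header_mm = as.numeric(num(tb$header_mm)),
                labels = as.numeric(num(tb$labels)), cells_mm = arr)
    names(out$box_mm) <- names(out$header_mm) <- c("x0", "y0", "x1", "y1")
    if (!is.null(tb$subject_row)) out$subject_row <- as.integer(tb$subject_row)
    out
  })
  structure(list(kind = obj$kind, version = obj$version,
                 page_mm = c(width = as.numeric(obj$page_mm$width),
                             height = as.numeric(obj$page_mm$height)),
                 frame_mm = stats::setNames(as.numeric(num(obj$frame_mm)),
                                            c("x0", "y0", "x1", "y1")),
                 border_mm = as.numeric(obj$border_mm),
                 n_subjects = as.integer(obj$n_subjects),
                 tables = tables),
            class = "sheet_layout")
}

#' Generate a printable template
#'
#' Renders the sheet (fiducial border, table grids, per-column force
#' labels) at `dpi` and writes it as a single-page raster PDF plus a JSON
#' layout sidecar (`<path>.layout.json`). Output is byte-stable for a
#' fixed package version, kind and dpi.
#'
#' @param kind sheet kind (see [build_sheet_layout()]).
#' @param path output PDF path, or `NULL` to skip writing.
#' @param dpi render resolution (default 300).
#' @return list with `layout`, `image` (a `page_image`), `pdf`, `sidecar`.
#' @export
generate_template <- function(kind, path = NULL, dpi = 300) {
  layout <- build_sheet_layout(kind)
  img <- render_layout_raster(layout, dpi)
  sidecar <- NULL
  if (!is.null(path)) {
    write_scan_pdf(list(img$img), path, page_mm = layout$page_mm)
    sidecar <- paste0(sub("\\.pdf$", "", path, ignore.case = TRUE), ".layout.json")
    save_layout(layout, sidecar)
  }
  invisible(list(layout = layout, image = img, pdf = path, sidecar = sidecar))
}
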