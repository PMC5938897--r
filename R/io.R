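# Page I/O. Templates and synthetic scans are written as raster PDFs (one
# 8-bit grayscale FlateDecode image XObject per page); rasterize() reads
# that container plus PGM (P2/P5) and PNG page images. Vector-PDF input is
# not supported: no PDF renderer is available offline, and every sheet this
# package reads is printed from its own templates.

#' Write a grayscale matrix as PGM
#' @param img numeric matrix in `[0, 255]`.
#' @param path output path (`.pgm`).
#' @param ascii write plain (P2) instead of binary (P5) format.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, ascii = FALSE) {
  v <- as.integer(pmin(pmax(round(t(img)), 0), 255))  # row-major
  if (ascii) {
    writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255",
                 paste(v, collapse = " ")), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img))), con)
    writeBin(as.raw(v), con)
  }
  invisible(path)
}

#' Read a PGM (P2 or P5) image
#' @param path input path.
#' @return numeric matrix in `[0, 255]`.
#' @export
read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 2 || rawToChar(raw[1:2]) %in% c("P2", "P5") == FALSE)
    stop_updown("updown_input", "%s is not a PGM file", path)
  magic <- rawToChar(raw[1:2])
  # tokenize header (magic, width, height, maxval), skipping '#' comments
  pos <- 3L; tokens <- character(0)
  while (length(tokens) < 3 && pos <= length(raw)) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") { while (pos <= length(raw) && rawToChar(raw[pos]) != "\n") pos <- pos + 1L }
    else if (grepl("[[:space:]]", ch)) pos <- pos + 1L
    else {
      tok <- ""
      while (pos <= length(raw) && !grepl("[[:space:]]", rawToChar(raw[pos]))) {
        tok <- paste0(tok, rawToChar(raw[pos])); pos <- pos + 1L
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2]); mx <- as.integer(tokens[3])
  if (anyNA(c(w, h, mx))) stop_updown("updown_input", "bad PGM header in %s", path)
  if (magic == "P5") {
    pos <- pos + 1L  # single whitespace after maxval
    v <- as.integer(raw[pos:(pos + w * h - 1L)])
  } else {
    txt <- rawToChar(raw[pos:length(raw)])
    v <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[1:(w * h)]
  }
  matrix(v * (255 / mx), nrow = h, ncol = w, byrow = TRUE)
}

read_page_png <- function(path) {
  a <- png::readPNG(path)
  g <- if (length(dim(a)) == 2) a
       else 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  g * 255
}

#' Write pages as a raster PDF
#'
#' Minimal PDF 1.4 writer: each page is one 8-bit grayscale image XObject,
#' zlib (FlateDecode) compressed, scaled to the page media box. Output is
#' deterministic (no timestamps), so identical inputs give identical bytes.
#'
#' @param images list of numeric matrices in `[0, 255]`.
#' @param path output PDF path.
#' @param page_mm page size in mm, `c(width, height)`.
#' @return `path`, invisibly.
#' @export
write_scan_pdf <- function(images, path, page_mm = c(width = 210, height = 297)) {
  if (length(images) == 0) stop_updown("updown_domain", "no pages to write")
  wpt <- unname(page_mm[[1]] * 72 / 25.4)
  hpt <- unname(page_mm[[2]] * 72 / 25.4)
  npage <- length(images)
  objs <- vector("list", 2 + 3 * npage)
  kids <- paste(sprintf("%d 0 R", 3 + 3 * (seq_len(npage) - 1)), collapse = " ")
  objs[[1]] <- charToRaw("<< /Type /Catalog /Pages 2 0 R >>")
  objs[[2]] <- charToRaw(sprintf("<< /Type /Pages /Kids [%s] /Count %d >>", kids, npage))
  for (i in seq_len(npage)) {
    img <- images[[i]]
    if (inherits(img, "page_image")) img <- img$img
    base <- 3 + 3 * (i - 1)
    objs[[base]] <- charToRaw(sprintf(
      "<< /Type /Page /Parent 2 0 R /MediaBox [0 0 %.4f %.4f] /Resources << /XObject << /Im%d %d 0 R >> >> /Contents %d 0 R >>",
      wpt, hpt, i, base + 2, base + 1))
    content <- sprintf("q\n%.4f 0 0 %.4f 0 0 cm\n/Im%d Do\nQ\n", wpt, hpt, i)
    objs[[base + 1]] <- c(
      charToRaw(sprintf("<< /Length %d >>\nstream\n", nchar(content))),
      charToRaw(content), charToRaw("endstream"))
    bytes <- as.raw(pmin(pmax(round(as.vector(t(img))), 0), 255))
    z <- memCompress(bytes, "gzip")  # zlib stream, as FlateDecode expects
    objs[[base + 2]] <- c(
      charToRaw(sprintf(
        "<< /Type /XObject /Subtype /Image /Width %d /Height %d /ColorSpace /DeviceGray /BitsPerComponent 8 /Filter /FlateDecode /Length %d >>\nstream\n",
        ncol(img), nrow(img), length(z))),
      z, charToRaw("\nendstream"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  out <- charToRaw("%PDF-1.4\n")
  offsets <- integer(length(objs))
  for (k in seq_along(objs)) {
    offsets[k] <- length(out)
    out <- c(out, charToRaw(sprintf("%d 0 obj\n", k)), objs[[k]],
             charToRaw("\nendobj\n"))
  }
  xref_at <- length(out)
  xref <- c(sprintf("xref\n0 %d", length(objs) + 1),
            "0000000000 65535 f ",
            sprintf("%010d 00000 n ", offsets),
            sprintf("trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF",
                    length(objs) + 1, xref_at))
  out <- c(out, charToRaw(paste(xref, collapse = "\n")))
  writeBin(out, con)
  invisible(path)
}

#' Read pages from a raster PDF
#'
#' Parses the container written by [write_scan_pdf()]: grayscale
#' FlateDecode image XObjects in page order. Encrypted or vector PDFs are
#' rejected with an input error.
#'
#' @param path PDF path.
#' @return list of `list(img, width_mm, height_mm)`.
#' @export
read_scan_pdf <- function(path) {
  if (!file.exists(path)) stop_updown("updown_input", "no such file: %s", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:5]) != "%PDF-")
    stop_updown("updown_input", "%s is not a PDF", path)
  # byte-exact text view (NULs masked) + useBytes regexes, so that match
  # offsets are byte offsets into `raw`
  masked <- raw
  masked[masked == as.raw(0)] <- as.raw(1)
  s <- rawToChar(masked)
  if (grepl("/Encrypt", s, fixed = TRUE, useBytes = TRUE))
    stop_updown("updown_input", "%s is encrypted", path)
  img_re <- "<< /Type /XObject /Subtype /Image /Width ([0-9]+) /Height ([0-9]+) /ColorSpace /DeviceGray /BitsPerComponent 8 /Filter /FlateDecode /Length ([0-9]+) >>\nstream\n"
  dims <- regmatches(s, gregexpr("/MediaBox \\[0 0 [0-9.]+ [0-9.]+\\]", s,
                                 useBytes = TRUE))[[1]]
  m <- gregexpr(img_re, s, useBytes = TRUE)[[1]]
  if (m[1] == -1)
    stop_updown("updown_input",
                "%s contains no supported raster pages (vector PDFs are not readable offline)",
                path)
  hdrs <- regmatches(s, gregexpr(img_re, s, useBytes = TRUE))[[1]]
  pages <- vector("list", length(m))
  for (i in seq_along(m)) {
    nums <- as.integer(regmatches(hdrs[i], gregexpr("[0-9]+", hdrs[i]))[[1]])
    w <- nums[1]; h <- nums[2]; len <- nums[length(nums)]
    start <- m[i] + attr(m, "match.length")[i]
    z <- raw[start:(start + len - 1L)]
    bytes <- memDecompress(z, "gzip")
    if (length(bytes) != w * h)
      stop_updown("updown_input", "corrupt image stream on page %d of %s", i, path)
    img <- matrix(as.integer(bytes), nrow = h, ncol = w, byrow = TRUE)
    box <- as.numeric(regmatches(dims[min(i, length(dims))],
                                 gregexpr("[0-9.]+", dims[min(i, length(dims))]))[[1]])
    pages[[i]] <- list(img = img, width_mm = box[3] * 25.4 / 72,
                       height_mm = box[4] * 25.4 / 72)
  }
  pages
}

#' Rasterize a scanned document to page images
#'
#' Accepts the raster-PDF container written by this package (multi-page)
#' or single PGM/PNG page images, and resamples to the requested
#' resolution.
#'
#' @param path input file (`.pdf`, `.pgm`, `.png`).
#' @param dpi target resolution (default 300).
#' @return list of `page_image` objects, one per page, in document order.
#' @export
rasterize <- function(path, dpi = 300) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop_updown("updown_input", "input file not found: %s",
                if (is.character(path)) path else "<non-path>")
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdf") {
    pages <- read_scan_pdf(path)
    lapply(seq_along(pages), function(i) {
      p <- pages[[i]]
      native_dpi <- ncol(p$img) / (p$width_mm / 25.4)
      tw <- round(p$width_mm / 25.4 * dpi)
      th <- round(p$height_mm / 25.4 * dpi)
      img <- if (abs(native_dpi - dpi) / dpi < 0.005 &&
                 ncol(p$img) == tw && nrow(p$img) == th) p$img
             else resize_area(p$img, th, tw)
      page_image(img, dpi, page = i)
    })
  } else if (ext == "pgm") {
    list(page_image(read_pgm(path), dpi, page = 1L))
  } else if (ext == "png") {
    list(page_image(read_page_png(path), dpi, page = 1L))
  } else {
    stop_updown("updown_input", "unsupported input format: .%s", ext)
  }
}
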