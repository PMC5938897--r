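# Exhaustive enumeration of legal tables and the string encoding used for
# validation and Levenshtein repair.

#' Encode a response table as a canonical string
#'
#' Row-major flattening over the alphabet `{X, O, .}` ('.' = empty);
#' length is always `5 * n_filaments`.
#'
#' @param table a `response_table`.
#' @return single string.
#' @export
encode_table <- function(table) paste(t(table$cells), collapse = "")

#' Decode a canonical table string
#' @param text string of length `5 * n_filaments` over `{X, O, .}`.
#' @param assay assay identifier.
#' @param source optional provenance.
#' @return a `response_table`.
#' @export
decode_table <- function(text, assay, source = NULL) {
  ladder <- build_ladder(assay)
  n <- ladder$n_filaments
  if (nchar(text) != 5 * n)
    stop_updown("updown_domain", "table string must have length %d", 5 * n)
  ch <- strsplit(text, "")[[1]]
  if (!all(ch %in% MARKS))
    stop_updown("updown_domain", "table string alphabet is {X, O, .}")
  response_table(assay, matrix(ch, nrow = 5, byrow = TRUE), source = source)
}

#' Enumerate every legal table for an assay
#'
#' Depth-first expansion of the recording grammar: all completed tables
#' plus all out-of-range-terminated tables. Used as the valid-sequence
#' lexicon for validation and closest-match repair.
#'
#' @param ladder a `filament_ladder`.
#' @return object of class `valid_lexicon`: list with `assay`, sorted
#'   character `entries` (encoded tables), and a content `fingerprint`.
#' @export
enumerate_valid_tables <- function(ladder) {
  n <- ladder$n_filaments
  start <- ladder$start_index
  acc <- new.env(parent = emptyenv())
  acc$out <- character(0)
  emit <- function(cells) acc$out <- c(acc$out, paste(t(cells), collapse = ""))

  # rows 2..5, one trial each; idx/last are the change trial's state
  post <- function(cells, idx, last, row) {
    nxt <- idx + if (last == "X") -1L else 1L
    for (r in c("X", "O")) {
      cl <- cells
      cl[row, nxt] <- r
      if (row == 5L) { emit(cl); next }
      if (r == "O" && nxt == n) { emit(cl); next }   # OOR_HIGH mid-table
      if (r == "X" && nxt == 1L) { emit(cl); next }  # OOR_LOW mid-table
      post(cl, nxt, r, row + 1L)
    }
  }

  # row 1: run of r0 from the start column, then either the change or an
  # out-of-range conclusion at the ladder edge
  for (r0 in c("X", "O")) {
    dir <- if (r0 == "X") -1L else 1L
    edge <- if (r0 == "X") 1L else n
    cols <- seq(start, edge, by = dir)
    for (k in seq_along(cols)) {
      i <- cols[k]
      if (i == edge) {
        # response r0 at the edge concludes out of range
        cl <- matrix(".", 5, n)
        cl[1, cols[1:k]] <- r0
        emit(cl)
        break
      }
      # change at the next tested filament
      j <- cols[k + 1]
      cl <- matrix(".", 5, n)
      cl[1, cols[1:k]] <- r0
      cl[1, j] <- if (r0 == "X") "O" else "X"
      post(cl, j, cl[1, j], 2L)
    }
  }
  entries <- sort(unique(acc$out))
  structure(list(assay = ladder$assay, entries = entries,
                 fingerprint = fnv1a(c(ladder$assay, "v1", entries))),
            class = "valid_lexicon")
}

#' @export
print.valid_lexicon <- function(x, ...) {
  cat(sprintf("<valid_lexicon: %s, %d entries, fingerprint %s>\n",
              x$assay, length(x$entries), x$fingerprint))
  invisible(x)
}

#' Lexicon for an assay, cached per session
#' @param assay assay identifier.
#' @return a `valid_lexicon`.
#' @export
assay_lexicon <- function(assay) {
  key <- paste0("lexicon_", assay)
  if (is.null(.updown_env[[key]]))
    .updown_env[[key]] <- enumerate_valid_tables(build_ladder(assay))
  .updown_env[[key]]
}

#' Persist / load a lexicon as sorted plain text
#'
#' One encoded table per line, preceded by `#`-comment header lines with
#' the assay and fingerprint.
#'
#' @param lexicon a `valid_lexicon`.
#' @param path file path.
#' @return `path` (save) or a `valid_lexicon` (load).
#' @export
save_lexicon <- function(lexicon, path) {
  writeLines(c(sprintf("# updown valid-sequence lexicon"),
               sprintf("# assay: %s", lexicon$assay),
               sprintf("# fingerprint: %s", lexicon$fingerprint),
               lexicon$entries), path)
  invisible(path)
}

#' @rdname save_lexicon
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path)
  assay <- sub("^# assay: ", "", grep("^# assay: ", lines, value = TRUE))
  entries <- lines[!startsWith(lines, "#")]
  lex <- structure(list(assay = assay, entries = entries,
                        fingerprint = fnv1a(c(assay, "v1", entries))),
                   class = "valid_lexicon")
  stated <- sub("^# fingerprint: ", "", grep("^# fingerprint: ", lines, value = TRUE))
  if (length(stated) == 1 && !identical(stated, lex$fingerprint))
    stop_updown("updown_parse", "lexicon fingerprint mismatch in %s", path)
  lex
}
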