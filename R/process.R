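# Document processing pipeline: rasterize -> locate frame -> extract cells
# -> classify -> validity gate -> repair -> Dixon threshold, one result row
# per table slot per page, in page order. Page-level failures (unreadable
# page, frame not found) are reported in the rows, never fatal.

#' Default pipeline configuration
#'
#' @param dpi rasterization resolution.
#' @param ink_threshold minimum ink fraction for a mark.
#' @param repair_cutoff maximum accepted Levenshtein repair distance.
#' @param inner_margin cell crop margin (fraction per side).
#' @return named list of settings.
#' @export
updown_config <- function(dpi = 150, ink_threshold = 0.02, repair_cutoff = 3L,
                          inner_margin = 0.12) {
  list(dpi = dpi, ink_threshold = ink_threshold,
       repair_cutoff = as.integer(repair_cutoff), inner_margin = inner_margin)
}

#' Read a configuration file
#'
#' Simple INI-style `key = value` lines (sections and `#`/`;` comments
#' ignored); unknown keys are rejected. Missing keys keep their defaults.
#'
#' @param path config file path.
#' @return config list as from [updown_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  cfg <- updown_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop_updown("updown_parse", "malformed config line: %s", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg))
      stop_updown("updown_parse", "unknown config key: %s", key)
    cfg[[key]] <- if (key == "repair_cutoff") as.integer(val) else as.numeric(val)
  }
  cfg
}

result_row <- function(file, page, table, assay, raw = NA_character_,
                       repaired = NA_character_, distance = NA_integer_,
                       status, threshold = NA_real_, kappa = NA_real_,
                       final_force = NA_real_, flags = "") {
  data.frame(file = file, page = page, table = table, assay = assay,
             raw = raw, repaired = repaired, repair_distance = distance,
             status = status,
             threshold_g = if (is.na(threshold)) "N/A"
                           else format(signif(threshold, 4), trim = TRUE),
             kappa = kappa, final_force_g = final_force, flags = flags,
             stringsAsFactors = FALSE)
}

process_table <- function(ext, file, pageno, config, ensemble, kappa) {
  nc <- ncol(ext$ink)
  marks <- matrix(".", 5, nc)
  inked <- which(ext$ink >= config$ink_threshold)
  agreement <- matrix(1, 5, nc)
  if (length(inked)) {
    patches <- lapply(ext$bin[inked], canonical_patch)
    pred <- predict_ensemble(ensemble, patches)
    marks[inked] <- pred$label
    agreement[inked] <- pred$agreement
  }
  tab <- response_table(ext$assay, marks,
                        source = list(page = pageno, table = ext$index))
  base <- function(...) result_row(file = file, page = pageno,
                                   table = ext$index, assay = ext$assay, ...)
  nmarks <- count_marks(tab)
  if (nmarks == 0)
    return(base(status = "INVALID", flags = "empty"))
  if (validity_gate(tab) == "INVALID_OVERMARKED")
    return(base(raw = encode_table(tab), status = "INVALID", flags = "overmarked"))
  raw <- encode_table(tab)
  rep <- repair_table(raw, assay_lexicon(ext$assay),
                      confidence = as.numeric(t(agreement)),
                      cutoff = config$repair_cutoff)
  if (!rep$accepted)
    return(base(raw = raw, distance = rep$distance, status = "INVALID",
                flags = "unrepairable"))
  seq <- table_to_sequence(decode_table(rep$corrected, ext$assay))
  res <- compute_threshold(seq, kappa = kappa,
                           source = list(page = pageno, table = ext$index))
  base(raw = raw, repaired = rep$corrected, distance = rep$distance,
       status = res$status, threshold = res$threshold_g,
       kappa = res$kappa_used, final_force = res$final_force_g,
       flags = if (rep$ambiguous) "ambiguous_repair" else "")
}

#' Process a scanned document into result rows
#'
#' Runs the full reading pipeline on every page. Every table slot yields
#' exactly one row (empty slots are flagged `empty`, crossed-out tables are
#' N/A with flag `overmarked`, unusable pages are flagged per row), so the
#' row count is always pages x tables-per-sheet.
#'
#' @param input path to a PDF/PGM/PNG scan, or a list of `page_image`s.
#' @param kind sheet kind the document was printed from (`"mouse"`,
#'   `"rat"`, `"human"`).
#' @param config pipeline settings, see [updown_config()].
#' @param ensemble trained `mark_ensemble`; default is the bundled
#'   synthetic-glyph model.
#' @return `data.frame` of class `updown_results`, one row per table slot.
#' @export
process_document <- function(input, kind, config = updown_config(),
                             ensemble = NULL) {
  layout <- build_sheet_layout(kind)
  kappa <- load_kappa_table()
  if (is.null(ensemble)) ensemble <- default_ensemble()
  file <- if (is.character(input)) input else "<in-memory>"
  pages <- if (is.character(input)) rasterize(input, config$dpi)
           else lapply(seq_along(input), function(i) {
             p <- input[[i]]
             if (!inherits(p, "page_image"))
               stop_updown("updown_input", "in-memory input must be page_image objects")
             if (is.na(p$page)) p$page <- i
             p
           })
  if (length(pages) == 0) stop_updown("updown_input", "document has no pages")
  rows <- vector("list", length(pages))
  for (p in seq_along(pages)) {
    pageno <- pages[[p]]$page %||% p
    warp <- tryCatch(locate_frame(pages[[p]], layout), updown_error = identity)
    if (inherits(warp, "condition")) {
      rows[[p]] <- do.call(rbind, lapply(layout$tables, function(tb)
        result_row(file, pageno, tb$index, tb$assay, status = "INVALID",
                   flags = "frame_not_found")))
      next
    }
    ext <- extract_cells(warp, layout, inner_margin = config$inner_margin)
    rows[[p]] <- do.call(rbind, lapply(ext, process_table, file = file,
                                       pageno = pageno, config = config,
                                       ensemble = ensemble, kappa = kappa))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("updown_results", "data.frame")
  out
}

#' Write result rows as CSV
#'
#' RFC-4180 CSV with header, UTF-8, '.' decimal separator. The default
#' output path is the input file with a `.csv` extension, next to the scan.
#'
#' @param rows an `updown_results` data frame.
#' @param path output path; default derives from the `file` column.
#' @return the output path, invisibly.
#' @export
write_results_csv <- function(rows, path = NULL) {
  if (is.null(path)) {
    src <- unique(rows$file)
    if (length(src) != 1 || src == "<in-memory>")
      stop_updown("updown_domain", "cannot derive a default path; pass `path`")
    path <- paste0(sub("\\.[A-Za-z0-9]+$", "", src), ".csv")
  }
  df <- as.data.frame(rows)
  tryCatch(write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE, na = ""),
           error = function(e)
             stop_updown("updown_output", "cannot write %s: %s", path,
                         conditionMessage(e)))
  invisible(path)
}
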