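# The recording grammar of up-down scoring tables.
#
# A table is a 5 x n grid. Row 1 holds the first run of identical
# responses starting at the mid-range filament (moving weaker after X,
# stronger after O) up to and including the first response change; the
# next four trials occupy rows 2-5, one mark each. A negative response at
# the strongest filament (or, symmetrically, a positive at the weakest)
# terminates the test out of range and leaves the remaining rows empty.

MARKS <- c("X", "O", ".")

#' Construct a response table
#'
#' @param assay assay identifier (see [updown_assays()]).
#' @param cells 5 x n character matrix over `{"X","O","."}`; default empty.
#' @param source optional provenance (list with `page`, `table`).
#' @return object of class `response_table`.
#' @export
response_table <- function(assay, cells = NULL, source = NULL) {
  ladder <- build_ladder(assay)
  if (is.null(cells))
    cells <- matrix(".", nrow = 5, ncol = ladder$n_filaments)
  if (!is.matrix(cells) || nrow(cells) != 5 || ncol(cells) != ladder$n_filaments)
    stop_updown("updown_domain", "cells must be a 5 x %d matrix", ladder$n_filaments)
  if (!all(cells %in% MARKS))
    stop_updown("updown_domain", "cells must contain only X, O or .")
  structure(list(assay = assay, cells = cells,
                 source = source %||% list(page = NA_integer_, table = NA_integer_)),
            class = "response_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table: %s, %d marks>\n", x$assay, count_marks(x)))
  apply(x$cells, 1, function(r) cat(" ", paste(r, collapse = " "), "\n"))
  invisible(x)
}

#' Count non-empty cells
#' @param table a `response_table`.
#' @return integer mark count.
#' @export
count_marks <- function(table) sum(table$cells != ".")

#' Over-marking validity gate
#'
#' A table with more than 12 marked cells is treated as deliberately
#' crossed out (recording mistake) and reported as N/A downstream; 12 marks
#' or fewer pass this gate.
#'
#' @param table a `response_table`.
#' @return `"VALID"` or `"INVALID_OVERMARKED"`.
#' @export
validity_gate <- function(table) {
  if (count_marks(table) > 12L) "INVALID_OVERMARKED" else "VALID"
}

new_trial_sequence <- function(index, response, first_change_pos, termination, assay) {
  structure(list(
    trials = data.frame(index = as.integer(index), response = response,
                        stringsAsFactors = FALSE),
    first_change_pos = first_change_pos,
    completed = identical(termination, "COMPLETED"),
    termination = termination,
    assay = assay), class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence: %s, %d trials, %s>\n ", x$assay,
              nrow(x$trials), x$termination))
  cat(paste0("(", x$trials$index, ",", x$trials$response, ")", collapse = " "), "\n")
  invisible(x)
}

stop_grammar <- function(msg, ...) stop_updown("updown_ungrammatical", msg, ...)

#' Reconstruct the trial sequence from a response table
#'
#' Reads the table under the recording grammar and returns the ordered
#' trials, the position of the first response change, and the termination
#' state (`COMPLETED`, `OOR_HIGH` when testing concluded with no response
#' at the strongest filament, `OOR_LOW` symmetrically at the weakest).
#' Tables violating the grammar raise an `updown_ungrammatical` error
#' (callers then attempt repair).
#'
#' @param table a `response_table` (must pass [validity_gate()]).
#' @param ladder matching `filament_ladder`; default built from the table.
#' @return object of class `trial_sequence`.
#' @export
table_to_sequence <- function(table, ladder = build_ladder(table$assay)) {
  cells <- table$cells
  n <- ladder$n_filaments
  start <- ladder$start_index
  if (ncol(cells) != n) stop_grammar("table has %d columns, ladder %d", ncol(cells), n)

  w1 <- which(cells[1, ] != ".")
  if (length(w1) == 0) stop_grammar("row 1 is empty")
  if (!start %in% w1) stop_grammar("row 1 does not mark the start filament")
  if (!identical(w1, seq(min(w1), max(w1)))) stop_grammar("row 1 marks are not contiguous")
  if (length(w1) == 1) stop_grammar("row 1 has a single mark (incomplete recording)")
  if (min(w1) != start && max(w1) != start)
    stop_grammar("start filament is not an endpoint of the row-1 run")
  dir <- if (min(w1) == start) 1L else -1L
  cols1 <- seq(start, if (dir == 1L) max(w1) else min(w1), by = dir)
  resp1 <- cells[1, cols1]
  r0 <- if (dir == 1L) "O" else "X"
  k <- length(cols1)
  if (!all(resp1[-k] == r0))
    stop_grammar("row-1 responses inconsistent with recording direction")

  idx <- cols1
  resp <- resp1

  if (resp1[k] == r0) {
    # no change in row 1: must be an out-of-range conclusion
    if (any(cells[2:5, ] != ".")) stop_grammar("marks below an unterminated row 1")
    if (r0 == "O" && cols1[k] == n)
      return(new_trial_sequence(idx, resp, NA_integer_, "OOR_HIGH", table$assay))
    if (r0 == "X" && cols1[k] == 1L)
      return(new_trial_sequence(idx, resp, NA_integer_, "OOR_LOW", table$assay))
    stop_grammar("row 1 has no response change and no out-of-range end")
  }

  fcp <- k
  cur <- cols1[k]
  last <- resp1[k]
  for (row in 2:5) {
    nxt <- cur + if (last == "X") -1L else 1L
    if (nxt < 1L || nxt > n) stop_grammar("expected filament out of range at row %d", row)
    wr <- which(cells[row, ] != ".")
    if (length(wr) == 0) stop_grammar("row %d is empty before completion", row)
    if (length(wr) > 1) stop_grammar("row %d has %d marks", row, length(wr))
    if (wr != nxt) stop_grammar("row %d marked at column %d, expected %d", row, wr, nxt)
    cur <- nxt
    last <- cells[row, wr]
    idx <- c(idx, cur)
    resp <- c(resp, last)
    if (row < 5) {
      if (last == "O" && cur == n) {
        if (any(cells[(row + 1):5, ] != ".")) stop_grammar("marks after out-of-range end")
        return(new_trial_sequence(idx, resp, fcp, "OOR_HIGH", table$assay))
      }
      if (last == "X" && cur == 1L) {
        if (any(cells[(row + 1):5, ] != ".")) stop_grammar("marks after out-of-range end")
        return(new_trial_sequence(idx, resp, fcp, "OOR_LOW", table$assay))
      }
    }
  }
  new_trial_sequence(idx, resp, fcp, "COMPLETED", table$assay)
}

#' Response pattern used for the kappa lookup
#'
#' The responses of the last six trials of a completed sequence: the trial
#' before the first change, the change trial, and the four trials after it.
#'
#' @param seq a completed `trial_sequence`.
#' @return 6-character string over `{X, O}`.
#' @export
kappa_pattern <- function(seq) {
  if (!isTRUE(seq$completed))
    stop_updown("updown_no_pattern", "no kappa pattern for a non-completed sequence")
  r <- seq$trials$response
  paste(tail(r, 6), collapse = "")
}

#' Compute the Dixon 50% threshold for a sequence
#'
#' Completed sequences use `10^(Xf + kappa*delta)/10000` with `Xf` the
#' log-unit value of the final filament. Out-of-range sequences are capped
#' at the extreme filament force and flagged, keeping the column numeric.
#'
#' @param seq a grammatical `trial_sequence`.
#' @param ladder matching `filament_ladder`.
#' @param kappa a `kappa_table` (default: bundled resource).
#' @param source optional provenance carried through.
#' @return object of class `threshold_result` with `threshold_g`, `status`
#'   (`OK`, `OOR_HIGH`, `OOR_LOW`), `kappa_used`, `pattern`,
#'   `final_force_g`, `provenance`.
#' @export
compute_threshold <- function(seq, ladder = build_ladder(seq$assay),
                              kappa = load_kappa_table(), source = NULL) {
  final_force <- ladder$forces_g[tail(seq$trials$index, 1)]
  if (seq$termination == "OOR_HIGH") {
    res <- list(threshold_g = max(ladder$forces_g), status = "OOR_HIGH",
                kappa_used = NA_real_, pattern = NA_character_,
                final_force_g = final_force)
  } else if (seq$termination == "OOR_LOW") {
    res <- list(threshold_g = min(ladder$forces_g), status = "OOR_LOW",
                kappa_used = NA_real_, pattern = NA_character_,
                final_force_g = final_force)
  } else {
    pat <- kappa_pattern(seq)
    k <- kappa_lookup(kappa, pat)
    res <- list(threshold_g = dixon_threshold(final_force, k, ladder$delta),
                status = "OK", kappa_used = k, pattern = pat,
                final_force_g = final_force)
  }
  res$provenance <- source
  structure(res, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: %s, %s g (final %s g, kappa %s)>\n",
              x$status, format(signif(x$threshold_g, 4)),
              format(x$final_force_g),
              if (is.na(x$kappa_used)) "-" else format(signif(x$kappa_used, 4))))
  invisible(x)
}

#' Invalid-threshold result
#'
#' Used for tables rejected by the validity gate, empty slots, and
#' unrepairable recognizer output; the threshold is not applicable.
#'
#' @param reason short reason string (`"overmarked"`, `"empty"`, ...).
#' @param source optional provenance.
#' @return `threshold_result` with status `INVALID` and `NA` threshold.
#' @export
invalid_threshold <- function(reason, source = NULL) {
  structure(list(threshold_g = NA_real_, status = "INVALID",
                 kappa_used = NA_real_, pattern = NA_character_,
                 final_force_g = NA_real_, reason = reason,
                 provenance = source), class = "threshold_result")
}
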