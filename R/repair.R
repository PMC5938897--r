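# Levenshtein rectification of recognizer output against the lexicon.

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute dynamic programming.
#'
#' @param a,b character scalars.
#' @return integer distance.
#' @export
edit_distance <- function(a, b) {
  if (length(a) != 1 || length(b) != 1 || anyNA(c(a, b)))
    stop_updown("updown_domain", "edit_distance takes two character scalars")
  cpp_lev(a, b)
}

#' Repair a table string by closest match against the lexicon
#'
#' Lexicon members are returned unchanged (distance 0). Otherwise the entry
#' with minimal Levenshtein distance wins; ties are broken by preferring the
#' candidate that changes the fewest high-confidence cells (when per-cell
#' confidences are supplied), then lexicographically. A repair is accepted
#' when the distance does not exceed `cutoff` (default 3); beyond that the
#' table is treated as unrepairable.
#'
#' @param observed table string over `{X, O, .}`.
#' @param lexicon a `valid_lexicon`.
#' @param confidence optional numeric vector, one value per character of
#'   `observed` (higher = more confident classification).
#' @param cutoff maximum accepted distance.
#' @return object of class `repair_outcome`: `corrected`, `distance`,
#'   `ambiguous`, `accepted`.
#' @export
repair_table <- function(observed, lexicon, confidence = NULL, cutoff = 3L) {
  entries <- lexicon$entries
  if (length(entries) == 0)
    stop_updown("updown_config", "empty lexicon")
  if (observed %in% entries)
    return(structure(list(corrected = observed, distance = 0L,
                          ambiguous = FALSE, accepted = TRUE),
                     class = "repair_outcome"))
  d <- cpp_lev_scan(observed, entries,
                    limit = max(nchar(observed), nchar(entries[1])) + 1L,
                    slack = 0L)
  dmin <- min(d)
  cand <- entries[d == dmin]
  ambiguous <- length(cand) > 1L
  if (ambiguous) {
    if (!is.null(confidence) && all(nchar(cand) == nchar(observed))) {
      obs <- strsplit(observed, "")[[1]]
      cost <- vapply(cand, function(s) {
        diffpos <- strsplit(s, "")[[1]] != obs
        sum(confidence[diffpos])
      }, numeric(1))
      cand <- cand[cost == min(cost)]
    }
    cand <- sort(cand)[1]
  }
  structure(list(corrected = cand, distance = as.integer(dmin),
                 ambiguous = ambiguous, accepted = dmin <= cutoff),
            class = "repair_outcome")
}

#' @export
print.repair_outcome <- function(x, ...) {
  cat(sprintf("<repair_outcome: distance %d, %s%s>\n", x$distance,
              if (x$accepted) "accepted" else "rejected",
              if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}
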