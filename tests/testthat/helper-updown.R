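# shared fixtures, built in code

# a table following the worked protocol example: X at the 0.6 g start,
# O at 0.4 g (first change), then X/O alternating for four more trials
example_mouse_table <- function() {
  tb <- response_table("mouse")
  tb$cells[1, 5] <- "X"; tb$cells[1, 4] <- "O"
  tb$cells[2, 5] <- "X"; tb$cells[3, 4] <- "O"
  tb$cells[4, 5] <- "X"; tb$cells[5, 4] <- "O"
  tb
}

# insensitive subject: row 1 all O up to the strongest filament
oor_high_mouse_table <- function() {
  tb <- response_table("mouse")
  tb$cells[1, 5:9] <- "O"
  tb
}

# responder replaying a fixed outcome vector (TRUE = positive)
vector_responder <- function(bits) function(force_g, trial) {
  if (bits[trial]) "X" else "O"
}

# sweep run_protocol over every outcome vector of length `len`
protocol_image <- function(ladder, len = 12L) {
  seen <- character(2^len)
  for (v in 0:(2^len - 1)) {
    bits <- as.logical(intToBits(v))[1:len]
    res <- run_protocol(NULL, ladder, responder = vector_responder(bits))
    seen[v + 1] <- encode_table(res$table)
  }
  sort(unique(seen))
}

# expected threshold strings; accepts a synth_scan_document() result or a
# single render_filled_sheet() truth list
truth_strings <- function(doc) {
  pages <- if (!is.null(doc$truth)) doc$truth else list(doc)
  unlist(lapply(pages, function(pg) sapply(pg, function(t)
    if (is.null(t$expected)) NA_character_
    else if (is.na(t$expected$threshold_g)) "N/A"
    else format(signif(t$expected$threshold_g, 4), trim = TRUE))))
}
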