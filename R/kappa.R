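# Kappa correction table for the Dixon formula.
#
# The correction kappa is indexed by the pattern of the last six responses
# (the trial before the first change, the change trial, and the four
# post-change trials). The bundled resource is derived numerically by the
# maximum-likelihood construction behind the classical small-sample
# up-down tables: responses follow a cumulative normal in log force with
# scale sigma equal to the step delta; the positions of the six trials
# relative to the final one are fixed by the up-down rule; kappa is the ML
# location estimate measured from the final filament, in delta units.
# Values are computed on the X-leading half of the pattern space and
# negated for complements, so antisymmetry is exact by construction.

#' All legal kappa patterns
#'
#' Six-character strings over `{X, O}` whose first two characters differ
#' (position one is the trial before the first response change, position
#' two is the change itself).
#'
#' @return character vector of 32 patterns.
#' @export
kappa_patterns <- function() {
  tails <- do.call(paste0, expand.grid(rep(list(c("O", "X")), 4),
                                       stringsAsFactors = FALSE))
  sort(c(paste0("XO", tails), paste0("OX", tails)))
}

#' Complement a response pattern
#' @param pattern string over `{X, O}`.
#' @return the pattern with X and O swapped.
#' @export
complement_pattern <- function(pattern) chartr("XO", "OX", pattern)

check_pattern <- function(pattern) {
  if (length(pattern) != 1 || !grepl("^[XO]{6}$", pattern))
    stop_updown("updown_domain", "pattern must be a 6-character string over {X,O}")
  ch <- strsplit(pattern, "")[[1]]
  if (ch[1] == ch[2])
    stop_updown("updown_domain",
                "positions 1 and 2 of a kappa pattern must differ (pre-change vs change)")
  ch
}

# Trial positions (in delta units) relative to the final trial at 0:
# the next index steps down after X, up after O.
pattern_positions <- function(ch) {
  x <- numeric(6)
  for (i in 5:1) x[i] <- x[i + 1] + if (ch[i] == "X") 1 else -1
  x
}

#' Derive kappa for one response pattern
#'
#' Maximum-likelihood location of a cumulative-normal response curve
#' (sigma = step) given the six trials of the pattern, measured from the
#' final filament in step units.
#'
#' @param pattern 6-character string over `{X, O}`, first two differing.
#' @return kappa (numeric scalar).
#' @examples
#' derive_kappa("XOXOXO")  # exactly 0.5 by symmetry
#' @export
derive_kappa <- function(pattern) {
  ch <- check_pattern(pattern)
  x <- pattern_positions(ch)
  pos <- ch == "X"
  nll <- function(mu)
    -sum(pnorm(x[pos] - mu, log.p = TRUE)) - sum(pnorm(mu - x[!pos], log.p = TRUE))
  opt <- optimize(nll, interval = c(-8, 8), tol = 1e-10)
  opt$minimum
}

#' Compute the full kappa table
#'
#' Computed on patterns starting with X and negated for complements, so
#' `kappa(complement(p)) == -kappa(p)` holds exactly.
#'
#' @return named numeric vector of class `kappa_table` (names are patterns).
#' @export
make_kappa_table <- function() {
  pats <- kappa_patterns()
  lead_x <- pats[startsWith(pats, "X")]
  k <- vapply(lead_x, derive_kappa, numeric(1))
  out <- c(k, stats::setNames(-k, complement_pattern(lead_x)))
  out <- out[order(names(out))]
  structure(out, class = "kappa_table")
}

#' Load the bundled kappa resource
#'
#' Plain-text key/value table (`pattern kappa`, `#` comments). Validated at
#' load: every pattern legal, complement present, antisymmetry within 1e-6.
#' The result is cached for the session.
#'
#' @param path resource file; default is the bundled synthetic table.
#' @return named numeric vector of class `kappa_table`.
#' @export
load_kappa_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.updown_env$kappa)) return(.updown_env$kappa)
    path <- system.file("extdata", "kappa_table_synthetic.txt",
                        package = "updown", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 2))
    stop_updown("updown_parse", "malformed kappa resource line in %s", path)
  pats <- vapply(parts, `[[`, character(1), 1)
  vals <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(vals) || anyDuplicated(pats))
    stop_updown("updown_parse", "bad kappa values or duplicate patterns in %s", path)
  tab <- structure(stats::setNames(vals, pats), class = "kappa_table")
  for (p in pats) {
    check_pattern(p)
    cp <- complement_pattern(p)
    if (!cp %in% pats)
      stop_updown("updown_parse", "kappa table misses complement of %s", p)
    if (abs(tab[[cp]] + tab[[p]]) > 1e-6)
      stop_updown("updown_parse", "kappa antisymmetry violated for %s", p)
  }
  if (cache) .updown_env$kappa <- tab
  tab
}

#' Look up kappa for a pattern
#' @param table a `kappa_table`.
#' @param pattern 6-character response pattern.
#' @return kappa value.
#' @export
kappa_lookup <- function(table, pattern) {
  if (!pattern %in% names(table))
    stop_updown("updown_missing_kappa", "pattern '%s' absent from kappa table", pattern)
  unname(table[[pattern]])
}

#' Write the kappa table as the plain-text resource format
#' @param table a `kappa_table` (default: freshly computed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kappa_table <- function(table = make_kappa_table(), path) {
  hdr <- c(
    "# kappa correction table (SYNTHETIC, numerically derived)",
    "# Maximum-likelihood location of a cumulative-normal response curve",
    "# (sigma = step) over the six trials of each pattern, measured from the",
    "# final filament in step units. Antisymmetric by construction.",
    "# columns: pattern kappa")
  body <- sprintf("%s % .6f", names(table), as.numeric(table))
  writeLines(c(hdr, body), path)
  invisible(path)
}
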