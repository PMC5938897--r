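# Filament ladders for the four supported assays.
#
# The published force *ranges* are: mouse 0.04-4 g, rat 0.6-15 g, human
# MDT 0.02-1.4 g, human MPT 4-180 g, with mid-range start filaments
# (mouse 0.6 g, rat 4 g, MDT 0.4 g, MPT 8 g). The exact sets below are the
# standard commercial von Frey kit restricted to those ranges; their mean
# log spacings reproduce the printed delta constants for mouse (0.25),
# rat (0.17) and MPT (0.21). For MDT the printed 0.25 and the ladder mean
# (~0.26) disagree slightly; the printed constant is used in the formula
# and both values are stored on the ladder.

.ladder_specs <- list(
  mouse = list(
    forces_g = c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0, 4.0),
    start_index = 5L, delta = 0.25),
  rat = list(
    forces_g = c(0.6, 1.0, 1.4, 2.0, 4.0, 6.0, 8.0, 10, 15),
    start_index = 5L, delta = 0.17),
  human_mdt = list(
    forces_g = c(0.02, 0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4),
    start_index = 5L, delta = 0.25),
  human_mpt = list(
    forces_g = c(4, 6, 8, 10, 15, 26, 60, 100, 180),
    start_index = 3L, delta = 0.21))

#' Supported assays
#' @return character vector of assay identifiers.
#' @export
updown_assays <- function() names(.ladder_specs)

#' Convert gram-force to log units
#'
#' The log-unit convention is the filament handle marking: log10 of the
#' force expressed in 0.1 mg units, i.e. `log10(10000 * grams)`. Under this
#' convention a kappa of zero makes the Dixon formula return exactly the
#' final filament force.
#'
#' @param force_g force in grams (> 0).
#' @return numeric log-unit value(s).
#' @examples
#' grams_to_log_units(1)    # 4
#' grams_to_log_units(0.6)  # log10(6000)
#' @export
grams_to_log_units <- function(force_g) {
  if (!is.numeric(force_g) || any(!is.finite(force_g)) || any(force_g <= 0))
    stop_updown("updown_domain", "force_g must be positive and finite")
  log10(10000 * force_g)
}

#' Convert gram-force to millinewtons
#'
#' Uses standard gravity (1 gf = 9.80665 mN).
#'
#' @param force_g force in grams.
#' @return force in mN.
#' @export
grams_to_mN <- function(force_g) force_g * 9.80665

#' Build the filament ladder for an assay
#'
#' A ladder is the ordered set of filament forces for one assay, with
#' log-unit values, the step constant delta used by the Dixon formula, the
#' ladder-derived mean log spacing, and the start (mid-range) filament.
#'
#' @param assay one of `"mouse"`, `"rat"`, `"human_mdt"`, `"human_mpt"`.
#' @return an object of class `filament_ladder` with fields `assay`,
#'   `forces_g`, `log_units`, `delta` (printed constant, used in the
#'   threshold formula), `delta_mean` (mean successive log difference),
#'   `start_index`, `n_filaments`.
#' @examples
#' build_ladder("mouse")
#' @export
build_ladder <- function(assay) {
  if (length(assay) != 1 || !assay %in% names(.ladder_specs))
    stop_updown("updown_unsupported_assay",
                "unsupported assay '%s' (expected one of %s)",
                paste(assay, collapse = ","),
                paste(names(.ladder_specs), collapse = ", "))
  spec <- .ladder_specs[[assay]]
  lu <- grams_to_log_units(spec$forces_g)
  structure(list(
    assay = assay,
    forces_g = spec$forces_g,
    log_units = lu,
    delta = spec$delta,
    delta_mean = mean(diff(lu)),
    start_index = spec$start_index,
    n_filaments = length(spec$forces_g)),
    class = "filament_ladder")
}

#' @export
print.filament_ladder <- function(x, ...) {
  cat(sprintf("<filament_ladder: %s, %d filaments %g-%g g, start %g g, delta %g>\n",
              x$assay, x$n_filaments, min(x$forces_g), max(x$forces_g),
              x$forces_g[x$start_index], x$delta))
  invisible(x)
}

#' Dixon 50% threshold formula
#'
#' `10^(Xf + kappa * delta) / 10000` grams, where `Xf` is the log-unit
#' value of the final filament used.
#'
#' @param final_force_g final filament force in grams.
#' @param kappa tabulated correction for the response pattern.
#' @param delta mean log-unit spacing between stimuli.
#' @return threshold in grams.
#' @export
dixon_threshold <- function(final_force_g, kappa, delta) {
  10^(grams_to_log_units(final_force_g) + kappa * delta) / 10000
}
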