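# Report rendering. Exact values are the computational currency everywhere
# else; these helpers are the only place display rounding happens, so that
# machine output (full precision) and human output (rounded) never drift.

.strip_trailing_zero <- function(s) sub("\\.0$", "", s)

#' Format a volume for display
#'
#' Volumes below 0.01 mL display in microlitres to one decimal; larger
#' volumes display in mL, rounded to `ml_digits` decimals (a trailing
#' `".0"` is dropped, so 3.0 renders as `"3 mL"`). Formatting is a pure
#' function of the exact value; nothing upstream is rounded.
#'
#' @param ml Volume in mL.
#' @param ml_digits Decimals for the mL display: 1 for per-female unit
#'   volumes, 0 (default) for plan-scale volumes.
#' @return Display string, e.g. `"1.5 mL"`, `"395 mL"`, `"0.3 µL"`.
#' @export
format_volume <- function(ml, ml_digits = 0) {
  stopifnot(is.numeric(ml), length(ml) == 1L, is.finite(ml), ml >= 0)
  if (ml < 0.01 && ml > 0) {
    sprintf("%s \u00b5L", .strip_trailing_zero(sprintf("%.1f", ml * 1000)))
  } else {
    sprintf("%s mL",
            .strip_trailing_zero(sprintf("%.*f", as.integer(ml_digits), ml)))
  }
}

#' Format a count of freezing containers for display
#'
#' @param n Whole container count.
#' @param container_label Container description from the profile; used to
#'   pick the short noun ("straws", "vials", or "containers").
#' @return Display string, e.g. `"3 straws"`, `"1 vial"`.
#' @export
format_containers <- function(n, container_label = "container") {
  noun <- if (grepl("straw", container_label, ignore.case = TRUE)) {
    "straw"
  } else if (grepl("vial", container_label, ignore.case = TRUE)) {
    "vial"
  } else {
    "container"
  }
  sprintf("%d %s%s", as.integer(n), noun, if (n == 1) "" else "s")
}

#' Format an egg count for display
#'
#' Counts of 100,000 or more display at two significant figures in
#' scientific notation (hatchery-scale magnitudes); smaller counts display
#' as plain integers.
#'
#' @param eggs Whole egg count.
#' @return Display string, e.g. `"176"` or `"2.9e+06"`.
#' @export
format_eggs <- function(eggs) {
  stopifnot(is.numeric(eggs), length(eggs) == 1L, is.finite(eggs), eggs >= 0)
  if (eggs >= 1e5) {
    sprintf("%.1e", signif(eggs, 2))
  } else {
    sprintf("%d", as.integer(eggs))
  }
}

#' Per-female fertilization unit table for the packaged species
#'
#' One row per species: the inputs (eggs per female, sperm:egg ratio,
#' concentration, container fill volume) and the computed unit (required
#' sperm cells, fresh volume, whole containers), with exact values alongside
#' the display renderings.
#'
#' @param species Character vector of species keys or profile file paths;
#'   defaults to the packaged species.
#' @return Data frame with exact and display columns.
#' @examples
#' unit_table()[, c("species", "volume_display", "unit_display")]
#' @export
unit_table <- function(species = list_species()) {
  rows <- lapply(species, function(key) {
    p <- load_profile(key)
    u <- frozen_unit(p)
    data.frame(
      species              = p$species_name,
      eggs_per_female      = p$eggs_per_female,
      sperm_egg_ratio      = p$sperm_egg_ratio,
      sperm_concentration_per_ml = p$sperm_concentration_per_ml,
      container_volume_ml  = p$container_volume_ml,
      required_sperm_cells = u$required_sperm_cells,
      fresh_volume_ml      = u$fresh_volume_ml,
      containers           = u$containers,
      containers_exact     = u$containers_exact,
      volume_display       = format_volume(u$fresh_volume_ml, ml_digits = 1),
      unit_display         = format_containers(u$containers,
                                               p$container_label),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Production requirement table for the packaged species
#'
#' One row per species: the offspring target and the back-calculated egg
#' requirement, sperm volume, container count and minimum broodstock
#' numbers, with exact values alongside display renderings.
#'
#' @inheritParams unit_table
#' @param apply_pool_minimum Apply each profile's male pool-size floor (see
#'   [broodstock_minima()])? Off by default; the raw calculated minimum is
#'   always included.
#' @return Data frame with exact and display columns.
#' @examples
#' production_table()[, c("species", "eggs_display", "volume_display",
#'                        "containers_display")]
#' @export
production_table <- function(species = list_species(),
                             apply_pool_minimum = FALSE) {
  rows <- lapply(species, function(key) {
    p <- load_profile(key)
    plan <- production_plan(p, apply_pool_minimum = apply_pool_minimum)
    data.frame(
      species             = p$species_name,
      target_offspring    = plan$target_offspring,
      survival_stage      = plan$survival_stage_label,
      eggs_required       = plan$eggs_required,
      eggs_required_exact = plan$eggs_required_exact,
      sperm_volume_ml     = plan$sperm_volume_ml,
      containers          = plan$containers,
      min_males           = plan$min_males,
      min_males_raw       = plan$min_males_raw,
      min_females         = plan$min_females,
      eggs_display        = format_eggs(plan$eggs_required),
      volume_display      = format_volume(plan$sperm_volume_ml),
      containers_display  = format_containers(plan$containers,
                                              p$container_label),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
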