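# The fertilization unit: the sperm dose that reliably fertilizes all
# viable eggs produced by one female, expressed as a fresh volume or a
# whole number of cryopreservation containers.

# Least non-negative integer n with n * step >= requirement. A bare
# ceiling(requirement/step) can be off by one when the division rounds
# across an integer boundary; the correction loops restore the defining
# inequality in floating point.
least_cover_count <- function(requirement, step) {
  if (step <= 0) stop("step must be strictly positive", call. = FALSE)
  if (requirement <= 0) return(0)
  n <- ceiling(requirement / step)
  while (n > 0 && (n - 1) * step >= requirement) n <- n - 1
  while (n * step < requirement) n <- n + 1
  n
}

#' Fresh-sperm fertilization unit volume
#'
#' The volume of fresh sperm, at the profile concentration, holding enough
#' cells to fertilize one female's eggs:
#' `eggs * sperm_egg_ratio / sperm_concentration_per_ml` (mL).
#' The exact value is returned; display rounding belongs to the report layer
#' (see [format_volume()]).
#'
#' @param profile A valid [species_profile()].
#' @param eggs Number of eggs to cover; defaults to the profile's
#'   `eggs_per_female`. May be overridden (including to 0) for what-if
#'   calculations.
#' @return Volume in mL.
#' @examples
#' fresh_unit_volume(load_profile("catfish")) # 1.485 mL
#' @export
fresh_unit_volume <- function(profile, eggs = profile$eggs_per_female) {
  profile <- validate_species_profile(profile)
  if (!is.numeric(eggs) || length(eggs) != 1L || !is.finite(eggs) || eggs < 0) {
    stop("eggs must be a single non-negative number", call. = FALSE)
  }
  eggs * profile$sperm_egg_ratio / profile$sperm_concentration_per_ml
}

#' Cryopreserved-sperm fertilization unit
#'
#' Sizes the dose for one female in frozen form: the required sperm cell
#' count, the equivalent volume at the in-container concentration, and the
#' number of freezing containers rounded up to a whole container so no
#' container is partially used. Cell counts and volumes are never rounded;
#' only the container count is.
#'
#' @param profile A valid [species_profile()].
#' @return An object of class `fertilization_unit` with fields
#'   `species_name`, `required_sperm_cells`, `fresh_volume_ml`, `containers`
#'   (integer, rounded up), `containers_exact` (unrounded), `excess_factor`
#'   (sperm frozen in the rounded-up unit over sperm required; equals 1 only
#'   when the unit is an exact whole number of containers), and
#'   `container_label`.
#' @examples
#' frozen_unit(load_profile("oyster")) # 6 straws, exactly
#' @export
frozen_unit <- function(profile) {
  profile <- validate_species_profile(profile)
  required <- profile$eggs_per_female * profile$sperm_egg_ratio
  volume <- required / profile$sperm_concentration_per_ml
  n <- least_cover_count(volume, profile$container_volume_ml)
  structure(list(
    species_name         = profile$species_name,
    required_sperm_cells = required,
    fresh_volume_ml      = volume,
    containers           = as.integer(n),
    containers_exact     = volume / profile$container_volume_ml,
    excess_factor        = n * profile$container_volume_ml *
      profile$sperm_concentration_per_ml / required,
    container_label      = profile$container_label
  ), class = "fertilization_unit")
}

#' Excess-sperm factor of a fertilization unit
#'
#' How many times more sperm is committed than is strictly required for one
#' female. Two bases are exposed because they answer different questions:
#'
#' * `"container"`: sperm content of one filled container over the sperm
#'   required for one female. This is the natural basis when a single
#'   container exceeds a whole unit, as for zebrafish, where one 0.02 mL
#'   cryo-vial at 1e8 cells/mL holds about 66.7 times the 3e4 cells needed.
#' * `"unit"`: sperm content of the whole rounded-up unit (all its
#'   containers) over the sperm required. This reflects the waste introduced
#'   by rounding up to whole containers (catfish: 3 straws vs 2.97 needed,
#'   factor about 1.01).
#'
#' @param profile A valid [species_profile()].
#' @param basis `"container"` (default) or `"unit"`.
#' @return Dimensionless ratio; always >= 1 on the `"unit"` basis.
#' @examples
#' excess_factor(load_profile("zebrafish"))         # ~66.7
#' excess_factor(load_profile("catfish"), "unit")   # ~1.01
#' @export
excess_factor <- function(profile, basis = c("container", "unit")) {
  profile <- validate_species_profile(profile)
  basis <- match.arg(basis)
  required <- profile$eggs_per_female * profile$sperm_egg_ratio
  if (required <= 0) {
    stop("required sperm is zero; excess factor undefined", call. = FALSE)
  }
  per_container <- profile$container_volume_ml *
    profile$sperm_concentration_per_ml
  if (basis == "container") {
    per_container / required
  } else {
    frozen_unit(profile)$excess_factor
  }
}

#' Update profile fields for a what-if calculation
#'
#' Returns a copy of the profile with the named fields replaced and
#' re-validated, for perturbation analyses such as recomputing a unit after
#' an order-of-magnitude drop in sperm concentration.
#'
#' @param profile A valid [species_profile()].
#' @param ... Named profile fields to replace.
#' @return A validated [species_profile()].
#' @examples
#' p <- update_profile(load_profile("catfish"),
#'                     sperm_concentration_per_ml = 1e8)
#' frozen_unit(p)$containers # 30 straws instead of 3
#' @export
update_profile <- function(profile, ...) {
  profile <- validate_species_profile(profile)
  changes <- list(...)
  if (length(changes) && is.null(names(changes))) {
    stop("profile updates must be named", call. = FALSE)
  }
  unknown <- setdiff(names(changes), names(.profile_field_kinds))
  if (length(unknown)) {
    stop(sprintf("unknown species profile field '%s'", unknown[[1L]]),
         call. = FALSE)
  }
  p <- unclass(profile)
  p[names(changes)] <- changes
  validate_species_profile(p)
}

#' @export
print.fertilization_unit <- function(x, ...) {
  cat(sprintf("Fertilization unit: %s\n", x$species_name))
  cat(sprintf("  required sperm        %g cells\n", x$required_sperm_cells))
  cat(sprintf("  fresh volume          %s (exact %g mL)\n",
              format_volume(x$fresh_volume_ml, ml_digits = 1),
              x$fresh_volume_ml))
  cat(sprintf("  frozen containers     %d (%s; exact %.4g)\n",
              x$containers, x$container_label, x$containers_exact))
  cat(sprintf("  unit excess factor    %.4g\n", x$excess_factor))
  invisible(x)
}
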