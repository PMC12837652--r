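# Production planning: back-calculate eggs, sperm volume, container count,
# and minimum broodstock numbers from a target offspring count.

#' Eggs required for a production target
#'
#' Inverts the survival chain: a target number of offspring at the chosen
#' life stage requires `target / survival_rate / fertilization_rate` eggs.
#' The two divisions are applied with no intermediate rounding; the result
#' is then rounded up to the least whole egg count whose expected output
#' (`eggs * fertilization_rate * survival_rate`) still meets the target.
#'
#' @param target Desired number of surviving offspring (>= 1).
#' @param survival_rate Fraction surviving from fertilized egg to the target
#'   stage, in (0, 1].
#' @param fertilization_rate Fraction of eggs fertilized, in (0, 1].
#' @return List with `eggs` (whole-egg count, as a double to allow counts
#'   beyond integer range) and `exact` (the unrounded requirement).
#' @examples
#' eggs_required(100, survival_rate = 0.95, fertilization_rate = 0.60) # 176
#' @export
eggs_required <- function(target, survival_rate, fertilization_rate) {
  for (nm in c("target", "survival_rate", "fertilization_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
  }
  if (target < 1 || target != floor(target)) {
    stop("target must be a positive whole number", call. = FALSE)
  }
  if (survival_rate <= 0 || survival_rate > 1) {
    stop("survival_rate must be in (0, 1]", call. = FALSE)
  }
  if (fertilization_rate <= 0 || fertilization_rate > 1) {
    stop("fertilization_rate must be in (0, 1]", call. = FALSE)
  }
  exact <- target / survival_rate / fertilization_rate
  n <- ceiling(exact)
  # enforce the guarantee inequality in floating point
  while (n > 1 && (n - 1) * fertilization_rate * survival_rate >= target) {
    n <- n - 1
  }
  while (n * fertilization_rate * survival_rate < target) n <- n + 1
  list(eggs = n, exact = exact)
}

#' Sperm volume required to fertilize a number of eggs
#'
#' `eggs * sperm_egg_ratio / sperm_concentration_per_ml`, in mL, exact
#' (no rounding).
#'
#' @param eggs Number of eggs to fertilize (>= 0).
#' @param profile A valid [species_profile()].
#' @return Volume in mL.
#' @export
sperm_volume_required <- function(eggs, profile) {
  fresh_unit_volume(profile, eggs = eggs)
}

#' Freezing containers required to hold a sperm volume
#'
#' Rounds up to whole containers: the least non-negative integer `n` with
#' `n * container_volume_ml >= volume_ml`. Zero volume needs zero
#' containers.
#'
#' @param volume_ml Sperm volume to package, mL (>= 0).
#' @param container_volume_ml Fill volume of one container, mL (> 0).
#' @return Whole number of containers.
#' @examples
#' containers_required(395.08, 0.5) # 791
#' @export
containers_required <- function(volume_ml, container_volume_ml) {
  if (!is.numeric(volume_ml) || length(volume_ml) != 1L ||
      !is.finite(volume_ml) || volume_ml < 0) {
    stop("volume_ml must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(container_volume_ml) || length(container_volume_ml) != 1L ||
      !is.finite(container_volume_ml) || container_volume_ml <= 0) {
    stop("container_volume_ml must be strictly positive", call. = FALSE)
  }
  least_cover_count(volume_ml, container_volume_ml)
}

#' Minimum broodstock numbers for a plan
#'
#' The fewest females whose pooled eggs cover the egg requirement and the
#' fewest males whose pooled sperm covers the volume requirement, each
#' rounded up to whole animals. Some standard operating procedures impose a
#' floor on the male pool (zebrafish protocols pool sperm from at least 10
#' males even when one would suffice); the floor is applied only when
#' `apply_pool_minimum = TRUE`, and the unfloored value is always reported.
#'
#' @param eggs Egg requirement (>= 0).
#' @param volume_ml Sperm volume requirement, mL (>= 0).
#' @param profile A valid [species_profile()].
#' @param apply_pool_minimum Apply the profile's `male_pool_minimum` floor?
#' @return List with `min_males`, `min_males_raw`, `min_females`.
#' @export
broodstock_minima <- function(eggs, volume_ml, profile,
                              apply_pool_minimum = FALSE) {
  profile <- validate_species_profile(profile)
  min_females <- least_cover_count(eggs, profile$eggs_per_female)
  min_males_raw <- least_cover_count(volume_ml,
                                     profile$sperm_volume_per_male_ml)
  min_males <- min_males_raw
  if (isTRUE(apply_pool_minimum) && profile$male_pool_minimum > 0) {
    min_males <- max(min_males_raw, profile$male_pool_minimum)
  }
  list(min_males = min_males, min_males_raw = min_males_raw,
       min_females = min_females)
}

#' Full production plan for a species
#'
#' Chains the planning steps: eggs from the target and the survival chain,
#' sperm volume from the eggs, whole containers from the volume, and minimum
#' broodstock from eggs and volume. The exact (unrounded) egg requirement is
#' retained for audit, but the whole-egg count feeds the volume calculation
#' (count semantics).
#'
#' @param profile A valid [species_profile()].
#' @param target Offspring target; defaults to the profile's
#'   `target_offspring`.
#' @param apply_pool_minimum Apply the male pool-size floor (see
#'   [broodstock_minima()])? Off by default.
#' @return An object of class `production_plan`.
#' @examples
#' production_plan(load_profile("catfish"))
#' @export
production_plan <- function(profile, target = NULL,
                            apply_pool_minimum = FALSE) {
  profile <- validate_species_profile(profile)
  if (is.null(target)) target <- profile$target_offspring
  egg <- eggs_required(target, profile$survival_rate,
                       profile$fertilization_rate)
  volume <- sperm_volume_required(egg$eggs, profile)
  n_containers <- containers_required(volume, profile$container_volume_ml)
  brood <- broodstock_minima(egg$eggs, volume, profile,
                             apply_pool_minimum = apply_pool_minimum)
  structure(list(
    species_name         = profile$species_name,
    target_offspring     = target,
    survival_stage_label = profile$survival_stage_label,
    eggs_required        = egg$eggs,
    eggs_required_exact  = egg$exact,
    sperm_volume_ml      = volume,
    containers           = n_containers,
    container_label      = profile$container_label,
    min_males            = brood$min_males,
    min_males_raw        = brood$min_males_raw,
    min_females          = brood$min_females,
    pool_minimum_applied = isTRUE(apply_pool_minimum) &&
      profile$male_pool_minimum > 0
  ), class = "production_plan")
}

#' @export
print.production_plan <- function(x, ...) {
  cat(sprintf("Production plan: %s\n", x$species_name))
  cat(sprintf("  target offspring   %s (%s)\n",
              format(x$target_offspring, big.mark = ",", scientific = FALSE),
              x$survival_stage_label))
  cat(sprintf("  eggs required      %s (exact %.2f)\n",
              format(x$eggs_required, big.mark = ",", scientific = FALSE),
              x$eggs_required_exact))
  cat(sprintf("  sperm volume       %s (exact %g mL)\n",
              format_volume(x$sperm_volume_ml), x$sperm_volume_ml))
  cat(sprintf("  containers         %s (%s)\n",
              format(x$containers, big.mark = ","), x$container_label))
  males <- format(x$min_males, big.mark = ",")
  if (x$pool_minimum_applied && x$min_males != x$min_males_raw) {
    males <- sprintf("%s (calculated %s; SOP pool minimum applied)",
                     males, format(x$min_males_raw, big.mark = ","))
  }
  cat(sprintf("  min males          %s\n", males))
  cat(sprintf("  min females        %s\n",
              format(x$min_females, big.mark = ",")))
  invisible(x)
}
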