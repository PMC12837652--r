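# Species parameter profiles: the husbandry metrics that drive every
# downstream dose and planning calculation. Canonical units are mL for
# volumes and cells/mL for concentrations; microlitre keys (*_ul) are
# accepted on input and converted.

# field name -> validation kind
.profile_field_kinds <- c(
  species_name               = "label",
  eggs_per_female            = "positive",
  sperm_egg_ratio            = "positive",
  sperm_concentration_per_ml = "positive",
  container_volume_ml        = "positive",
  container_label            = "label",
  sperm_volume_per_male_ml   = "positive",
  fertilization_rate         = "rate",
  survival_rate              = "rate",
  survival_stage_label       = "label",
  target_offspring           = "count",
  male_pool_minimum          = "nonneg_count",
  concentration_context      = "context"
)

# *_ul keys accepted on input, divided by 1000 into the canonical mL field
.microlitre_aliases <- c(
  container_volume_ul      = "container_volume_ml",
  sperm_volume_per_male_ul = "sperm_volume_per_male_ml"
)

.optional_fields <- c("male_pool_minimum", "concentration_context")

#' Construct a validated species parameter profile
#'
#' A species profile bundles the husbandry metrics needed to size a
#' fertilization unit and back-calculate production requirements: fecundity,
#' the sperm-to-egg ratio used at fertilization, sperm concentration, the
#' fill volume of the freezing container, per-male sperm yield, fertilization
#' and survival rates, and the production target.
#'
#' @param species_name Text label for the species.
#' @param eggs_per_female Average number of viable eggs produced per female.
#' @param sperm_egg_ratio Sperm cells applied per egg (a protocol parameter,
#'   not a derived quantity).
#' @param sperm_concentration_per_ml Sperm cells per mL, as diluted for use
#'   (the same number describes fresh sperm and the in-container sample; see
#'   `concentration_context`).
#' @param container_volume_ml Fill volume of one freezing container in mL.
#'   This is the volume actually frozen, which can be far below the nominal
#'   container capacity (zebrafish cryo-vials hold 0.5 mL but are filled with
#'   0.02 mL of sample).
#' @param container_label Text describing the container, e.g.
#'   `"0.5 mL French straw"`.
#' @param sperm_volume_per_male_ml Average sperm volume collected per male, mL.
#' @param fertilization_rate Fraction of eggs fertilized, in (0, 1].
#' @param survival_rate Fraction of fertilized eggs surviving to the stage in
#'   `survival_stage_label`, in (0, 1].
#' @param survival_stage_label Life stage at which survival is assessed,
#'   e.g. `"swim-up fry"`, `"28 dpf"`, `"spat"`.
#' @param target_offspring Default production target (offspring surviving to
#'   the stage above) for planning, a positive whole number.
#' @param male_pool_minimum Standard-operating-procedure floor on the number
#'   of males pooled when collecting sperm (10 for zebrafish, 0 = no floor).
#' @param concentration_context How the single concentration number is used:
#'   `"fresh_and_container"` (default; one value serves both roles, as in the
#'   packaged profiles), `"fresh"`, or `"container"`.
#' @return An object of class `species_profile` (a named list).
#' @seealso [load_profile()], [save_profile()], [frozen_unit()],
#'   [production_plan()]
#' @examples
#' species_profile(
#'   species_name = "demo minnow", eggs_per_female = 500,
#'   sperm_egg_ratio = 100, sperm_concentration_per_ml = 1e7,
#'   container_volume_ml = 0.25, container_label = "0.25 mL straw",
#'   sperm_volume_per_male_ml = 0.5, fertilization_rate = 0.8,
#'   survival_rate = 0.5, survival_stage_label = "fry",
#'   target_offspring = 1000
#' )
#' @export
species_profile <- function(species_name,
                            eggs_per_female,
                            sperm_egg_ratio,
                            sperm_concentration_per_ml,
                            container_volume_ml,
                            container_label,
                            sperm_volume_per_male_ml,
                            fertilization_rate,
                            survival_rate,
                            survival_stage_label,
                            target_offspring,
                            male_pool_minimum = 0,
                            concentration_context = "fresh_and_container") {
  p <- list(
    species_name               = species_name,
    eggs_per_female            = eggs_per_female,
    sperm_egg_ratio            = sperm_egg_ratio,
    sperm_concentration_per_ml = sperm_concentration_per_ml,
    container_volume_ml        = container_volume_ml,
    container_label            = container_label,
    sperm_volume_per_male_ml   = sperm_volume_per_male_ml,
    fertilization_rate         = fertilization_rate,
    survival_rate              = survival_rate,
    survival_stage_label       = survival_stage_label,
    target_offspring           = target_offspring,
    male_pool_minimum          = male_pool_minimum,
    concentration_context      = concentration_context
  )
  validate_species_profile(p)
}

#' Validate a species profile
#'
#' Checks field presence, types and ranges: rates must lie strictly in
#' (0, 1], counts, volumes and concentrations must be strictly positive, and
#' the male pool minimum must be a non-negative whole number. Errors name the
#' offending field.
#'
#' @param profile A named list or `species_profile`.
#' @return The validated profile, classed `species_profile`, with fields in
#'   canonical order.
#' @export
validate_species_profile <- function(profile) {
  if (!is.list(profile)) {
    stop("species profile must be a named list", call. = FALSE)
  }
  fields <- names(.profile_field_kinds)
  missing <- setdiff(setdiff(fields, .optional_fields), names(profile))
  if (length(missing)) {
    stop(sprintf("species profile is missing field '%s'", missing[[1L]]),
         call. = FALSE)
  }
  unknown <- setdiff(names(profile), fields)
  if (length(unknown)) {
    stop(sprintf(
      "unknown species profile field '%s' (unit-suffixed canonical names are required)",
      unknown[[1L]]), call. = FALSE)
  }
  if (is.null(profile$male_pool_minimum)) profile$male_pool_minimum <- 0
  if (is.null(profile$concentration_context)) {
    profile$concentration_context <- "fresh_and_container"
  }
  for (f in fields) {
    v <- profile[[f]]
    kind <- .profile_field_kinds[[f]]
    bad <- function(why) {
      stop(sprintf("invalid species profile: field '%s' %s", f, why),
           call. = FALSE)
    }
    if (kind == "label") {
      if (!is.character(v) || length(v) != 1L || is.na(v) || !nzchar(v)) {
        bad("must be a non-empty string")
      }
    } else if (kind == "context") {
      if (!is.character(v) || length(v) != 1L ||
          !v %in% c("fresh_and_container", "fresh", "container")) {
        bad("must be one of 'fresh_and_container', 'fresh', 'container'")
      }
    } else {
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        bad("must be a single finite number")
      }
      v <- as.numeric(v)
      if (kind == "positive" && v <= 0) bad("must be strictly positive")
      if (kind == "rate" && (v <= 0 || v > 1)) {
        bad("must be a fraction in (0, 1]")
      }
      if (kind == "count" && (v < 1 || v != floor(v))) {
        bad("must be a positive whole number")
      }
      if (kind == "nonneg_count" && (v < 0 || v != floor(v))) {
        bad("must be a non-negative whole number")
      }
      profile[[f]] <- v
    }
  }
  structure(profile[fields], class = "species_profile")
}

#' List the packaged species profiles
#'
#' @return Character vector of packaged species keys usable with
#'   [load_profile()].
#' @examples
#' list_species()
#' @export
list_species <- function() {
  files <- list.files(system.file("extdata", "profiles", package = "fertunit"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' Load a species profile from a packaged key or a file
#'
#' The packaged keys `"catfish"`, `"zebrafish"` and `"oyster"` return the
#' published parameterizations for blue/channel hybrid catfish, zebrafish
#' (Zebrafish International Resource Center protocol) and eastern oysters.
#' A file path is read according to its extension: `.yaml`/`.yml`, `.json`,
#' or `.csv` (one row per species, header matching the field names).
#'
#' Volume fields may be supplied in microlitres via the alternate keys
#' `container_volume_ul` and `sperm_volume_per_male_ul`; they are converted
#' to the canonical mL fields on load.
#'
#' @param source A packaged species key or a path to a profile file.
#' @return A validated [species_profile()].
#' @examples
#' load_profile("catfish")
#' @export
load_profile <- function(source) {
  if (!is.character(source) || length(source) != 1L || is.na(source)) {
    stop("source must be a single species key or file path", call. = FALSE)
  }
  if (source %in% list_species()) {
    path <- system.file("extdata", "profiles", paste0(source, ".yaml"),
                        package = "fertunit")
    return(.profile_from_fields(yaml::read_yaml(path)))
  }
  if (!file.exists(source)) {
    stop(sprintf(
      "unknown species key or missing file '%s' (packaged keys: %s)",
      source, paste(list_species(), collapse = ", ")), call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", source))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(source),
    json = jsonlite::read_json(source, simplifyVector = TRUE),
    csv  = .profile_fields_from_csv(source),
    stop(sprintf("unsupported profile file extension '.%s'", ext),
         call. = FALSE)
  )
  .profile_from_fields(raw)
}

.profile_fields_from_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 1L) {
    stop("profile CSV must contain exactly one data row", call. = FALSE)
  }
  as.list(df[1L, , drop = FALSE])
}

.profile_from_fields <- function(raw) {
  if (!is.list(raw)) stop("profile file must decode to a mapping", call. = FALSE)
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  for (alias in names(.microlitre_aliases)) {
    if (alias %in% names(raw)) {
      target <- .microlitre_aliases[[alias]]
      if (target %in% names(raw)) {
        stop(sprintf(
          "profile supplies both '%s' and '%s'; give the volume once",
          alias, target), call. = FALSE)
      }
      raw[[target]] <- as.numeric(raw[[alias]]) / 1000
      raw[[alias]] <- NULL
    }
  }
  validate_species_profile(raw)
}

#' Save a species profile to YAML, JSON, or CSV
#'
#' The written file round-trips: `load_profile(destination)` reproduces the
#' profile exactly, including full double precision on numeric fields.
#'
#' @param profile A valid [species_profile()]; it is re-validated before
#'   writing, so an invalid profile is refused.
#' @param destination Output file path.
#' @param dialect `"yaml"`, `"json"`, or `"csv"`; defaults to the extension
#'   of `destination`.
#' @return `destination`, invisibly.
#' @export
save_profile <- function(profile, destination,
                         dialect = c("auto", "yaml", "json", "csv")) {
  profile <- validate_species_profile(profile)
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(sub(".*\\.", "", destination))
    dialect <- switch(ext, yml = "yaml", yaml = "yaml", json = "json",
                      csv = "csv",
                      stop(sprintf(
                        "cannot infer dialect from extension '.%s'", ext),
                        call. = FALSE))
  }
  fields <- unclass(profile)
  if (dialect == "yaml") {
    # character-format doubles at 17 significant digits so the YAML scanner
    # re-reads the exact same binary value
    txt <- vapply(names(fields), function(f) {
      v <- fields[[f]]
      val <- if (is.character(v)) {
        paste0("'", gsub("'", "''", v), "'")
      } else {
        .num17(v)
      }
      paste0(f, ": ", val)
    }, character(1))
    writeLines(txt, destination)
  } else if (dialect == "json") {
    # I(17) = 17 *significant* digits, enough to reproduce any double exactly
    jsonlite::write_json(fields, destination, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE)
  } else {
    chr <- vapply(fields,
                  function(v) if (is.character(v)) v else .num17(v),
                  character(1))
    df <- as.data.frame(as.list(chr), stringsAsFactors = FALSE,
                        check.names = FALSE)
    utils::write.csv(df, destination, row.names = FALSE)
  }
  invisible(destination)
}

.num17 <- function(x) {
  s <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", s)
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("Species profile: %s\n", x$species_name))
  cat(sprintf("  eggs per female          %s\n", format(x$eggs_per_female, big.mark = ",")))
  cat(sprintf("  sperm:egg ratio          %g\n", x$sperm_egg_ratio))
  cat(sprintf("  sperm concentration      %g cells/mL\n", x$sperm_concentration_per_ml))
  cat(sprintf("  container                %s (%g mL fill)\n", x$container_label, x$container_volume_ml))
  cat(sprintf("  sperm volume per male    %g mL\n", x$sperm_volume_per_male_ml))
  cat(sprintf("  fertilization rate       %g\n", x$fertilization_rate))
  cat(sprintf("  survival rate            %g (%s)\n", x$survival_rate, x$survival_stage_label))
  cat(sprintf("  target offspring         %s\n", format(x$target_offspring, big.mark = ",")))
  if (x$male_pool_minimum > 0) {
    cat(sprintf("  male pool minimum (SOP)  %d\n", as.integer(x$male_pool_minimum)))
  }
  invisible(x)
}

#' @export
format.species_profile <- function(x, ...) {
  paste(utils::capture.output(print(x)), collapse = "\n")
}
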