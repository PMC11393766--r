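#' @include AllClasses.R
NULL

#' Read allometric dispersal coefficients from a YAML config
#'
#' Coefficients are data, not code: the file must carry `retention` and
#' `speed` blocks, each with `intercept` and `exponent`, plus an optional
#' `provenance` citation note.  A bundled bird config is available at
#' `system.file("extdata", "allometry_birds.yaml", package = "coalSFS")`.
#'
#' @param path YAML path.
#' @return an [AllometricModel-class].
#' @export
readAllometryConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$retention) || is.null(cfg$speed))
    stop("allometry config must provide 'retention' and 'speed' blocks")
  allometricModel(retention = cfg$retention, speed = cfg$speed,
                  provenance = cfg$provenance %||% "")
}

#' Gut retention time from body mass
#'
#' @param body_mass_g body mass in grams (positive; vectorized).
#' @param am an [AllometricModel-class].
#' @return retention time in minutes.
#' @export
retentionTime <- function(body_mass_g, am) {
  stopifnot(is(am, "AllometricModel"))
  if (any(body_mass_g <= 0)) stop("body mass must be positive")
  am@retention$intercept * body_mass_g^am@retention$exponent
}

#' Flight speed from body mass
#'
#' @inheritParams retentionTime
#' @return flight speed in km/h.
#' @export
flightSpeed <- function(body_mass_g, am) {
  stopifnot(is(am, "AllometricModel"))
  if (any(body_mass_g <= 0)) stop("body mass must be positive")
  am@speed$intercept * body_mass_g^am@speed$exponent
}

#' Allometric seed-dispersal distance
#'
#' Distance is flight speed times gut retention time:
#' `km = (km/h) * (min) / 60`, the exact unit conversion.
#'
#' @inheritParams retentionTime
#' @return data.frame with `body_mass_g`, `speed_kmh`, `retention_min` and
#'   `distance_km`.
#' @export
dispersalDistance <- function(body_mass_g, am) {
  sp <- flightSpeed(body_mass_g, am)
  rt <- retentionTime(body_mass_g, am)
  data.frame(body_mass_g = body_mass_g, speed_kmh = sp, retention_min = rt,
             distance_km = sp * rt / 60)
}

#' Dispersal-distance table for a species list
#'
#' @param species data.frame with columns `name` and `body_mass_g`, or the
#'   path of a TSV with those columns.
#' @param am an [AllometricModel-class].
#' @return data.frame with one row per species.
#' @export
dispersalTable <- function(species, am) {
  if (is.character(species))
    species <- utils::read.table(species, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  if (!all(c("name", "body_mass_g") %in% names(species)))
    stop("species table needs columns 'name' and 'body_mass_g'")
  cbind(species["name"], dispersalDistance(species$body_mass_g, am))
}
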