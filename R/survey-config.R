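#' Configure a synthetic towed-camera survey
#'
#' Builds the configuration object consumed by the synthetic survey
#' generators. The defaults describe a desk-scale two-region survey: four
#' dives over a deep western basin (base depth -3400 m) and three over a
#' shallower eastern area (-2700 m), giving the characteristic ~700 m
#' regional depth offset. Along-track topographic features (a 200 m
#' seamount, a pair of 40 m abyssal hills, a canyon with 20 m walls and a
#' 500 m-wide cross-section) locally raise faunal intensity through
#' per-taxon enhancement factors.
#'
#' @param dives Tibble with one row per dive: `dive_id`, `region`
#'   (`"East"`/`"West"`), `length_m`, `acquisition_hz`, `speed_mps`,
#'   `speed_sd`, `start_lon`, `start_lat`, `heading_deg`.
#' @param features Tibble of along-track bathymetric features: `dive_id`,
#'   `kind` (`"seamount"`, `"hill"` or `"canyon"`), `centre_m`, `width_m`,
#'   `height_m`.
#' @param taxa Tibble with per-taxon regional base intensities
#'   (individuals/m^2): `taxon`, `east`, `west`, `enhancement` (intensity
#'   multiplier reached where topographic relief is maximal).
#' @param altitude_mean,altitude_sd Camera altitude above seafloor (m);
#'   jitter is truncated Gaussian with a 0.1 m floor.
#' @param base_depth_m Named vector of regional base depths (m, negative
#'   down) for `East` and `West`.
#' @param camera Camera opening angles, see [camera_geometry()].
#' @param image_size Height and width of generated images in pixels.
#' @param vignette_strength,cast_strength,brightness_sd,noise_sd Image
#'   degradation parameters: radial vignette falloff in `[0,1]`, greenish
#'   colour-cast strength, per-image brightness jitter sd, additive pixel
#'   noise sd. Set to 0 to disable a degradation.
#' @param regional_mean_abundance Named vector of target track-averaged
#'   total intensities (individuals/m^2) per region; the taxa intensities
#'   are rescaled so the survey's true regional means (topographic
#'   enhancement included) equal these values. Defaults to 0.44 (East) and
#'   0.03 (West), the regional mean abundances of the survey this
#'   generator emulates. `NULL` disables the calibration.
#' @return A `survey_config` object (a list).
#' @export
#' @examples
#' cfg <- survey_config()
#' cfg$dives
survey_config <- function(dives = default_dives(),
                          features = default_features(),
                          taxa = default_taxa(),
                          altitude_mean = 3.5,
                          altitude_sd = 0.4,
                          base_depth_m = c(East = -2700, West = -3400),
                          camera = camera_geometry(),
                          image_size = c(128L, 128L),
                          vignette_strength = 0.6,
                          cast_strength = 0.5,
                          brightness_sd = 0.15,
                          noise_sd = 0.02,
                          regional_mean_abundance = c(East = 0.44,
                                                      West = 0.03)) {
  dives <- as_tibble(dives)
  stopifnot(all(c("dive_id", "region", "length_m", "acquisition_hz",
                  "speed_mps", "speed_sd") %in% names(dives)))
  if (!all(dives$region %in% c("East", "West"))) {
    abort("dive regions must be 'East' or 'West'")
  }
  if (any(dives$length_m <= 0) || any(dives$acquisition_hz <= 0) ||
      any(dives$speed_mps <= 0)) {
    abort("dive lengths, frequencies and speeds must be positive")
  }
  features <- as_tibble(features)
  if (nrow(features) > 0) {
    bad <- setdiff(features$kind, c("seamount", "hill", "canyon"))
    if (length(bad) > 0) {
      abort(paste0("unknown feature kind: ", paste(bad, collapse = ", ")))
    }
    stopifnot(all(features$width_m > 0), all(features$height_m > 0))
  }
  taxa <- as_tibble(taxa)
  stopifnot(all(taxa$east >= 0), all(taxa$west >= 0),
            all(taxa$enhancement >= 1))
  if (!("start_lon" %in% names(dives))) {
    # spread dives ~20 km apart on an east-west line per region
    dives$start_lon <- 18 + 0.2 * seq_len(nrow(dives))
    dives$start_lat <- ifelse(dives$region == "East", -18, -23)
    dives$heading_deg <- 80
  }
  cfg <- structure(list(
    dives = dives, features = features, taxa = taxa,
    altitude_mean = altitude_mean, altitude_sd = altitude_sd,
    base_depth_m = base_depth_m, camera = camera,
    image_size = as.integer(image_size),
    vignette_strength = vignette_strength, cast_strength = cast_strength,
    brightness_sd = brightness_sd, noise_sd = noise_sd
  ), class = "survey_config")
  if (!is.null(regional_mean_abundance)) {
    gt <- survey_ground_truth(cfg)$regional_mean
    for (reg in names(regional_mean_abundance)) {
      cur <- gt$mean_total_intensity[gt$region == reg]
      col <- if (reg == "East") "east" else "west"
      if (length(cur) == 1 && cur > 0) {
        cfg$taxa[[col]] <- cfg$taxa[[col]] *
          regional_mean_abundance[[reg]] / cur
      }
    }
  }
  cfg
}

#' @rdname survey_config
#' @export
default_dives <- function() {
  tibble(
    dive_id = 1:7,
    region = c("West", "West", "West", "West", "East", "East", "East"),
    length_m = c(700, 2600, 1700, 2100, 1100, 1300, 700),
    acquisition_hz = c(0.2, 0.07, 0.07, 0.1, 0.1, 0.1, 0.1),
    speed_mps = c(0.35, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7),
    speed_sd = 0.08
  )
}

#' @rdname survey_config
#' @export
default_features <- function() {
  tibble(
    dive_id = c(2L, 2L, 3L, 6L, 7L),
    kind = c("hill", "hill", "seamount", "canyon", "seamount"),
    centre_m = c(1000, 1450, 850, 650, 350),
    width_m = c(200, 200, 600, 500, 300),
    height_m = c(40, 40, 200, 20, 80)
  )
}

#' @rdname survey_config
#' @export
default_taxa <- function() {
  tibble(
    taxon = c("Foraminifera", "Echinodermata", "Lebensspuren", "Porifera",
              "Cnidaria", "Mollusca", "Arthropoda"),
    east = c(0.10, 0.05, 0.09, 0.08, 0.06, 0.04, 0.02),
    west = c(0.012, 0.008, 0.003, 0.002, 0.002, 0.001, 0.002),
    enhancement = c(1.5, 2.0, 1.5, 3.0, 2.5, 2.0, 2.0)
  )
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config>\n")
  cat("  dives:", nrow(x$dives), " (",
      sum(x$dives$region == "East"), "East /",
      sum(x$dives$region == "West"), "West )\n")
  cat("  total track:", sum(x$dives$length_m), "m\n")
  cat("  taxa:", nrow(x$taxa), " features:", nrow(x$features), "\n")
  invisible(x)
}
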