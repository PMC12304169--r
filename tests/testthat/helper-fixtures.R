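# small survey configurations used across tests

# one flat dive, single taxon at constant intensity, no features
flat_config <- function(length_m = 1000, hz = 0.1, speed = 1, speed_sd = 0,
                        intensity = 0.5, altitude = 3.5, altitude_sd = 0,
                        region = "West", image_size = c(64L, 64L)) {
  survey_config(
    dives = tibble::tibble(dive_id = 1L, region = region,
                           length_m = length_m, acquisition_hz = hz,
                           speed_mps = speed, speed_sd = speed_sd),
    features = tibble::tibble(dive_id = integer(), kind = character(),
                              centre_m = numeric(), width_m = numeric(),
                              height_m = numeric()),
    taxa = tibble::tibble(taxon = "Holothuria", east = intensity,
                          west = intensity, enhancement = 1),
    altitude_mean = altitude, altitude_sd = altitude_sd,
    image_size = image_size,
    regional_mean_abundance = NULL
  )
}

# two dives, one per region, single taxon with a known East/West ratio
two_region_config <- function(east = 0.44, west = 0.03, length_m = 4100) {
  survey_config(
    dives = tibble::tibble(dive_id = 1:2, region = c("West", "East"),
                           length_m = length_m, acquisition_hz = 0.1,
                           speed_mps = 0.7, speed_sd = 0.05),
    features = tibble::tibble(dive_id = integer(), kind = character(),
                              centre_m = numeric(), width_m = numeric(),
                              height_m = numeric()),
    taxa = tibble::tibble(taxon = "Megafauna", east = east, west = west,
                          enhancement = 1),
    altitude_sd = 0.3,
    regional_mean_abundance = NULL
  )
}

# unit table on a straight meridian track, spacing_m apart
line_units <- function(n, spacing_m = 100, dive_id = 1L, lat0 = -23) {
  tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n)),
    dive_id = dive_id,
    centroid_lon = 18,
    centroid_lat = lat0 + (seq_len(n) - 1) * spacing_m / 111194.9
  )
}

# hand-built ring weights: two symmetric neighbours each, weight 1/2
ring_weights <- function(n) {
  nb <- cbind(c(n, seq_len(n - 1)), c(2:n, 1))
  structure(list(ids = sprintf("u%03d", seq_len(n)), nb = nb,
                 w = matrix(0.5, n, 2)),
            class = "spatial_weights")
}

# dense weight matrix from a spatial_weights object (for cross-checks)
weights_matrix <- function(w) {
  n <- length(w$ids)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, w$nb[i, ]] <- w$w[i, ]
  m
}
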