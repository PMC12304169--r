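#' Camera geometry
#'
#' Fixed opening angles of the downward-looking survey camera. The default
#' 48 degree horizontal by 33 degree vertical field of view; the vertical
#' axis is taken as oriented along-track (configurable via `along_track`).
#'
#' @param horizontal_angle,vertical_angle Opening angles in degrees,
#'   each in (0, 180).
#' @param along_track Which angular axis points along the direction of
#'   travel; determines which image dimension is compared against image
#'   spacing in [check_overlap()].
#' @return A `camera_geometry` object.
#' @export
camera_geometry <- function(horizontal_angle = 48, vertical_angle = 33,
                            along_track = c("vertical", "horizontal")) {
  if (horizontal_angle <= 0 || horizontal_angle >= 180 ||
      vertical_angle <= 0 || vertical_angle >= 180) {
    abort("opening angles must be in (0, 180) degrees")
  }
  structure(list(horizontal_angle = horizontal_angle,
                 vertical_angle = vertical_angle,
                 along_track = match.arg(along_track)),
            class = "camera_geometry")
}

#' Visual footprint of one photograph
#'
#' Area of seafloor imaged from altitude `h` by a camera with opening
#' angles `H` x `V`: `(2 h tan(H/2)) * (2 h tan(V/2))` square metres.
#' `footprint_length()` returns the along-track extent of the image,
#' `2 h tan(a/2)` for the along-track axis `a`.
#'
#' @param altitude Altitude(s) above the seafloor in metres, > 0.
#' @param geometry A [camera_geometry()].
#' @return Numeric vector of areas (m^2) or lengths (m).
#' @export
#' @examples
#' footprint_area(3, camera_geometry())  # ~4.75 m^2
footprint_area <- function(altitude, geometry = camera_geometry()) {
  if (any(altitude <= 0)) abort("altitude must be positive")
  h <- altitude
  (2 * h * tan(geometry$horizontal_angle / 2 * pi / 180)) *
    (2 * h * tan(geometry$vertical_angle / 2 * pi / 180))
}

#' @rdname footprint_area
#' @export
footprint_length <- function(altitude, geometry = camera_geometry()) {
  if (any(altitude <= 0)) abort("altitude must be positive")
  ang <- if (geometry$along_track == "vertical") geometry$vertical_angle
         else geometry$horizontal_angle
  2 * altitude * tan(ang / 2 * pi / 180)
}

#' Fill cumulative along-track positions from navigation fixes
#'
#' Within each dive (records sorted by timestamp), the along-track position
#' of an image is the cumulative haversine distance between successive
#' lon/lat fixes, with the first image at 0 m.
#'
#' @param navigation Tibble with `image_id`, `dive_id`, `timestamp_s`,
#'   `lon_deg`, `lat_deg`.
#' @return The input with `along_track_m` (re)computed.
#' @export
along_track_positions <- function(navigation) {
  navigation |>
    dplyr::group_by(.data$dive_id) |>
    dplyr::arrange(.data$timestamp_s, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      if (anyDuplicated(df$timestamp_s)) {
        abort(paste0("duplicate timestamps in dive ", key$dive_id))
      }
      if (nrow(df) == 1) {
        df$along_track_m <- 0
        return(df)
      }
      p <- cbind(df$lon_deg, df$lat_deg)
      step <- geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                       p[-1, , drop = FALSE], r = 6371000)
      df$along_track_m <- c(0, cumsum(step))
      df
    }) |>
    dplyr::ungroup()
}

#' Image overlap diagnostic per dive
#'
#' Compares the mean spacing between successive images against the mean
#' along-track image length. Successive photographs overlap when the image
#' length exceeds the spacing (strict inequality; equality counts as no
#' overlap).
#'
#' @param navigation Navigation tibble with `along_track_m` and
#'   `altitude_m`.
#' @param geometry A [camera_geometry()].
#' @return Tibble per dive: `dive_id`, `mean_spacing_m`,
#'   `mean_image_length_m`, `overlap`.
#' @export
check_overlap <- function(navigation, geometry = camera_geometry()) {
  navigation |>
    dplyr::group_by(.data$dive_id) |>
    dplyr::summarise(
      mean_spacing_m = mean(diff(sort(.data$along_track_m))),
      mean_image_length_m = mean(footprint_length(.data$altitude_m, geometry)),
      .groups = "drop"
    ) |>
    dplyr::mutate(overlap = .data$mean_image_length_m > .data$mean_spacing_m)
}

#' Partition dives into fixed-length sampling units
#'
#' Splits each dive's track into successive `[0,L), [L,2L), ...` intervals
#' of `unit_length_m` metres. A trailing remainder at least half a unit
#' long becomes its own unit; a shorter one is merged into the previous
#' unit. A dive shorter than half a unit yields a single unit covering the
#' whole dive. Every image is assigned to exactly one unit by its
#' along-track position; unit centroids are the mean lon/lat of member
#' images.
#'
#' @param navigation Navigation tibble with `along_track_m` filled.
#' @param unit_length_m Unit length in metres (default 100).
#' @return Tibble of units: `unit_id`, `dive_id`, `region` (if present),
#'   `start_m`, `end_m`, `n_images`, `centroid_lon`, `centroid_lat`,
#'   `depth_m` (mean of member images, if present), `observed_area_m2 = NA`
#'   until pooled, plus an `image_unit` attribute mapping `image_id` to
#'   `unit_id`.
#' @export
partition_units <- function(navigation, unit_length_m = 100) {
  stopifnot(unit_length_m > 0)
  if (!"along_track_m" %in% names(navigation)) {
    abort("navigation lacks along_track_m; run along_track_positions() first")
  }
  res <- purrr::map(split(navigation, navigation$dive_id), function(nav) {
    len <- max(nav$along_track_m)
    edges <- unit_edges(len, unit_length_m)
    idx <- findInterval(nav$along_track_m, edges$start_m)
    units <- edges
    units$dive_id <- nav$dive_id[1]
    if ("region" %in% names(nav)) units$region <- nav$region[1]
    units$unit_id <- sprintf("d%02d_u%03d", nav$dive_id[1],
                             seq_len(nrow(units)))
    agg <- tibble(unit = idx,
                  lon = nav$lon_deg, lat = nav$lat_deg,
                  depth = if ("depth_m" %in% names(nav)) nav$depth_m else NA_real_,
                  along = nav$along_track_m) |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(n_images = dplyr::n(),
                       centroid_lon = mean(.data$lon),
                       centroid_lat = mean(.data$lat),
                       depth_m = mean(.data$depth),
                       centre_along_m = mean(.data$along),
                       .groups = "drop")
    units$n_images <- 0L
    units$centroid_lon <- NA_real_; units$centroid_lat <- NA_real_
    units$depth_m <- NA_real_; units$centre_along_m <- NA_real_
    units[agg$unit, c("n_images", "centroid_lon", "centroid_lat",
                      "depth_m", "centre_along_m")] <-
      agg[, c("n_images", "centroid_lon", "centroid_lat", "depth_m",
              "centre_along_m")]
    map <- tibble(image_id = nav$image_id, unit_id = units$unit_id[idx])
    list(units = units, map = map)
  })
  units <- purrr::map_dfr(res, "units") |>
    dplyr::relocate("unit_id", "dive_id")
  attr(units, "image_unit") <- purrr::map_dfr(res, "map")
  units
}

# interval edges for one dive of length len
unit_edges <- function(len, L) {
  if (len <= L / 2) return(tibble(start_m = 0, end_m = max(len, L / 2)))
  n_full <- floor(len / L)
  rem <- len - n_full * L
  starts <- (seq_len(n_full) - 1) * L
  ends <- starts + L
  if (rem >= L / 2) {
    starts <- c(starts, n_full * L)
    ends <- c(ends, len)
  } else if (rem > 0) {
    ends[n_full] <- len
  }
  # make the final unit closed so the last image is included
  tibble(start_m = starts, end_m = ends)
}

#' Pool detections into units and standardise to abundances
#'
#' Sums detection counts per unit and taxon, accumulates the observed area
#' as the sum of member-image footprints, and divides counts by area to
#' obtain abundances in individuals per square metre. Units containing no
#' images are dropped with a warning.
#'
#' @param units Output of [partition_units()].
#' @param navigation Navigation tibble (with `altitude_m`).
#' @param detections Detection tibble (`image_id`, `taxon`).
#' @param geometry A [camera_geometry()].
#' @param taxa Optional character vector fixing the taxon column order;
#'   defaults to sorted unique taxa in `detections`.
#' @return An abundance tibble of class `abundance_tbl`: one row per unit
#'   with unit metadata, `observed_area_m2`, and one abundance column per
#'   taxon; the taxon names are stored in `attr(, "taxa")`. Raw counts are
#'   in `attr(, "counts")`.
#' @export
pool_and_standardise <- function(units, navigation, detections,
                                 geometry = camera_geometry(),
                                 taxa = NULL) {
  map <- attr(units, "image_unit")
  if (is.null(map)) abort("units must come from partition_units()")
  unknown <- setdiff(detections$image_id, navigation$image_id)
  if (length(unknown) > 0) {
    abort(paste0("detections reference unknown image ids, e.g. ", unknown[1]))
  }
  taxa <- taxa %||% sort(unique(detections$taxon))
  nav <- dplyr::left_join(navigation, map, by = "image_id")
  area <- nav |>
    dplyr::mutate(a = footprint_area(.data$altitude_m, geometry)) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(observed_area_m2 = sum(.data$a), .groups = "drop")
  det <- detections |>
    dplyr::left_join(map, by = "image_id") |>
    dplyr::count(.data$unit_id, .data$taxon)
  empty <- units$unit_id[units$n_images == 0]
  if (length(empty) > 0) {
    warn(paste0("dropping ", length(empty), " unit(s) with no images: ",
                paste(head(empty, 5), collapse = ", ")))
  }
  out <- units |>
    dplyr::filter(.data$n_images > 0) |>
    dplyr::left_join(area, by = "unit_id")
  counts <- matrix(0L, nrow(out), length(taxa),
                   dimnames = list(out$unit_id, taxa))
  if (nrow(det) > 0) {
    det <- det[det$unit_id %in% out$unit_id & det$taxon %in% taxa, ]
    counts[cbind(match(det$unit_id, out$unit_id),
                 match(det$taxon, taxa))] <- det$n
  }
  ab <- sweep(counts, 1, out$observed_area_m2, `/`)
  out <- dplyr::bind_cols(out, as_tibble(ab))
  attr(out, "taxa") <- taxa
  attr(out, "counts") <- counts
  class(out) <- c("abundance_tbl", class(out))
  out
}

#' Extract the numeric abundance matrix from an abundance tibble
#'
#' @param x An `abundance_tbl` from [pool_and_standardise()].
#' @param what `"abundance"` (individuals/m^2) or `"counts"`.
#' @return Numeric matrix, units x taxa, rownames = unit ids.
#' @export
abundance_values <- function(x, what = c("abundance", "counts")) {
  what <- match.arg(what)
  taxa <- attr(x, "taxa")
  if (is.null(taxa)) abort("not an abundance_tbl: missing taxa attribute")
  if (what == "counts") return(attr(x, "counts"))
  m <- as.matrix(as.data.frame(x)[, taxa, drop = FALSE])
  rownames(m) <- x$unit_id
  m
}

#' Check that standardisation decorrelates abundance from observed area
#'
#' For each dive with at least 3 units, reports the Pearson correlation of
#' total counts vs observed area and of total abundance vs observed area.
#' Under camera-driven footprint variability alone (constant faunal
#' intensity) counts scale with area while abundances should not.
#'
#' @param abundance An `abundance_tbl`.
#' @return Tibble per dive: `dive_id`, `n_units`, `r_counts_area`,
#'   `r_abundance_area` (NA where a correlation is undefined because of a
#'   zero-variance input).
#' @export
decorrelation_check <- function(abundance) {
  counts <- rowSums(abundance_values(abundance, "counts"))
  ab <- rowSums(abundance_values(abundance, "abundance"))
  tibble(dive_id = abundance$dive_id, area = abundance$observed_area_m2,
         counts = counts, ab = ab) |>
    dplyr::group_by(.data$dive_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      r_counts_area = safe_cor(.data$counts, .data$area),
      r_abundance_area = safe_cor(.data$ab, .data$area),
      .groups = "drop"
    )
}

safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}
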