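test_that("footprint geometry follows the opening-angle trigonometry", {
  sq <- camera_geometry(90, 90)
  expect_equal(footprint_area(1, sq), 4)
  expect_equal(footprint_area(3, camera_geometry(48, 33)),
               36 * tan(24 * pi / 180) * tan(16.5 * pi / 180),
               tolerance = 1e-12)
  expect_equal(footprint_area(3, camera_geometry(48, 33)), 4.748,
               tolerance = 1e-3)
  expect_lt(footprint_area(1e-6), 1e-10)
  expect_equal(footprint_length(2, camera_geometry(48, 33)),
               4 * tan(16.5 * pi / 180))
  expect_error(footprint_area(0), "positive")
  expect_error(camera_geometry(0, 33), "0, 180")
})

test_that("along-track positions accumulate haversine distances", {
  one <- tibble::tibble(image_id = "a", dive_id = 1L, timestamp_s = 0,
                        lon_deg = 18, lat_deg = -23)
  expect_equal(along_track_positions(one)$along_track_m, 0)

  cfg <- flat_config(length_m = 50, hz = 0.1, speed = 1, speed_sd = 0)
  nav <- generate_navigation(cfg, seed = 1)[, !(names(
    generate_navigation(cfg, seed = 1)) %in% "along_track_m")]
  out <- along_track_positions(nav)
  expect_equal(out$along_track_m, seq(0, 40, by = 10), tolerance = 1e-6)
  # telescoping: final position equals the sum of pairwise steps
  p <- cbind(out$lon_deg, out$lat_deg)
  steps <- geosphere::distHaversine(p[-5, ], p[-1, ], r = 6371000)
  expect_equal(max(out$along_track_m), sum(steps))

  dup <- one[c(1, 1), ]
  dup$image_id <- c("a", "b")
  expect_error(along_track_positions(dup), "duplicate timestamps")
})

test_that("overlap is flagged only when image length exceeds spacing", {
  mk <- function(spacing, altitude) {
    tibble::tibble(image_id = letters[1:5], dive_id = 1L,
                   along_track_m = (0:4) * spacing, altitude_m = altitude)
  }
  g <- camera_geometry(48, 33)
  alt_for_len <- function(len) len / (2 * tan(16.5 * pi / 180))
  expect_false(check_overlap(mk(10, alt_for_len(6)), g)$overlap)
  expect_true(check_overlap(mk(4, alt_for_len(6)), g)$overlap)
  expect_false(check_overlap(mk(6, alt_for_len(6)), g)$overlap)  # boundary
})

test_that("partitioning follows the half-unit remainder rule", {
  mk_nav <- function(len, step = 10) {
    n <- floor(len / step) + 1
    tibble::tibble(
      image_id = sprintf("i%04d", 1:n), dive_id = 1L,
      region = "West", timestamp_s = (1:n) * 10,
      lon_deg = 18, lat_deg = -23 + (0:(n - 1)) * step / 111194.9,
      depth_m = -3400, altitude_m = 3.5,
      along_track_m = (0:(n - 1)) * step
    )
  }
  u100 <- partition_units(mk_nav(100))
  expect_equal(nrow(u100), 1)
  u250 <- partition_units(mk_nav(250))
  expect_equal(u250$start_m, c(0, 100, 200))
  expect_equal(u250$end_m, c(100, 200, 250))
  u230 <- partition_units(mk_nav(230))
  expect_equal(u230$start_m, c(0, 100))
  expect_equal(u230$end_m, c(100, 230))
  u40 <- partition_units(mk_nav(40))
  expect_equal(nrow(u40), 1)
  # every image lands in exactly one unit
  map <- attr(u250, "image_unit")
  expect_equal(nrow(map), 26)
  expect_equal(sum(u250$n_images), 26)
  expect_false(anyNA(map$unit_id))
  # centroid is the mean of member positions
  first <- mk_nav(250)[1:10, ]
  expect_equal(u250$centroid_lat[1], mean(first$lat_deg))
})

test_that("pooling conserves counts and standardises by observed area", {
  mk_nav <- function() {
    tibble::tibble(
      image_id = sprintf("i%02d", 1:10), dive_id = 1L, region = "East",
      timestamp_s = (1:10) * 10, lon_deg = 18,
      lat_deg = -18 + (0:9) * 10 / 111194.9, depth_m = -2700,
      altitude_m = sqrt(2 / (4 * tan(24 * pi / 180) * tan(16.5 * pi / 180))),
      along_track_m = (0:9) * 10
    )
  }
  nav <- mk_nav()  # 10 images x 2 m^2 each = 20 m^2
  det <- tibble::tibble(image_id = rep(nav$image_id, 1),
                        taxon = "Porifera")
  units <- partition_units(nav)
  ab <- pool_and_standardise(units, nav, det)
  expect_equal(unname(ab$observed_area_m2), 20, tolerance = 1e-9)
  expect_equal(unname(abundance_values(ab)[, "Porifera"]), 0.5,
               tolerance = 1e-9)
  expect_equal(sum(abundance_values(ab, "counts")), nrow(det))

  # zero detections: an all-zero abundance row survives
  ab0 <- pool_and_standardise(units, nav,
                              det[0, ], taxa = "Porifera")
  expect_equal(unname(abundance_values(ab0)[, "Porifera"]), 0)

  # duplicating every image and detection leaves abundances unchanged
  nav2 <- dplyr::bind_rows(nav, dplyr::mutate(
    nav, image_id = paste0(image_id, "dup"),
    timestamp_s = timestamp_s + 0.5))
  det2 <- dplyr::bind_rows(det, dplyr::mutate(
    det, image_id = paste0(image_id, "dup")))
  nav2 <- dplyr::arrange(nav2, timestamp_s)
  units2 <- partition_units(nav2)
  ab2 <- pool_and_standardise(units2, nav2, det2)
  expect_equal(abundance_values(ab2), abundance_values(ab),
               tolerance = 1e-12)

  bad <- tibble::tibble(image_id = "nope", taxon = "Porifera")
  expect_error(pool_and_standardise(units, nav, bad), "unknown image")
})

test_that("standardisation decorrelates abundance from observed area", {
  # constant intensity, strongly varying altitude: counts scale with the
  # observed area while abundances should not
  rs <- purrr::map_dfr(1:20, function(s) {
    cfg <- flat_config(length_m = 2000, hz = 0.25, speed = 1,
                       intensity = 2, altitude = 3.5, altitude_sd = 1)
    nav <- generate_navigation(cfg, seed = s)
    det <- generate_detections(nav, cfg, seed = s)
    units <- partition_units(nav)
    ab <- pool_and_standardise(units, nav, det)
    decorrelation_check(ab)
  })
  expect_gt(mean(rs$r_counts_area), 0.5)
  expect_lt(mean(abs(rs$r_abundance_area)), 0.2)
  expect_true(all(abs(rs$r_abundance_area) < abs(rs$r_counts_area)))
})

test_that("terrain covariates respond to the depth profile", {
  cfg <- survey_config()
  nav <- generate_navigation(cfg, seed = 2)
  units <- partition_units(nav)
  cov <- unit_covariates(units, cfg, seed = 2)
  expect_true(all(c("slope", "tpi", "tri", "temperature", "salinity",
                    "longitude") %in% names(cov)))
  # the seamount dive (3) must show more relief than the flat dive (1)
  expect_gt(max(cov$slope[cov$dive_id == 3]), max(cov$slope[cov$dive_id == 1]))
  expect_gt(mean(cov$temperature[cov$region == "East"]),
            mean(cov$temperature[cov$region == "West"]))
})
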