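test_that("bathymetry reproduces configured feature relief", {
  flat <- flat_config()
  prof <- generate_bathymetry(flat, 1)
  expect_true(all(prof$depth_m == prof$depth_m[1]))

  cfg <- survey_config(
    dives = tibble::tibble(dive_id = 1L, region = "West", length_m = 3000,
                           acquisition_hz = 0.1, speed_mps = 0.7,
                           speed_sd = 0),
    features = tibble::tibble(dive_id = 1L, kind = "seamount",
                              centre_m = 1500, width_m = 600,
                              height_m = 200),
    regional_mean_abundance = NULL
  )
  prof <- generate_bathymetry(cfg, 1, at = seq(0, 3000, by = 1))
  expect_equal(max(prof$depth_m) - (-3400), 200, tolerance = 1e-6)

  canyon <- survey_config(
    dives = tibble::tibble(dive_id = 1L, region = "East", length_m = 2000,
                           acquisition_hz = 0.1, speed_mps = 0.7,
                           speed_sd = 0),
    features = tibble::tibble(dive_id = 1L, kind = "canyon",
                              centre_m = 1000, width_m = 500,
                              height_m = 20),
    regional_mean_abundance = NULL
  )
  prof <- generate_bathymetry(canyon, 1, at = seq(0, 2000, by = 0.5))
  drop <- max(prof$depth_m) - min(prof$depth_m)
  expect_equal(drop, 20, tolerance = 0.1)
  # flat floor: the deepest ~300 m of the notch sit at the full drop
  floor_pts <- prof$depth_m[abs(prof$along_track_m - 1000) < 150]
  expect_lt(diff(range(floor_pts)), 0.01)
  expect_error(generate_bathymetry(canyon, 99), "unknown dive_id")
  expect_error(
    survey_config(features = tibble::tibble(dive_id = 1L, kind = "volcano",
                                            centre_m = 1, width_m = 1,
                                            height_m = 1)),
    "unknown feature kind"
  )
})

test_that("navigation spacing, altitude jitter and determinism behave", {
  cfg <- flat_config(length_m = 1000, hz = 0.1, speed = 1, speed_sd = 0)
  nav <- generate_navigation(cfg, seed = 1)
  expect_equal(nrow(nav), 100)
  expect_equal(nav$along_track_m, seq(0, 990, by = 10))
  expect_true(all(nav$altitude_m == 3.5))
  expect_true(all(diff(nav$timestamp_s) == 10))

  nav2 <- generate_navigation(cfg, seed = 1)
  expect_identical(nav, nav2)
  nav3 <- generate_navigation(flat_config(speed_sd = 0.1), seed = 2)
  expect_false(identical(nav3$along_track_m, nav$along_track_m))

  expect_error(flat_config(speed = 0), "positive")
  expect_error(flat_config(hz = -1), "positive")
})

test_that("detection counts are Poisson draws from intensity x footprint", {
  empty <- flat_config(intensity = 0)
  nav <- generate_navigation(empty, seed = 1)
  det <- generate_detections(nav, empty, seed = 1)
  expect_equal(nrow(det), 0)

  # 100 images, altitude chosen so each footprint is 10 m^2 => 1000 m^2
  h <- sqrt(10 / (4 * tan(24 * pi / 180) * tan(16.5 * pi / 180)))
  cfg <- flat_config(intensity = 0.5, altitude = h, altitude_sd = 0)
  nav <- generate_navigation(cfg, seed = 1)
  area_total <- sum(footprint_area(nav$altitude_m, cfg$camera))
  expect_equal(area_total, 1000, tolerance = 1e-6)
  for (s in 1:3) {
    det <- generate_detections(nav, cfg, seed = s)
    expect_lt(abs(nrow(det) - 500), 4 * sqrt(500))
  }
  expect_true(all(det$confidence >= 0 & det$confidence <= 1))
  expect_true(all(det$x >= 0 & det$x + det$w <= cfg$image_size[2]))
  expect_true(all(det$y >= 0 & det$y + det$h <= cfg$image_size[1]))
})

test_that("per-image counts have Poisson mean-variance balance", {
  cfg <- flat_config(length_m = 5000, hz = 0.2, speed = 1,
                     intensity = 0.8, altitude_sd = 0)
  nav <- generate_navigation(cfg, seed = 4)
  expect_gte(nrow(nav), 1000)
  det <- generate_detections(nav, cfg, seed = 4)
  counts <- table(factor(det$image_id, levels = nav$image_id))
  expect_equal(unname(var(counts) / mean(counts)), 1, tolerance = 0.15)
})

test_that("ground truth surfaces, hotspot intervals and calibration agree", {
  cfg <- survey_config()
  gt <- survey_ground_truth(cfg)
  expect_true(all(gt$intensity$intensity >= 0))
  expect_equal(gt$regional_mean$mean_total_intensity[
    gt$regional_mean$region == "East"], 0.44, tolerance = 1e-6)
  expect_equal(gt$regional_mean$mean_total_intensity[
    gt$regional_mean$region == "West"], 0.03, tolerance = 1e-6)
  # planted hotspot intervals lie within their dive and are hotter than
  # their flanks
  lens <- setNames(cfg$dives$length_m, cfg$dives$dive_id)
  expect_true(all(gt$hotspots$start_m >= 0))
  expect_true(all(gt$hotspots$end_m <= lens[as.character(gt$hotspots$dive_id)]))
  tot <- gt$intensity |>
    dplyr::summarise(total = sum(intensity),
                     .by = c(dive_id, along_track_m))
  for (i in seq_len(nrow(gt$hotspots))) {
    hs <- gt$hotspots[i, ]
    dv <- tot[tot$dive_id == hs$dive_id, ]
    all_hs <- gt$hotspots[gt$hotspots$dive_id == hs$dive_id, ]
    near_any <- Reduce(`|`, lapply(seq_len(nrow(all_hs)), function(j) {
      dv$along_track_m >= all_hs$start_m[j] - 200 &
        dv$along_track_m <= all_hs$end_m[j] + 200
    }))
    inside <- dv$total[dv$along_track_m >= hs$start_m &
                         dv$along_track_m <= hs$end_m]
    background <- dv$total[!near_any]
    expect_gt(min(inside), max(background))
  }
})

test_that("generated images expose the configured degradations", {
  nav1 <- generate_navigation(flat_config(length_m = 30), seed = 1)[1, ]
  clean_cfg <- flat_config(length_m = 30)
  clean_cfg$vignette_strength <- 0
  clean_cfg$cast_strength <- 0
  clean_cfg$brightness_sd <- 0
  clean_cfg$noise_sd <- 0
  img <- generate_images(nav1, clean_cfg, seed = 9)
  tex <- substrate_texture(img$substrate[1], clean_cfg$image_size,
                           seed = benthoscan:::child_seed(9, 100001L))
  expect_equal(img$image[[1]], tex)

  vig_cfg <- clean_cfg
  vig_cfg$vignette_strength <- 0.6
  img <- generate_images(nav1, vig_cfg, seed = 9)[["image"]][[1]]
  corner <- mean(img[1:8, 1:8, ])
  centre <- mean(img[29:36, 29:36, ])
  expect_lt(corner / centre, 1)

  cast_cfg <- clean_cfg
  cast_cfg$cast_strength <- 0.5
  img <- generate_images(nav1, cast_cfg, seed = 9)[["image"]][[1]]
  expect_gt(mean(img[, , 2]), mean(img[, , 1]))
})

test_that("a fixed seed reproduces the survey bit for bit", {
  cfg <- flat_config(length_m = 300, speed_sd = 0.1, altitude_sd = 0.3,
                     intensity = 0.4)
  s1 <- simulate_survey(cfg, seed = 11, images = TRUE)
  s2 <- simulate_survey(cfg, seed = 11, images = TRUE)
  expect_identical(s1$navigation, s2$navigation)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$images$image, s2$images$image)
  s3 <- simulate_survey(cfg, seed = 12)
  expect_false(identical(s1$detections, s3$detections))
})
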