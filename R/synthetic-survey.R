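# --- internal bathymetry / intensity machinery -------------------------------

# normalised relief in [0,1] contributed by each feature of one dive
relief_at <- function(config, dive_id, x) {
  feats <- config$features[config$features$dive_id == dive_id, , drop = FALSE]
  r <- rep(0, length(x))
  if (nrow(feats) == 0) return(r)
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    if (f$kind %in% c("seamount", "hill")) {
      r <- r + exp(-0.5 * ((x - f$centre_m) / (f$width_m / 4))^2)
    } else { # canyon: flat-bottomed notch with steep smoothed walls
      s <- f$width_m / 50
      r <- r + (tanh((x - (f$centre_m - f$width_m / 2)) / s) -
                  tanh((x - (f$centre_m + f$width_m / 2)) / s)) / 2
    }
  }
  pmin(r, 1)
}

depth_at <- function(config, dive_id, x) {
  region <- config$dives$region[match(dive_id, config$dives$dive_id)]
  d <- rep(unname(config$base_depth_m[region]), length(x))
  feats <- config$features[config$features$dive_id == dive_id, , drop = FALSE]
  if (nrow(feats) == 0) return(d)
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    if (f$kind %in% c("seamount", "hill")) {
      d <- d + f$height_m * exp(-0.5 * ((x - f$centre_m) / (f$width_m / 4))^2)
    } else {
      s <- f$width_m / 50
      d <- d - f$height_m *
        (tanh((x - (f$centre_m - f$width_m / 2)) / s) -
           tanh((x - (f$centre_m + f$width_m / 2)) / s)) / 2
    }
  }
  d
}

# positions x taxa matrix of true intensity (individuals/m^2)
intensity_at <- function(config, dive_id, x) {
  region <- config$dives$region[match(dive_id, config$dives$dive_id)]
  base <- if (region == "East") config$taxa$east else config$taxa$west
  relief <- relief_at(config, dive_id, x)
  mult <- outer(relief, config$taxa$enhancement - 1) + 1
  sweep(mult, 2, base, `*`)
}

# --- exported generators ------------------------------------------------------

#' Along-track bathymetry profile for one dive
#'
#' Evaluates the dive's depth profile: the regional base depth plus Gaussian
#' bumps for seamounts/hills and a flat-bottomed notch with steep smoothed
#' walls for canyons. Deterministic (no randomness involved).
#'
#' @param config A [survey_config()].
#' @param dive_id Dive identifier present in `config$dives`.
#' @param at Along-track positions (m) at which to evaluate; default a 5 m
#'   grid over the dive length.
#' @return Tibble with `along_track_m` and `depth_m`.
#' @export
generate_bathymetry <- function(config, dive_id, at = NULL) {
  stopifnot(inherits(config, "survey_config"))
  if (!dive_id %in% config$dives$dive_id) {
    abort(paste0("unknown dive_id: ", dive_id))
  }
  if (is.null(at)) {
    len <- config$dives$length_m[match(dive_id, config$dives$dive_id)]
    at <- seq(0, len, by = 5)
  }
  tibble(along_track_m = at, depth_m = depth_at(config, dive_id, at))
}

#' Generate navigation records for all dives
#'
#' Produces one image record per camera trigger. Timestamps tick at each
#' dive's fixed acquisition frequency; the platform advances along a
#' straight geodesic with per-step speed jitter; camera altitude is the
#' configured mean plus truncated Gaussian jitter (floored at 0.1 m). The
#' number of images per dive is `floor(length_m / (speed_mps /
#' acquisition_hz))`, the expected count at the mean speed.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Tibble of image records: `image_id`, `dive_id`, `region`,
#'   `timestamp_s`, `lon_deg`, `lat_deg`, `depth_m`, `altitude_m`,
#'   `along_track_m`.
#' @export
generate_navigation <- function(config, seed = 1L) {
  stopifnot(inherits(config, "survey_config"))
  purrr::map_dfr(seq_len(nrow(config$dives)), function(i) {
    dv <- config$dives[i, ]
    set.seed(child_seed(seed, dv$dive_id))
    spacing <- dv$speed_mps / dv$acquisition_hz
    n <- floor(dv$length_m / spacing)
    dt <- 1 / dv$acquisition_hz
    steps <- pmax(rnorm(n - 1, dv$speed_mps, dv$speed_sd), 0.05) * dt
    along <- c(0, cumsum(steps))
    pos <- geosphere::destPoint(
      c(dv$start_lon, dv$start_lat), dv$heading_deg, along, r = 6371000
    )
    alt <- pmax(rnorm(n, config$altitude_mean, config$altitude_sd), 0.1)
    tibble(
      image_id = sprintf("d%02d_i%05d", dv$dive_id, seq_len(n)),
      dive_id = dv$dive_id,
      region = dv$region,
      timestamp_s = dv$dive_id * 1e5 + (seq_len(n) - 1) * dt,
      lon_deg = pos[, 1],
      lat_deg = pos[, 2],
      depth_m = depth_at(config, dv$dive_id, along),
      altitude_m = alt,
      along_track_m = along
    )
  })
}

#' Generate taxon detections from the true intensity surface
#'
#' For each image and taxon the detection count is Poisson with mean
#' `intensity(position) * footprint_area(altitude)`; each detection receives
#' a uniformly placed bounding box within image bounds and a confidence in
#' `[0.5, 1]`.
#'
#' @param navigation Output of [generate_navigation()].
#' @param config A [survey_config()].
#' @param seed Integer seed.
#' @return Tibble of detections: `image_id`, `taxon`, `x`, `y`, `w`, `h`
#'   (pixels, 0-based, origin top-left), `confidence`. May have zero rows.
#' @export
generate_detections <- function(navigation, config, seed = 1L) {
  stopifnot(inherits(config, "survey_config"))
  if (any(navigation$altitude_m <= 0)) abort("altitudes must be positive")
  set.seed(child_seed(seed, 7001L))
  H <- config$image_size[1]; W <- config$image_size[2]
  out <- purrr::map_dfr(split(navigation, navigation$dive_id), function(nav) {
    area <- footprint_area(nav$altitude_m, config$camera)
    lam <- intensity_at(config, nav$dive_id[1], nav$along_track_m) * area
    counts <- matrix(rpois(length(lam), lam), nrow = nrow(nav))
    idx <- which(counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(tibble())
    n_per <- counts[idx]
    tibble(
      image_id = rep(nav$image_id[idx[, 1]], n_per),
      taxon = rep(config$taxa$taxon[idx[, 2]], n_per)
    )
  })
  if (nrow(out) == 0) {
    return(tibble(image_id = character(), taxon = character(),
                  x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                  confidence = numeric()))
  }
  n <- nrow(out)
  w <- runif(n, 4, W / 4)
  h <- runif(n, 4, H / 4)
  out$x <- runif(n, 0, W - w)
  out$y <- runif(n, 0, H - h)
  out$w <- w
  out$h <- h
  out$confidence <- runif(n, 0.5, 1)
  out[order(out$image_id, out$taxon), ]
}

#' Ground truth of a synthetic survey
#'
#' Evaluates the per-taxon intensity surfaces on an along-track grid,
#' derives the planted hotspot intervals (where normalised topographic
#' relief exceeds 0.5) and the true regional mean total intensities
#' (track-averaged, enhancement included).
#'
#' @param config A [survey_config()].
#' @param grid_step Grid spacing in metres.
#' @return List with tibbles `intensity` (`dive_id`, `along_track_m`,
#'   `taxon`, `intensity`), `hotspots` (`dive_id`, `start_m`, `end_m`) and
#'   `regional_mean` (`region`, `mean_total_intensity`).
#' @export
survey_ground_truth <- function(config, grid_step = 10) {
  stopifnot(inherits(config, "survey_config"))
  grids <- purrr::map(seq_len(nrow(config$dives)), function(i) {
    dv <- config$dives[i, ]
    x <- seq(0, dv$length_m, by = grid_step)
    list(dive = dv, x = x,
         lam = intensity_at(config, dv$dive_id, x),
         relief = relief_at(config, dv$dive_id, x))
  })
  intensity <- purrr::map_dfr(grids, function(g) {
    tibble(
      dive_id = g$dive$dive_id,
      along_track_m = rep(g$x, ncol(g$lam)),
      taxon = rep(config$taxa$taxon, each = length(g$x)),
      intensity = as.vector(g$lam)
    )
  })
  hotspots <- purrr::map_dfr(grids, function(g) {
    hot <- g$relief > 0.5
    if (!any(hot)) return(tibble())
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    keep <- which(r$values)
    tibble(dive_id = g$dive$dive_id,
           start_m = g$x[starts[keep]], end_m = g$x[ends[keep]])
  })
  regional_mean <- purrr::map_dfr(grids, function(g) {
    tibble(region = g$dive$region, dive_id = g$dive$dive_id,
           n = length(g$x), total = mean(rowSums(g$lam)))
  }) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      mean_total_intensity = stats::weighted.mean(.data$total, .data$n),
      .groups = "drop"
    )
  list(intensity = intensity, hotspots = hotspots,
       regional_mean = regional_mean)
}

#' Procedural seafloor texture
#'
#' Generates one clean (undegraded) greyscale-to-RGB substrate texture of a
#' given class: `"smooth"` (low-contrast smoothed noise, foraminiferal
#' ooze-like), `"bioturbated"` (isotropic dark pits and bright mounds) or
#' `"ripples"` (oriented sinusoidal bedforms).
#'
#' @param class Texture class name.
#' @param size `c(H, W)` in pixels (each >= 32).
#' @param seed Integer seed.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
substrate_texture <- function(class = c("smooth", "bioturbated", "ripples"),
                              size = c(128L, 128L), seed = 1L) {
  class <- match.arg(class)
  if (any(size < 32)) abort("image size must be at least 32 x 32")
  set.seed(seed)
  H <- size[1]; W <- size[2]
  g <- matrix(0.5, H, W)
  if (class == "smooth") {
    coarse <- matrix(runif(64, -1, 1), 8, 8)
    gy <- seq(1, 8, length.out = H); gx <- seq(1, 8, length.out = W)
    # bilinear upscale of the coarse grid
    y0 <- pmin(floor(gy), 7); x0 <- pmin(floor(gx), 7)
    fy <- gy - y0; fx <- gx - x0
    up <- (1 - fy) %o% (1 - fx) * coarse[cbind(rep(y0, W), rep(x0, each = H))] +
      fy %o% (1 - fx) * coarse[cbind(rep(y0 + 1, W), rep(x0, each = H))] +
      (1 - fy) %o% fx * coarse[cbind(rep(y0, W), rep(x0 + 1, each = H))] +
      fy %o% fx * coarse[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
    g <- 0.45 + 0.05 * up
  } else if (class == "bioturbated") {
    n_spots <- 40
    cy <- runif(n_spots, 1, H); cx <- runif(n_spots, 1, W)
    rad <- runif(n_spots, 2, 6)
    amp <- sample(c(-0.25, 0.25), n_spots, replace = TRUE)
    yy <- row(g); xx <- col(g)
    for (s in seq_len(n_spots)) {
      g <- g + amp[s] * exp(-((yy - cy[s])^2 + (xx - cx[s])^2) / (2 * rad[s]^2))
    }
  } else {
    theta <- runif(1, 0, pi)
    lambda <- runif(1, 8, 16)
    phi <- runif(1, 0, 2 * pi)
    yy <- row(g); xx <- col(g)
    g <- 0.5 + 0.15 * sin(2 * pi * (xx * cos(theta) + yy * sin(theta)) /
                            lambda + phi)
  }
  g <- pmin(pmax(g, 0), 1)
  # sediment tint: slightly warm grey
  out <- array(0, c(H, W, 3))
  out[, , 1] <- g * 0.92
  out[, , 2] <- g * 0.90
  out[, , 3] <- g * 0.82
  out
}

# deterministic substrate class for an image given its track context;
# dive_id and x are parallel vectors
substrate_class_at <- function(config, dive_id, x) {
  region <- config$dives$region[match(dive_id, config$dives$dive_id)]
  relief <- numeric(length(x))
  for (dv in unique(dive_id)) {
    sel <- dive_id == dv
    relief[sel] <- relief_at(config, dv, x[sel])
  }
  dplyr::case_when(
    relief >= 0.3 ~ "ripples",
    region == "East" ~ "bioturbated",
    TRUE ~ "smooth"
  )
}

#' Generate degraded seafloor images for navigation records
#'
#' Each image is a procedural substrate texture degraded the way raw
#' underwater photographs are: multiplied by a radial vignette, given a
#' greenish colour cast, scaled by a per-image brightness factor and
#' perturbed by additive noise. The true substrate class of every image is
#' returned alongside.
#'
#' @param navigation Navigation tibble (or a subset of its rows).
#' @param config A [survey_config()].
#' @param seed Integer seed.
#' @return Tibble with `image_id`, `dive_id`, `substrate` and a list-column
#'   `image` of `H x W x 3` arrays in `[0, 1]`.
#' @export
generate_images <- function(navigation, config, seed = 1L) {
  stopifnot(inherits(config, "survey_config"))
  if (any(config$image_size < 32)) abort("image size must be at least 32 x 32")
  H <- config$image_size[1]; W <- config$image_size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rmax2 <- cy^2 + cx^2
  vmask <- 1 - config$vignette_strength *
    ((row(matrix(0, H, W)) - cy)^2 + (col(matrix(0, H, W)) - cx)^2) / rmax2
  cls <- substrate_class_at(config, navigation$dive_id, navigation$along_track_m)
  imgs <- purrr::map(seq_len(nrow(navigation)), function(i) {
    iseed <- child_seed(seed, 100000L + i)
    img <- substrate_texture(cls[i], c(H, W), seed = iseed)
    set.seed(child_seed(seed, 200000L + i))
    bright <- min(max(rnorm(1, 1, config$brightness_sd), 0.5), 1.5)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * vmask
    cast <- config$cast_strength
    img[, , 1] <- img[, , 1] * (1 - 0.30 * cast)
    img[, , 3] <- img[, , 3] * (1 - 0.20 * cast)
    img[, , 2] <- img[, , 2] + 0.08 * cast
    img <- img * bright
    if (config$noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, config$noise_sd), dim(img))
    }
    pmin(pmax(img, 0), 1)
  })
  tibble(image_id = navigation$image_id, dive_id = navigation$dive_id,
         substrate = cls, image = imgs)
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper chaining [generate_navigation()],
#' [generate_detections()] and [survey_ground_truth()] (and optionally
#' [generate_images()]) under one seed.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed.
#' @param images Generate images too? Off by default; image stages of the
#'   pipeline generate them batch-wise instead of holding the whole
#'   collection in memory.
#' @return List of class `benthic_survey` with elements `config`,
#'   `navigation`, `detections`, `ground_truth` (and `images` if requested).
#' @export
simulate_survey <- function(config = survey_config(), seed = 1L,
                            images = FALSE) {
  nav <- generate_navigation(config, seed)
  det <- generate_detections(nav, config, seed)
  out <- list(config = config, navigation = nav, detections = det,
              ground_truth = survey_ground_truth(config))
  if (images) out$images <- generate_images(nav, config, seed)
  structure(out, class = "benthic_survey")
}

#' @export
print.benthic_survey <- function(x, ...) {
  cat("<benthic_survey>\n")
  cat("  images:", nrow(x$navigation), " detections:", nrow(x$detections), "\n")
  cat("  dives:", length(unique(x$navigation$dive_id)), "\n")
  invisible(x)
}
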