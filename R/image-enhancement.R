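#' Configuration for the image visibility-improvement workflow
#'
#' @param batch_size Images per z-score batch (>= 2, default 32).
#' @param tile_grid `c(rows, cols)` tile layout for local histogram
#'   equalisation (each >= 2, default 8 x 8).
#' @param clip_fraction Contrast-limiting clip limit as a fraction of tile
#'   pixels per histogram bin, in (0, 1] (default 0.04).
#' @param bins Histogram bins for equalisation.
#' @param reference_image_id Id of the manually chosen histogram-matching
#'   reference image; required by [enhance_collection()].
#' @param epsilon Variance floor for the z-score denominator.
#' @return An `enhancement_config` list.
#' @export
enhancement_config <- function(batch_size = 32, tile_grid = c(8, 8),
                               clip_fraction = 0.04, bins = 256,
                               reference_image_id = NULL,
                               epsilon = 1e-6) {
  if (batch_size < 2) abort("batch_size must be at least 2")
  if (any(tile_grid < 2)) abort("tile_grid must be at least 2 x 2")
  if (clip_fraction <= 0 || clip_fraction > 1) {
    abort("clip_fraction must be in (0, 1]")
  }
  structure(list(batch_size = as.integer(batch_size),
                 tile_grid = as.integer(tile_grid),
                 clip_fraction = clip_fraction, bins = as.integer(bins),
                 reference_image_id = reference_image_id, epsilon = epsilon),
            class = "enhancement_config")
}

#' Batch z-score normalisation of chronologically sorted images
#'
#' Computes, per channel, the pixel-wise mean and standard deviation
#' across the batch and standardises every image against them:
#' `z = (x - mean) / (sd + epsilon)`, affinely rescaled so that
#' `z` in `[-3, 3]` maps to `[0, 1]` (clipped). Static spatial patterns
#' shared by the whole batch — the vignette's radial intensity drop-off,
#' a common haze level — cancel out of `z`.
#'
#' @param images List of >= 2 numeric arrays with identical dimensions.
#' @param epsilon Variance floor.
#' @return List of arrays in `[0, 1]`, same order.
#' @export
batch_zscore <- function(images, epsilon = 1e-6) {
  if (length(images) < 2) abort("batch z-scoring needs at least 2 images")
  dims <- dim(images[[1]])
  if (!all(vapply(images, function(x) identical(dim(x), dims), logical(1)))) {
    abort("all images in a batch must have identical dimensions")
  }
  stack <- array(unlist(images, use.names = FALSE), c(dims, length(images)))
  mu <- apply(stack, seq_along(dims), mean)
  sg <- apply(stack, seq_along(dims), sd)
  lapply(images, function(x) {
    z <- (x - mu) / (sg + epsilon)
    pmin(pmax((z + 3) / 6, 0), 1)
  })
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Equalises intensity histograms within local tiles (with bilinear
#' interpolation between tile mappings) under a clip limit, raising local
#' contrast without over-amplifying noise. Backed by the CLAHE
#' implementation in \pkg{EBImage}; images whose dimensions are not
#' multiples of the tile grid are reflect-padded and cropped back.
#'
#' @param image 2-D matrix or `H x W x C` array with values in `[0, 1]`.
#' @param config An [enhancement_config()].
#' @return Array of the same shape, values in `[0, 1]`.
#' @export
adaptive_hist_eq <- function(image, config = enhancement_config()) {
  d <- dim(image)
  nx <- config$tile_grid[2]; ny <- config$tile_grid[1]
  if (d[1] < ny || d[2] < nx) {
    abort("tile grid larger than image")
  }
  limit <- max(1, config$clip_fraction * config$bins)
  eq1 <- function(m) {
    if (diff(range(m)) < 1e-8) return(m)  # nothing to equalise
    padr <- (ny - nrow(m) %% ny) %% ny
    padc <- (nx - ncol(m) %% nx) %% nx
    mp <- m
    if (padr > 0) mp <- rbind(mp, mp[nrow(mp):(nrow(mp) - padr + 1), ,
                                     drop = FALSE])
    if (padc > 0) mp <- cbind(mp, mp[, ncol(mp):(ncol(mp) - padc + 1),
                                     drop = FALSE])
    out <- EBImage::clahe(mp, nx = nx, ny = ny, bins = config$bins,
                          limit = limit)
    pmin(pmax(out[seq_len(nrow(m)), seq_len(ncol(m))], 0), 1)
  }
  if (length(d) == 2) return(eq1(image))
  out <- image
  for (ch in seq_len(d[3])) out[, , ch] <- eq1(image[, , ch])
  out
}

#' Histogram matching against a reference image
#'
#' Monotone quantile mapping, per channel: each pixel's rank in its own
#' channel is mapped to the reference value at the same quantile, so the
#' output's empirical distribution matches the reference's. Matching an
#' image to itself is the identity (up to rank ties).
#'
#' @param image Matrix or `H x W x C` array.
#' @param reference Image with the same number of channels (sizes may
#'   differ); must be non-empty.
#' @return Matched image, same shape as `image`.
#' @export
histogram_match <- function(image, reference) {
  if (length(reference) == 0) abort("reference image is empty")
  di <- dim(image); dr <- dim(reference)
  ci <- if (length(di) == 3) di[3] else 1L
  cr <- if (length(dr) == 3) dr[3] else 1L
  if (ci != cr) abort("image and reference must have equal channel counts")
  match1 <- function(x, ref) {
    rs <- sort(as.vector(ref))
    r <- rank(as.vector(x), ties.method = "average")
    idx <- pmax(1, ceiling(r / length(x) * length(rs)))
    matrix(rs[idx], nrow(x), ncol(x))
  }
  if (ci == 1) {
    m <- match1(as.matrix(image), as.matrix(reference))
    if (length(di) == 3) dim(m) <- di
    return(m)
  }
  out <- image
  for (ch in seq_len(ci)) out[, , ch] <- match1(image[, , ch],
                                                reference[, , ch])
  out
}

#' Run the full three-step visibility-improvement workflow
#'
#' Groups chronologically sorted images into consecutive batches of
#' `batch_size` (a trailing batch of one image is merged into the previous
#' batch) and applies, in order: batch z-score normalisation, per-image
#' contrast-limited adaptive histogram equalisation, and histogram
#' matching against the configured reference image (the reference is taken
#' after its own batch's first two steps).
#'
#' @param navigation Navigation tibble sorted (or sortable) by
#'   `timestamp_s`; rows align with `images` by `image_id`.
#' @param images Tibble with `image_id` and list-column `image`, or a
#'   named list of arrays.
#' @param config An [enhancement_config()] with `reference_image_id` set.
#' @return Tibble `image_id`, `image` (enhanced arrays, original order).
#' @export
enhance_collection <- function(navigation, images,
                               config = enhancement_config()) {
  if (is.data.frame(images)) {
    imgs <- setNames(images$image, images$image_id)
  } else {
    imgs <- images
  }
  if (length(imgs) < 2) abort("need at least two images")
  nav <- dplyr::arrange(navigation, .data$timestamp_s)
  ids <- nav$image_id[nav$image_id %in% names(imgs)]
  if (length(ids) < 2) abort("fewer than two images match navigation")
  ref_id <- config$reference_image_id
  if (is.null(ref_id)) abort("config$reference_image_id must be set")
  if (!ref_id %in% ids) abort("reference image not in the collection")
  batches <- batch_indices(length(ids), config$batch_size)
  step2 <- vector("list", length(ids))
  names(step2) <- ids
  for (b in batches) {
    zs <- batch_zscore(imgs[ids[b]], config$epsilon)
    step2[ids[b]] <- lapply(zs, adaptive_hist_eq, config = config)
  }
  ref <- step2[[ref_id]]
  out <- lapply(step2, histogram_match, reference = ref)
  tibble(image_id = ids, image = unname(out))
}

# consecutive batch index sets; a trailing singleton merges into the
# previous batch
batch_indices <- function(n, batch_size) {
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) s:min(s + batch_size - 1, n))
  last <- length(batches)
  if (last > 1 && length(batches[[last]]) < 2) {
    batches[[last - 1]] <- c(batches[[last - 1]], batches[[last]])
    batches[[last]] <- NULL
  }
  batches
}
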