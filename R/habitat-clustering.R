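# grey-level co-occurrence summaries, averaged over the four unit-offset
# directions (0, 45, 90, 135 degrees) with symmetric pairing, so the
# summaries are invariant to 90-degree image rotation
glcm_summaries <- function(gray, levels = 16L) {
  q <- pmin(floor(gray * levels), levels - 1L)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  acc <- c(contrast = 0, energy = 0, homogeneity = 0, entropy = 0)
  H <- nrow(q); W <- ncol(q)
  for (off in offsets) {
    r0 <- max(1, 1 - off[1]):min(H, H - off[1])
    c0 <- max(1, 1 - off[2]):min(W, W - off[2])
    a <- q[r0, c0]
    b <- q[r0 + off[1], c0 + off[2]]
    tab <- table(factor(a, levels = 0:(levels - 1)),
                 factor(b, levels = 0:(levels - 1)))
    p <- (tab + t(tab)) / (2 * sum(tab))
    ij <- outer(0:(levels - 1), 0:(levels - 1), `-`)
    acc["contrast"] <- acc["contrast"] + sum(p * ij^2)
    acc["energy"] <- acc["energy"] + sum(p^2)
    acc["homogeneity"] <- acc["homogeneity"] + sum(p / (1 + abs(ij)))
    pp <- p[p > 0]
    acc["entropy"] <- acc["entropy"] - sum(pp * log(pp))
  }
  acc / length(offsets)
}

# radial spectral-energy summaries of the centred power spectrum; invariant
# to 90-degree rotation. Periodic textures (ripples) concentrate energy in
# few coefficients, smooth sediment in low radial frequencies.
spectral_summaries <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  f <- Mod(stats::fft(gray - mean(gray)))^2
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1))
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1))
  rad <- sqrt(outer(fy^2, fx^2, `+`))
  f[1, 1] <- 0
  tot <- sum(f)
  if (tot < 1e-12) {
    return(c(spec_low = 0, spec_mid = 0, spec_peak = 0, spec_top8 = 0))
  }
  c(spec_low = sum(f[rad <= 4]) / tot,
    spec_mid = sum(f[rad > 4 & rad <= 16]) / tot,
    spec_peak = max(f) / tot,
    spec_top8 = sum(sort(f, decreasing = TRUE)[1:8]) / tot)
}

# mean-pool a matrix onto a coarse grid
block_mean <- function(m, grid = 8L) {
  ry <- ceiling(seq_len(nrow(m)) / nrow(m) * grid)
  rx <- ceiling(seq_len(ncol(m)) / ncol(m) * grid)
  tapply(m, list(ry[row(m)], rx[col(m)]), mean)
}

#' Encode one image as a fixed-length feature vector
#'
#' The default `"summary"` extractor is deterministic and hand-crafted:
#' per-channel intensity statistics (mean, sd and the 0.1/0.25/0.5/0.75/0.9
#' quantiles), grey-level co-occurrence texture summaries (contrast,
#' energy, homogeneity, entropy; rotation-invariant by direction
#' averaging), radial spectral-energy summaries (low/mid-frequency
#' fractions and peak concentration, which tell periodic bedforms from
#' isotropic bioturbation), and an 8 x 8 mean-pooled intensity grid. Deep
#' (CNN) embeddings can be plugged in behind the same interface by
#' registering another extractor name.
#'
#' @param image Matrix or `H x W x C` array, values in `[0, 1]`.
#' @param extractor Extractor name; only `"summary"` is built in.
#' @return Named numeric vector (same length for every image).
#' @export
extract_features <- function(image, extractor = "summary") {
  if (!identical(extractor, "summary")) {
    abort(paste0("unknown extractor: ", extractor))
  }
  d <- dim(image)
  chans <- if (length(d) == 3) {
    lapply(seq_len(d[3]), function(ch) image[, , ch])
  } else {
    list(image)
  }
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  stats <- unlist(lapply(seq_along(chans), function(i) {
    x <- chans[[i]]
    setNames(c(mean(x), sd(x), quantile(x, probs, names = FALSE)),
             paste0("ch", i, "_", c("mean", "sd", paste0("q", probs * 100))))
  }))
  gray <- Reduce(`+`, chans) / length(chans)
  tex <- glcm_summaries(gray)
  names(tex) <- paste0("glcm_", names(tex))
  spec <- spectral_summaries(gray)
  grid <- as.vector(block_mean(gray, 8L))
  names(grid) <- paste0("grid", seq_along(grid))
  c(stats, tex, spec, grid)
}

#' Feature matrix for an image collection
#'
#' @param images Tibble with `image_id` and list-column `image`, or a
#'   named list of arrays.
#' @param extractor Passed to [extract_features()].
#' @return Numeric matrix, one row per image, rownames = image ids.
#' @export
extract_feature_matrix <- function(images, extractor = "summary") {
  if (is.data.frame(images)) {
    imgs <- setNames(images$image, images$image_id)
  } else {
    imgs <- images
  }
  m <- t(vapply(imgs, extract_features, extract_features(imgs[[1]]),
                extractor = extractor))
  rownames(m) <- names(imgs)
  m
}

# standardise feature columns (constant columns become 0), then weight
# the feature blocks — channel stats, co-occurrence texture, spectral,
# intensity grid — so each block contributes equally to squared distance;
# otherwise the 64 grid cells drown the handful of texture summaries
scale_features <- function(m) {
  mu <- colMeans(m)
  sg <- apply(m, 2, sd)
  sg[sg == 0] <- 1
  z <- sweep(sweep(m, 2, mu), 2, sg, `/`)
  nm <- colnames(m) %||% rep("", ncol(m))
  block <- dplyr::case_when(
    grepl("^glcm", nm) ~ "glcm",
    grepl("^spec", nm) ~ "spec",
    grepl("^grid", nm) ~ "grid",
    TRUE ~ "stats"
  )
  for (b in unique(block)) {
    z[, block == b] <- z[, block == b] / sqrt(sum(block == b))
  }
  z
}

# k-means that tolerates k equal to the number of distinct points (each
# distinct point becomes its own centre); returns NULL when k exceeds the
# number of distinct rows
kmeans_safe <- function(m, k, nstart = 10) {
  ux <- unique(m)
  if (nrow(ux) < k) return(NULL)
  if (nrow(ux) == k) {
    key <- apply(m, 1, paste, collapse = "\r")
    ukey <- apply(ux, 1, paste, collapse = "\r")
    cl <- match(key, ukey)
    wss <- sum((m - ux[cl, , drop = FALSE])^2)
    return(list(cluster = cl, centers = ux, tot.withinss = wss))
  }
  suppressWarnings(kmeans(m, centers = k, nstart = nstart, iter.max = 100))
}

#' Choose the number of habitat classes
#'
#' Runs k-means over `k_range` and returns the k maximising the mean
#' silhouette width. The raw within-cluster sum of squares is retained in
#' the selection curve so an elbow criterion can be applied instead.
#'
#' @param features Numeric feature matrix (rows = images).
#' @param k_range Candidate cluster counts (default 2:20, clipped to
#'   `n - 1`).
#' @param seed Integer seed.
#' @param scale Standardise feature columns first?
#' @return Integer k, with the selection curve (`k`, `silhouette`, `wcss`)
#'   in `attr(, "curve")`.
#' @export
select_k <- function(features, k_range = 2:20, seed = 1L, scale = TRUE) {
  n <- nrow(features)
  if (n < 3) abort("need at least three images to select k")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("k_range is empty after clipping to n - 1")
  m <- if (scale) scale_features(features) else features
  dm <- dist(m)
  curve <- purrr::map_dfr(k_range, function(k) {
    set.seed(child_seed(seed, 900L + k))
    km <- kmeans_safe(m, k, nstart = 5)
    if (is.null(km)) return(tibble())  # fewer distinct points than k
    sil <- cluster::silhouette(km$cluster, dm)
    tibble(k = k, silhouette = mean(sil[, "sil_width"]),
           wcss = km$tot.withinss)
  })
  if (nrow(curve) == 0) abort("no candidate k is feasible for these data")
  best <- curve$k[which.max(curve$silhouette)]
  attr(best, "curve") <- curve
  best
}

#' Cluster images into habitat classes with k-means
#'
#' Multiple-restart k-means on (optionally standardised) feature vectors.
#'
#' @param features Numeric feature matrix with image ids as rownames.
#' @param k Number of classes (2 <= k <= n).
#' @param seed Integer seed.
#' @param nstart Restarts.
#' @param scale Standardise feature columns first?
#' @return A `habitat_clusters` object: `labels` tibble (`image_id`,
#'   `cluster`), `centroids`, `objective` (within-cluster sum of squares),
#'   `k`.
#' @export
cluster_habitats <- function(features, k, seed = 1L, nstart = 10,
                             scale = TRUE) {
  n <- nrow(features)
  if (k > n) abort("k cannot exceed the number of images")
  if (k < 1) abort("k must be positive")
  m <- if (scale) scale_features(features) else features
  set.seed(child_seed(seed, 1300L))
  km <- kmeans_safe(m, k, nstart = nstart)
  if (is.null(km)) abort("k exceeds the number of distinct feature vectors")
  ids <- rownames(features) %||% as.character(seq_len(n))
  structure(list(
    labels = tibble(image_id = ids, cluster = unname(km$cluster)),
    centroids = km$centers,
    objective = km$tot.withinss,
    k = k,
    features = m
  ), class = "habitat_clusters")
}

#' @export
print.habitat_clusters <- function(x, ...) {
  cat("<habitat_clusters> k =", x$k, " objective =",
      signif(x$objective, 5), "\n")
  print(table(x$labels$cluster))
  invisible(x)
}

#' @export
tidy.habitat_clusters <- function(x, ...) x$labels

#' @export
glance.habitat_clusters <- function(x, ...) {
  tibble(k = x$k, objective = x$objective, n = nrow(x$labels))
}

#' Project images onto principal axes of feature space
#'
#' Centred PCA of the feature matrix; component variances are
#' non-increasing.
#'
#' @param features Numeric feature matrix.
#' @param n_components Number of axes (default 2).
#' @return Tibble `image_id`, `PC1`, `PC2`, ... with explained variance
#'   proportions in `attr(, "explained")`.
#' @export
project_pca <- function(features, n_components = 2) {
  if (n_components > ncol(features)) {
    abort("n_components exceeds feature dimension")
  }
  if (all(apply(features, 2, var) == 0)) {
    abort("feature matrix has zero variance")
  }
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  out <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  out <- dplyr::bind_cols(
    tibble(image_id = rownames(features) %||%
             as.character(seq_len(nrow(features)))),
    out
  )
  attr(out, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  out
}

#' Exemplar images per habitat cluster
#'
#' Returns up to `n_per_cluster` image ids per cluster, nearest to the
#' cluster centroid first (ties broken by id), for manual inspection and
#' semantic labelling of clusters.
#'
#' @param model A [cluster_habitats()] result.
#' @param n_per_cluster Maximum exemplars per cluster (>= 1).
#' @param seed Unused; kept for interface stability.
#' @return Tibble `cluster`, `image_id`, `rank`.
#' @export
sample_exemplars <- function(model, n_per_cluster = 5, seed = 1L) {
  if (n_per_cluster < 1) abort("n_per_cluster must be at least 1")
  purrr::map_dfr(sort(unique(model$labels$cluster)), function(cl) {
    members <- which(model$labels$cluster == cl)
    dd <- sqrt(rowSums(
      (model$features[members, , drop = FALSE] -
         matrix(model$centroids[cl, ], length(members),
                ncol(model$centroids), byrow = TRUE))^2
    ))
    o <- members[order(dd, model$labels$image_id[members])]
    take <- head(o, n_per_cluster)
    tibble(cluster = cl, image_id = model$labels$image_id[take],
           rank = seq_along(take))
  })
}
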