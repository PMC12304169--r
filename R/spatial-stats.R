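#' k-nearest-neighbour spatial weights between sampling units
#'
#' Connects every unit to its `k` geographically nearest units (haversine
#' distance between centroids, sphere radius 6371 km). Weights are
#' row-standardised (each row sums to 1); distance ties are broken by
#' ascending unit id; a unit is never its own neighbour. By default
#' neighbours are restricted to the same dive (transects lie far apart);
#' set `within_dive = FALSE` to allow cross-dive links.
#'
#' @param units Tibble with `unit_id`, `centroid_lon`, `centroid_lat` and
#'   (if `within_dive`) `dive_id`.
#' @param k Number of neighbours (default 6).
#' @param within_dive Restrict neighbours to the same dive?
#' @return A `spatial_weights` object: list with `ids`, integer neighbour
#'   matrix `nb` (n x k) and weight matrix `w` (n x k).
#' @export
knn_graph <- function(units, k = 6, within_dive = TRUE) {
  n <- nrow(units)
  ids <- units$unit_id
  ord <- order(ids)
  groups <- if (within_dive && "dive_id" %in% names(units)) {
    units$dive_id
  } else {
    rep(1L, n)
  }
  nb <- matrix(NA_integer_, n, k)
  for (g in unique(groups)) {
    gi <- which(groups == g)
    if (length(gi) <= k) {
      abort(paste0("need more than k = ", k, " units per neighbourhood ",
                   "group (group ", g, " has ", length(gi), ")"))
    }
    p <- cbind(units$centroid_lon[gi], units$centroid_lat[gi])
    for (a in seq_along(gi)) {
      d <- geosphere::distHaversine(p[a, ], p, r = 6371000)
      d[a] <- Inf
      # deterministic tie-break: order by distance, then ascending unit id
      o <- gi[order(d, match(ids[gi], sort(ids[gi])))]
      nb[gi[a], ] <- o[seq_len(k)]
    }
  }
  structure(list(ids = ids, nb = nb,
                 w = matrix(1 / k, n, k)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> n =", length(x$ids), " k =", ncol(x$nb), "\n")
  invisible(x)
}

# spatial lag given weights object and a numeric vector
spatial_lag <- function(values, weights) {
  vapply(seq_along(values), function(i) {
    sum(weights$w[i, ] * values[weights$nb[i, ]])
  }, numeric(1))
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the total weight. Expected value under spatial
#' randomness is `-1 / (n - 1)`.
#'
#' @param values Numeric vector, one per unit, non-constant.
#' @param weights A [knn_graph()] result.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, weights) {
  if (!all(is.finite(values))) abort("values must be finite")
  if (var(values) == 0) abort("values have zero variance")
  n <- length(values)
  stopifnot(n == length(weights$ids))
  z <- values - mean(values)
  s0 <- sum(weights$w)
  lag_num <- vapply(seq_len(n), function(i) {
    sum(weights$w[i, ] * z[weights$nb[i, ]])
  }, numeric(1))
  (n / s0) * sum(z * lag_num) / sum(z^2)
}

#' Moran's I across neighbourhood sizes
#'
#' Recomputes global Moran's I for k = 1..`k_max` neighbours and reports
#' the step change `delta_i = I(k) - I(k-1)`. The suggested neighbourhood
#' size is the smallest k whose step change (and the next one) stays below
#' `threshold` in absolute value; if the curve never stabilises the
#' default of 6 neighbours is suggested.
#'
#' @param values Numeric vector per unit.
#' @param units Units tibble (centroids, dive ids).
#' @param k_max Largest neighbourhood size to scan.
#' @param threshold Stability threshold on `|delta_i|` (default 0.02).
#' @param within_dive Passed to [knn_graph()].
#' @return Tibble `(k, i, delta_i)` with the suggestion in
#'   `attr(, "suggested_k")`.
#' @export
neighbourhood_curve <- function(values, units, k_max = 10, threshold = 0.02,
                                within_dive = TRUE) {
  res <- purrr::map_dfr(seq_len(k_max), function(k) {
    w <- knn_graph(units, k = k, within_dive = within_dive)
    tibble(k = k, i = morans_i(values, w))
  })
  res$delta_i <- c(NA_real_, diff(res$i))
  suggested <- 6L
  ok <- abs(res$delta_i) < threshold
  for (k in 2:(k_max - 1)) {
    if (isTRUE(ok[k]) && isTRUE(ok[k + 1])) { suggested <- res$k[k]; break }
  }
  attr(res, "suggested_k") <- suggested
  res
}

#' Local Moran (LISA) statistics with conditional permutation test
#'
#' For standardised values `z`, the local Moran of unit i is
#' `I_i = z_i * sum_j w_ij z_j`. Significance uses conditional permutation:
#' holding unit i's value fixed, the remaining values are permuted among
#' the other units `n_perm` times and the pseudo p-value is
#' `(#{|I_perm| >= |I_obs|} + 1) / (n_perm + 1)` (two-sided). Quadrants of
#' the Moran scatterplot follow the signs of `(z_i, lag_i)`: HH, LL, HL,
#' LH. Units are classified hotspot (HH), coldspot (LL) or outlier (HL/LH)
#' when significant at `alpha`.
#'
#' @param values Numeric vector per unit, non-constant.
#' @param weights A [knn_graph()] result.
#' @param n_perm Number of conditional permutations (>= 99).
#' @param seed Integer seed.
#' @param alpha Significance level for classification.
#' @return Tibble of class `lisa_result`: `unit_id`, `value`, `z`, `lag`,
#'   `i_local`, `quadrant`, `p_pseudo`, `class`.
#' @export
local_moran <- function(values, weights, n_perm = 999, seed = 1L,
                        alpha = 0.05) {
  if (!all(is.finite(values))) abort("values must be finite")
  if (var(values) == 0) abort("values have zero variance")
  if (n_perm < 99) abort("n_perm must be at least 99")
  n <- length(values)
  stopifnot(n == length(weights$ids))
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  zs <- z / sqrt(m2)
  lag <- spatial_lag(zs, weights)
  i_local <- zs * lag
  set.seed(child_seed(seed, 4242L))
  k <- ncol(weights$nb)
  p_pseudo <- numeric(n)
  for (i in seq_len(n)) {
    others <- zs[-i]
    draws <- matrix(0, n_perm, k)
    for (p in seq_len(n_perm)) {
      draws[p, ] <- others[sample.int(n - 1, k)]
    }
    lag_perm <- draws %*% weights$w[i, ]
    i_perm <- zs[i] * lag_perm
    p_pseudo[i] <- (sum(abs(i_perm) >= abs(i_local[i])) + 1) / (n_perm + 1)
  }
  quadrant <- dplyr::case_when(
    zs >= 0 & lag >= 0 ~ "HH",
    zs < 0 & lag < 0 ~ "LL",
    zs >= 0 & lag < 0 ~ "HL",
    TRUE ~ "LH"
  )
  out <- tibble(unit_id = weights$ids, value = values, z = zs, lag = lag,
                i_local = i_local, quadrant = quadrant, p_pseudo = p_pseudo)
  out$class <- classify_lisa(out, alpha)
  attr(out, "alpha") <- alpha
  class(out) <- c("lisa_result", class(out))
  out
}

#' Classify LISA results into hotspots, coldspots and outliers
#'
#' @param lisa Tibble with `quadrant` and `p_pseudo` columns.
#' @param alpha Significance level.
#' @return Character vector: `"hotspot"`, `"coldspot"`, `"outlier"` or
#'   `"not-significant"`.
#' @export
classify_lisa <- function(lisa, alpha = 0.05) {
  dplyr::case_when(
    lisa$p_pseudo > alpha ~ "not-significant",
    lisa$quadrant == "HH" ~ "hotspot",
    lisa$quadrant == "LL" ~ "coldspot",
    TRUE ~ "outlier"
  )
}

#' Quantile bins for choropleth display
#'
#' Bins values into `n_bins` classes at the `i/n_bins` sample quantiles.
#' A value equal to a bin edge is assigned to the lower bin. When there
#' are fewer distinct edges than requested the number of bins is reduced
#' with a warning.
#'
#' @param values Finite numeric vector.
#' @param n_bins Number of classes (default 8).
#' @return Integer vector of bin indices in `[0, n_bins)`, with the bin
#'   edges in `attr(, "edges")`.
#' @export
quantile_bins <- function(values, n_bins = 8) {
  if (!all(is.finite(values))) abort("values must be finite")
  edges <- quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                    names = FALSE, type = 7)
  ue <- unique(edges)
  if (length(ue) < length(edges)) {
    warn(paste0("only ", length(ue) + 1, " distinct bins available; ",
                "reducing from ", n_bins))
    edges <- ue
  }
  # count of edges strictly below the value: ties go to the lower bin
  bins <- vapply(values, function(v) sum(edges < v), integer(1))
  attr(bins, "edges") <- edges
  bins
}

#' @export
tidy.lisa_result <- function(x, ...) {
  as_tibble(unclass(x)[names(x) != "alpha"])
}

#' @export
glance.lisa_result <- function(x, ...) {
  tibble(n = nrow(x),
         n_hotspot = sum(x$class == "hotspot"),
         n_coldspot = sum(x$class == "coldspot"),
         n_outlier = sum(x$class == "outlier"),
         alpha = attr(x, "alpha"))
}

#' Moran scatterplot of LISA results
#'
#' Standardised value against spatial lag, coloured by class; the slope of
#' the dashed reference line is the global Moran's I.
#'
#' @param object A [local_moran()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lisa_result <- function(object, ...) {
  gi <- mean(object$i_local)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$z, y = .data$lag,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = gi, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      hotspot = "#d73027", coldspot = "#4575b4",
      outlier = "#fdae61", `not-significant` = "grey60")) +
    ggplot2::labs(x = "standardised abundance z",
                  y = "spatial lag of z", colour = NULL,
                  title = "Moran scatterplot") +
    ggplot2::theme_minimal()
}
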