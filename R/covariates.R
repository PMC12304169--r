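#' Per-unit environmental covariates
#'
#' Derives bathymetric covariates from the unit depth sequence of each
#' dive by centred finite differences over a 3-unit window: `slope`
#' (degrees), topographic position index `tpi` (depth minus neighbourhood
#' mean) and terrain ruggedness index `tri` (mean absolute depth
#' difference to the neighbourhood). When a survey configuration is given,
#' regional water-mass properties are attached as well: temperature
#' (East 2.85 +/- 0.12 C, West 2.50 +/- 0.08 C) and salinity
#' (East 34.90, West 34.82, +/- 0.01). `longitude` duplicates the unit
#' centroid longitude as an explicit driver variable.
#'
#' @param units Units tibble with `dive_id`, `depth_m`, `centroid_lon`
#'   (and `region` when `config` is supplied).
#' @param config Optional [survey_config()] enabling the water-mass
#'   covariates.
#' @param seed Integer seed for the water-mass jitter.
#' @return The input with covariate columns appended.
#' @export
unit_covariates <- function(units, config = NULL, seed = 1L) {
  out <- units |>
    dplyr::group_by(.data$dive_id) |>
    dplyr::group_modify(function(df, key) {
      z <- df$depth_m
      x <- (df$start_m + df$end_m) / 2
      n <- length(z)
      if (n >= 3) {
        i <- 2:(n - 1)
        grad <- rep(NA_real_, n)
        grad[i] <- (z[i + 1] - z[i - 1]) / (x[i + 1] - x[i - 1])
        grad[1] <- (z[2] - z[1]) / (x[2] - x[1])
        grad[n] <- (z[n] - z[n - 1]) / (x[n] - x[n - 1])
        nb_mean <- rep(NA_real_, n); nb_rug <- rep(NA_real_, n)
        for (j in seq_len(n)) {
          nb <- setdiff(max(1, j - 1):min(n, j + 1), j)
          nb_mean[j] <- mean(z[nb])
          nb_rug[j] <- mean(abs(z[nb] - z[j]))
        }
        df$slope <- atan(abs(grad)) * 180 / pi
        df$tpi <- z - nb_mean
        df$tri <- nb_rug
      } else {
        df$slope <- 0; df$tpi <- 0; df$tri <- 0
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("unit_id")
  out$longitude <- out$centroid_lon
  if (!is.null(config)) {
    set.seed(child_seed(seed, 3100L))
    east <- out$region == "East"
    out$temperature <- ifelse(east, 2.85, 2.50) +
      rnorm(nrow(out), 0, ifelse(east, 0.12, 0.08))
    out$salinity <- ifelse(east, 34.90, 34.82) + rnorm(nrow(out), 0, 0.01)
  }
  for (a in c("image_unit")) attr(out, a) <- attr(units, a)
  if (inherits(units, "abundance_tbl")) {
    attr(out, "taxa") <- attr(units, "taxa")
    attr(out, "counts") <- attr(units, "counts")
    class(out) <- c("abundance_tbl", class(out))
  }
  out
}
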