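#' Double-root (fourth-root) transformation of abundances
#'
#' The severe variance-stabilising transform used before computing
#' Bray-Curtis dissimilarities: a square root applied twice, i.e. the
#' fourth root. A single square root is available via `transform`.
#'
#' @param x Non-negative numeric matrix (units x taxa) or `abundance_tbl`.
#' @param transform `"fourth-root"` (default) or `"sqrt"`.
#' @return Transformed numeric matrix.
#' @export
double_root <- function(x, transform = c("fourth-root", "sqrt")) {
  transform <- match.arg(transform)
  if (inherits(x, "abundance_tbl")) x <- abundance_values(x)
  x <- as.matrix(x)
  if (any(x < 0)) abort("abundances must be non-negative")
  if (transform == "fourth-root") x^0.25 else sqrt(x)
}

#' Bray-Curtis dissimilarity between sampling units
#'
#' `d(x, y) = sum|x_j - y_j| / sum(x_j + y_j)`, in `[0, 1]`; 0 for
#' identical rows and 1 for rows with disjoint support. Rows that are
#' entirely zero have no defined dissimilarity and are excluded with a
#' warning; the retained ids are in `attr(, "ids")`.
#'
#' @param x Non-negative matrix (units x taxa) or `abundance_tbl`.
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "abundance_tbl")) x <- abundance_values(x)
  x <- as.matrix(x)
  if (any(x < 0)) abort("abundances must be non-negative")
  zero <- rowSums(x) == 0
  if (any(zero)) {
    warn(paste0("excluding ", sum(zero), " all-zero unit(s) from ",
                "Bray-Curtis: ", paste(head(rownames(x)[zero], 5),
                                       collapse = ", ")))
    x <- x[!zero, , drop = FALSE]
  }
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "ids") <- rownames(x)
  d
}

#' Group-average (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with unweighted pair-group mean linkage; merge
#' heights are non-decreasing. Flat clusters are cut either at a
#' dissimilarity height `h` or into `k` groups.
#'
#' @param d A `dist` of dissimilarities.
#' @param h,k Optional cut height or number of clusters.
#' @return List with the `hclust` tree and (if a cut was requested) a
#'   tibble `clusters` of `id`, `cluster`.
#' @export
upgma_cluster <- function(d, h = NULL, k = NULL) {
  if (attr(d, "Size") < 2) abort("need at least two units")
  tree <- hclust(d, method = "average")
  out <- list(tree = tree)
  if (!is.null(h) || !is.null(k)) {
    cl <- cutree(tree, k = k, h = h)
    ids <- tree$labels %||% attr(d, "ids") %||% as.character(seq_along(cl))
    out$clusters <- tibble(id = ids, cluster = unname(cl))
  }
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. With mid-ranks `r` of all `M = n(n-1)/2`
#' pairwise dissimilarities, `R = (mean rank between - mean rank within) /
#' (n(n-1)/4)`, so `R` is 1 when all within-group pairs are closer than
#' every between-group pair and near 0 under the null. The p-value is
#' one-sided from `n_perm` label permutations with the +1 correction.
#'
#' @param d `dist` of dissimilarities.
#' @param groups Group label per unit (>= 2 groups, each of size >= 2).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An `anosim_result`: list with `statistic`, `p_value`, `n_perm`,
#'   `groups`, `perm_stats`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  stopifnot(length(groups) == n)
  if (nlevels(droplevels(groups)) < 2) abort("need at least two groups")
  if (any(table(groups) < 2)) abort("every group needs at least two members")
  r <- rank(as.vector(d))  # mid-ranks for ties
  denom <- n * (n - 1) / 4
  stat_for <- function(g) {
    between <- as.vector(dist(as.integer(g))) > 0
    (mean(r[between]) - mean(r[!between])) / denom
  }
  r_obs <- stat_for(groups)
  set.seed(child_seed(seed, 555L))
  perm <- vapply(seq_len(n_perm), function(i) stat_for(sample(groups)),
                 numeric(1))
  p <- (sum(perm >= r_obs) + 1) / (n_perm + 1)
  structure(list(statistic = r_obs, p_value = p, n_perm = n_perm,
                 groups = groups, perm_stats = perm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", round(x$statistic, 4), ", p =", signif(x$p_value, 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' @export
glance.anosim_result <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n_perm = x$n_perm,
         n_groups = nlevels(droplevels(x$groups)))
}

#' Similarity percentages (SIMPER) decomposition
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions. For each between-group pair of units (x, y)
#' taxon j contributes `|x_j - y_j| / sum_k (x_k + y_k)`; contributions
#' are averaged over all between-group pairs, so they sum exactly to the
#' mean between-group dissimilarity. Computed on the same (transformed)
#' matrix as the dissimilarities.
#'
#' @param x Non-negative matrix (units x taxa), typically
#'   [double_root()]-transformed.
#' @param groups Two-level group label per row.
#' @return A `simper_table` tibble sorted by decreasing contribution:
#'   `taxon`, `contribution`, `percent`, `cumulative_percent`; the mean
#'   between-group dissimilarity is in `attr(, "mean_dissimilarity")`.
#' @export
simper_table <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  stopifnot(nrow(x) == length(groups))
  lev <- levels(droplevels(groups))
  if (length(lev) != 2) abort("SIMPER needs exactly two groups")
  a <- which(groups == lev[1]); b <- which(groups == lev[2])
  if (length(a) == 0 || length(b) == 0) abort("a group has no members")
  contrib <- matrix(0, length(a) * length(b), ncol(x))
  p <- 0
  for (i in a) for (j in b) {
    p <- p + 1
    denom <- sum(x[i, ] + x[j, ])
    contrib[p, ] <- if (denom > 0) abs(x[i, ] - x[j, ]) / denom else 0
  }
  delta <- colMeans(contrib)
  out <- tibble(
    taxon = colnames(x) %||% paste0("taxon", seq_len(ncol(x))),
    contribution = delta,
    percent = 100 * delta / sum(delta)
  ) |>
    dplyr::arrange(dplyr::desc(.data$contribution)) |>
    dplyr::mutate(cumulative_percent = cumsum(.data$percent))
  attr(out, "mean_dissimilarity") <- sum(delta)
  class(out) <- c("simper_table", class(out))
  out
}

#' Shannon diversity index
#'
#' `H = -sum p_j log p_j` with natural logarithm; proportions are taxon
#' shares of the summed abundances and zero proportions contribute 0.
#'
#' @param x Non-negative vector of per-taxon abundances (sum > 0), or a
#'   matrix whose rows are treated separately.
#' @return Scalar H, or one H per row for a matrix.
#' @export
shannon_index <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, shannon_index))
  if (any(x < 0)) abort("abundances must be non-negative")
  s <- sum(x)
  if (s == 0) abort("all-zero abundance vector has no diversity")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal's nm-MDS: coordinates minimising stress-1
#' `sqrt(sum (dhat - disparity)^2 / sum dhat^2)` where disparities are the
#' monotone (pool-adjacent-violators) regression of configuration
#' distances on the rank order of the input dissimilarities. The best of
#' `n_starts` random starts is kept; the returned configuration is centred
#' with its first axis along the principal variance direction.
#'
#' @param d `dist` of dissimilarities (n >= 4).
#' @param dims Number of ordination axes (default 2).
#' @param n_starts Random restarts.
#' @param seed Integer seed.
#' @return An `nmds_ordination`: list with `points` tibble (`id`, `axis1`,
#'   `axis2`, ...), `stress`, `converged`.
#' @export
nmds_ordination <- function(d, dims = 2, n_starts = 20, seed = 1L) {
  if (!all(is.finite(as.vector(d)))) abort("dissimilarities must be finite")
  n <- attr(d, "Size")
  if (n < 4) abort("need at least four units for nm-MDS")
  set.seed(child_seed(seed, 777L))
  fit <- suppressWarnings(
    vegan::metaMDS(d, k = dims, trymax = n_starts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  )
  pts <- fit$points
  ids <- attr(d, "ids") %||% rownames(pts) %||% as.character(seq_len(n))
  points <- as_tibble(pts, .name_repair = "minimal")
  names(points) <- paste0("axis", seq_len(ncol(points)))
  points <- dplyr::bind_cols(tibble(id = ids), points)
  structure(list(points = points, stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$converged > 0,
                 dims = dims),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("nm-MDS:", x$dims, "axes, stress-1 =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble(stress = x$stress, dims = x$dims, converged = x$converged,
         n = nrow(x$points))
}

#' @export
tidy.nmds_ordination <- function(x, ...) x$points

#' Kruskal stress-1 of a configuration against dissimilarities
#'
#' Direct evaluation of stress-1 for externally supplied coordinates:
#' configuration distances are monotone-regressed (pool-adjacent-violators
#' via [stats::isoreg()]) on the rank order of `d`, and
#' `sqrt(sum (dhat - disparity)^2 / sum dhat^2)` is returned. Useful for
#' checking stress invariance under rotation/reflection/scaling of the
#' configuration.
#'
#' @param d `dist` of dissimilarities.
#' @param coords Numeric matrix of coordinates, rows aligned with `d`.
#' @return Stress-1 (scalar >= 0).
#' @export
kruskal_stress <- function(d, coords) {
  dv <- as.vector(d)
  dhat <- as.vector(dist(coords))
  o <- order(dv, dhat)
  fit <- stats::isoreg(dhat[o])
  disp <- fit$yf
  sqrt(sum((dhat[o] - disp)^2) / sum(dhat^2))
}

#' Fit environmental or taxa vectors onto an ordination
#'
#' For every (non-constant) numeric variable, finds the direction in
#' ordination space maximising its multiple correlation with the
#' coordinates; reports the direction cosines, squared correlation r2 and
#' a permutation p-value (variable shuffled across units).
#'
#' @param ordination An [nmds_ordination()] result.
#' @param variables Data frame of per-unit variables, rows aligned with
#'   the ordination points.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble: `variable`, one direction-cosine column per axis,
#'   `r2`, `p_value`.
#' @export
fit_vectors <- function(ordination, variables, n_perm = 999, seed = 1L) {
  stopifnot(inherits(ordination, "nmds_ordination"))
  pts <- as.matrix(ordination$points[, -1])
  variables <- as.data.frame(variables)
  stopifnot(nrow(variables) == nrow(pts))
  keep <- vapply(variables, function(v) is.numeric(v) && sd(v) > 0,
                 logical(1))
  if (any(!keep)) {
    warn(paste0("skipping constant/non-numeric variable(s): ",
                paste(names(variables)[!keep], collapse = ", ")))
  }
  variables <- variables[, keep, drop = FALSE]
  set.seed(child_seed(seed, 888L))
  ef <- vegan::envfit(pts, variables, permutations = n_perm)
  arr <- ef$vectors$arrows
  out <- tibble(variable = rownames(arr))
  for (j in seq_len(ncol(arr))) {
    out[[paste0("axis", j)]] <- arr[, j]
  }
  out$r2 <- unname(ef$vectors$r)
  out$p_value <- unname(ef$vectors$pvals)
  out
}

#' Ordination plot with group colouring and fitted vectors
#'
#' @param object An [nmds_ordination()] result.
#' @param groups Optional group label per unit (colour).
#' @param vectors Optional output of [fit_vectors()] to overlay as arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmds_ordination <- function(object, groups = NULL, vectors = NULL,
                                     ...) {
  pts <- object$points
  if (!is.null(groups)) pts$group <- groups
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "nm-MDS axis 1", y = "nm-MDS axis 2",
      title = sprintf("nm-MDS ordination (stress = %.3f)", object$stress)
    ) +
    ggplot2::theme_minimal()
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
  }
  if (!is.null(vectors)) {
    sc <- 0.8 * max(abs(c(pts$axis1, pts$axis2)))
    v <- dplyr::mutate(vectors,
                       xend = .data$axis1 * sqrt(.data$r2) * sc,
                       yend = .data$axis2 * sqrt(.data$r2) * sc)
    p <- p +
      ggplot2::geom_segment(
        data = v, ggplot2::aes(x = 0, y = 0, xend = .data$xend,
                               yend = .data$yend),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "grey30"
      ) +
      ggplot2::geom_text(
        data = v, ggplot2::aes(x = .data$xend * 1.08, y = .data$yend * 1.08,
                               label = .data$variable),
        colour = "grey30", size = 3
      )
  }
  p
}
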