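# brute-force ANOSIM oracle: exhaustive label permutations
anosim_exhaustive <- function(d, groups) {
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  r <- rank(as.vector(d))
  denom <- n * (n - 1) / 4
  stat <- function(g) {
    between <- as.vector(dist(as.integer(g))) > 0
    (mean(r[between]) - mean(r[!between])) / denom
  }
  obs <- stat(groups)
  idx <- utils::combn(n, sum(groups == levels(groups)[1]))
  stats <- apply(idx, 2, function(a) {
    g <- factor(ifelse(seq_len(n) %in% a, levels(groups)[1],
                       levels(groups)[2]))
    stat(g)
  })
  list(statistic = obs, p = mean(stats >= obs))
}

test_that("the double-root transform is the fourth root", {
  expect_equal(double_root(matrix(c(16, 0, 81, 1), 2))[, 1], c(2, 0))
  expect_equal(double_root(matrix(81))[1, 1], 3)
  expect_equal(double_root(matrix(16), transform = "sqrt")[1, 1], 4)
  expect_error(double_root(matrix(-1)), "non-negative")
})

test_that("Bray-Curtis dissimilarities match the defining formula", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.vector(bray_curtis(m)), 4 / 12, tolerance = 1e-12)
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(0, 5))
  d2 <- bray_curtis(m2)
  expect_equal(as.matrix(d2)["a", "b"], 0)
  m3 <- rbind(a = c(1, 0), b = c(0, 7))
  expect_equal(as.vector(bray_curtis(m3)), 1)

  set.seed(1)
  r <- matrix(rexp(5 * 4), 5)
  rownames(r) <- letters[1:5]
  d <- as.matrix(bray_curtis(r))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], sum(abs(r[i, ] - r[j, ])) / sum(r[i, ] + r[j, ]),
                 tolerance = 1e-12)
  }
  expect_warning(bray_curtis(rbind(a = c(1, 1), b = c(0, 0), c = c(2, 1))),
                 "all-zero")
})

test_that("UPGMA merges by group-average linkage with monotone heights", {
  d <- as.dist(matrix(c(0, 0.1, 0.9,
                        0.1, 0, 0.9,
                        0.9, 0.9, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  res <- upgma_cluster(d, k = 2)
  expect_equal(res$tree$height, c(0.1, 0.9), tolerance = 1e-12)
  expect_equal(res$clusters$cluster[1], res$clusters$cluster[2])
  expect_false(res$clusters$cluster[1] == res$clusters$cluster[3])

  same <- as.dist(matrix(0, 4, 4))
  t0 <- upgma_cluster(same, h = 0.5)
  expect_true(all(t0$clusters$cluster == 1))

  set.seed(2)
  rd <- dist(matrix(runif(40), 10))
  expect_true(all(diff(upgma_cluster(rd)$tree$height) >= -1e-12))
})

test_that("ANOSIM separates groups and matches brute-force enumeration", {
  # perfect separation: all within-distances below all between-distances
  x <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 5, 0.01), 4))
  d <- dist(x)
  res <- anosim_test(d, rep(c("a", "b"), each = 4), n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05)

  # null: random labels on i.i.d. data give R near zero on average
  set.seed(5)
  r_null <- replicate(60, {
    y <- matrix(rnorm(8 * 3), 8)
    anosim_test(dist(y), sample(rep(c("a", "b"), each = 4)),
                n_perm = 99, seed = 1)$statistic
  })
  expect_lt(abs(mean(r_null)), 0.1)

  # n = 6 (3+3): permutation p agrees with exhaustive enumeration
  set.seed(7)
  y <- matrix(rnorm(6 * 3), 6)
  d6 <- dist(y)
  g6 <- rep(c("a", "b"), each = 3)
  res6 <- anosim_test(d6, g6, n_perm = 999, seed = 2)
  ex <- anosim_exhaustive(d6, g6)
  expect_equal(res6$statistic, ex$statistic, tolerance = 1e-12)
  expect_lt(abs(res6$p_value - ex$p), 0.05)

  expect_error(anosim_test(d6, c("a", rep("b", 5)), n_perm = 99),
               "at least two members")
})

test_that("ANOSIM agrees with the vegan implementation", {
  set.seed(11)
  x <- matrix(rexp(12 * 5), 12)
  g <- rep(c("a", "b"), each = 6)
  d <- vegan::vegdist(x, "bray")
  ours <- anosim_test(d, g, n_perm = 999, seed = 3)
  ref <- vegan::anosim(d, g, permutations = 999)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.05)
})

test_that("SIMPER contributions decompose the between-group dissimilarity", {
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(rexp(10 * 6), 10)
    colnames(x) <- paste0("t", 1:6)
    g <- rep(c("a", "b"), each = 5)
    s <- simper_table(x, g)
    db <- as.matrix(bray_curtis(x))
    between <- mean(db[1:5, 6:10])
    expect_equal(attr(s, "mean_dissimilarity"), between, tolerance = 1e-12)
    expect_equal(sum(s$contribution), between, tolerance = 1e-12)
    expect_equal(sum(s$percent), 100, tolerance = 1e-9)
    expect_equal(max(s$cumulative_percent), 100, tolerance = 1e-9)
  }

  # only one taxon differs: it carries the whole dissimilarity
  x1 <- rbind(c(1, 2, 5), c(1, 2, 0), c(1, 2, 4), c(1, 2, 0.5))
  colnames(x1) <- c("same1", "same2", "diff")
  s1 <- simper_table(x1, c("a", "b", "a", "b"))
  expect_equal(s1$taxon[1], "diff")
  expect_equal(s1$percent[1], 100, tolerance = 1e-9)

  # two singleton groups reduce to the single-pair terms
  xa <- c(1, 0, 2); xb <- c(0, 1, 2)
  s2 <- simper_table(rbind(xa, xb), c("a", "b"))
  expect_equal(sort(s2$contribution),
               sort(c(1 / 6, 1 / 6, 0)), tolerance = 1e-12)
})

test_that("Shannon diversity follows the proportional formula", {
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(c(2, 2)), log(2))
  expect_equal(shannon_index(rep(0.3, 7)), log(7))
  m <- rbind(c(1, 1), c(3, 0))
  expect_equal(unname(shannon_index(m)), c(log(2), 0))
  expect_equal(unname(shannon_index(m)),
               unname(vegan::diversity(m, "shannon")))
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("nm-MDS recovers embeddable configurations and ranks", {
  set.seed(4)
  pts <- matrix(rnorm(8), 4, 2)
  d <- dist(pts)
  ord <- nmds_ordination(d, dims = 2, n_starts = 10, seed = 1)
  expect_lt(ord$stress, 0.01)

  # larger, noisier problem: stress decreases with dimensionality
  x <- matrix(rnorm(12 * 6), 12)
  dd <- dist(x)
  s2 <- nmds_ordination(dd, dims = 2, n_starts = 10, seed = 1)$stress
  s1 <- nmds_ordination(dd, dims = 1, n_starts = 10, seed = 1)$stress
  expect_lte(s2, s1 + 1e-8)

  expect_error(nmds_ordination(dist(matrix(rnorm(6), 3))), "at least four")
})

test_that("stress-1 is invariant to rotation, reflection and scaling", {
  set.seed(6)
  x <- matrix(rnorm(10 * 4), 10)
  d <- dist(x)
  ord <- nmds_ordination(d, dims = 2, n_starts = 10, seed = 2)
  coords <- as.matrix(ord$points[, c("axis1", "axis2")])
  s0 <- kruskal_stress(d, coords)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(kruskal_stress(d, coords %*% rot), s0, tolerance = 1e-10)
  expect_equal(kruskal_stress(d, coords %*% diag(c(-1, 1))), s0,
               tolerance = 1e-10)
  expect_equal(kruskal_stress(d, 3.7 * coords), s0, tolerance = 1e-10)
  # our evaluation agrees with the stress reported by the optimiser
  expect_equal(s0, ord$stress, tolerance = 0.02)
})

test_that("vector fitting recovers aligned drivers and ignores noise", {
  set.seed(8)
  x <- matrix(rnorm(20 * 5), 20)
  d <- dist(x)
  ord <- nmds_ordination(d, dims = 2, n_starts = 10, seed = 1)
  v <- data.frame(aligned = ord$points$axis1,
                  noise = rnorm(20))
  fits <- fit_vectors(ord, v, n_perm = 199, seed = 1)
  al <- fits[fits$variable == "aligned", ]
  expect_gt(al$r2, 0.999)
  expect_gt(abs(al$axis1), 0.99)
  expect_lt(fits$r2[fits$variable == "noise"], al$r2)

  v2 <- data.frame(aligned = 5 - 2 * ord$points$axis1)
  f2 <- fit_vectors(ord, v2, n_perm = 199, seed = 1)
  expect_equal(f2$r2, al$r2, tolerance = 1e-8)

  expect_warning(fit_vectors(ord, data.frame(flat = rep(1, 20),
                                             ok = rnorm(20)),
                             n_perm = 99, seed = 1), "constant")
})
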