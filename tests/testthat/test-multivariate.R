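test_that("pairwise distances satisfy their metric anchors", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- pairwise_distances(x)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  b <- rbind(p = c(1, 1, 0), q = c(1, 0, 1))
  dj <- pairwise_distances(b, "JACCARD")
  expect_equal(dj["p", "q"], 2 / 3)     # union 3, intersection 1
  dm <- pairwise_distances(b, "SIMPLE_MATCHING")
  expect_equal(dm["p", "q"], 2 / 3)     # 2 mismatches of 3
  expect_error(pairwise_distances(rbind(c(0, 2), c(1, 1)), "JACCARD"), "binary")
})

test_that("permanova matches vegan::adonis2 on SS, R2 and F", {
  skip_if_not_installed("vegan")
  set.seed(42)
  x <- matrix(rnorm(30 * 8), 30)
  meta <- data.frame(grp = rep(c("a", "b", "c"), each = 10), cov = rnorm(30))
  d <- pairwise_distances(x)
  pm <- permanova(d, ~ grp + cov, meta, permutations = 99, seed = 7)
  ad <- vegan::adonis2(stats::as.dist(d) ~ grp + cov, data = meta,
                       permutations = 99, by = "terms")
  expect_equal(pm$aov_table$SS, ad$SumOfSqs, tolerance = 1e-10)
  expect_equal(pm$aov_table$R2, ad$R2, tolerance = 1e-10)
  expect_equal(pm$aov_table$F[1:2], ad$F[1:2], tolerance = 1e-10)
  # R2 decomposition sums to one
  expect_equal(sum(pm$aov_table$R2[1:3]), 1)
})

test_that("permanova p equals the exhaustive enumeration oracle", {
  set.seed(5)
  x <- matrix(rnorm(6 * 3), 6)
  g <- data.frame(grp = rep(c("a", "b"), each = 3))
  d <- pairwise_distances(x)
  pm <- permanova(d, ~ grp, g, permutations = "exhaustive")
  expect_equal(pm$aov_table$p[1], brute_permanova_p(d, g$grp))
})

test_that("permanova is scale invariant and seed reproducible", {
  set.seed(9)
  x <- matrix(rnorm(20 * 4), 20)
  g <- data.frame(grp = rep(c("a", "b"), each = 10))
  d <- pairwise_distances(x)
  p1 <- permanova(d, ~ grp, g, permutations = 199, seed = 3)
  p2 <- permanova(as_distance_matrix(d * 7.3), ~ grp, g,
                  permutations = 199, seed = 3)
  expect_equal(p1$aov_table$F, p2$aov_table$F)
  expect_equal(p1$aov_table$R2, p2$aov_table$R2)
  expect_equal(p1$aov_table$p, p2$aov_table$p)
  p3 <- permanova(d, ~ grp, g, permutations = 199, seed = 3)
  expect_identical(p1$aov_table, p3$aov_table)
  # null data: R2 near zero
  expect_lt(p1$aov_table$R2[1], 0.2)
})

test_that("permanova rejects degenerate inputs", {
  d <- pairwise_distances(matrix(rnorm(12), 6))
  expect_error(permanova(d, ~ grp, data.frame(grp = rep("a", 6)), 99),
               "single level")
  expect_error(permanova(d, ~ grp, data.frame(grp = rep(c("a", "b"), 3)), 0),
               "permutations")
})

test_that("permdisp matches betadisper geometry and detects scale shifts", {
  skip_if_not_installed("vegan")
  set.seed(12)
  x <- matrix(rnorm(30 * 5), 30)
  g <- rep(c("a", "b"), each = 15)
  d <- pairwise_distances(x)
  pd <- permdisp(d, g, permutations = 99, seed = 2)
  bd <- vegan::betadisper(stats::as.dist(d), g, type = "centroid")
  expect_equal(unname(pd$distances), unname(bd$distances), tolerance = 1e-10)
  expect_equal(pd$F, stats::anova(bd)$`F value`[1], tolerance = 1e-10)

  # one group scaled x3 is detected in most seeded runs (n = 20/group)
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    xa <- matrix(rnorm(20 * 4), 20)
    xb <- matrix(rnorm(20 * 4), 20) * 3
    dd <- pairwise_distances(rbind(xa, xb))
    permdisp(dd, rep(c("a", "b"), each = 20), permutations = 199,
             seed = s)$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  # mirrored identical scatter: F ~ 0, p high
  xa <- matrix(rnorm(24), 12)
  dd <- pairwise_distances(rbind(xa, -xa))
  pd2 <- permdisp(dd, rep(c("a", "b"), each = 12), permutations = 199, seed = 1)
  expect_lt(pd2$F, 1e-10)
  expect_gt(pd2$p, 0.5)

  # size-1 groups are excluded with a warning
  expect_warning(permdisp(d, c("z", rep(c("a", "b"), length.out = 29)), 49),
                 "size-1")
})

test_that("permdisp p is approximately uniform under the null", {
  ps <- vapply(1:200, function(s) {
    set.seed(2000 + s)
    x <- matrix(rnorm(20 * 3), 20)
    permdisp(pairwise_distances(x), rep(c("a", "b"), each = 10),
             permutations = 99, seed = s)$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.12)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("pcoa reproduces Euclidean geometry and principal components", {
  set.seed(3)
  pts <- matrix(rnorm(12 * 2), 12)
  d <- pairwise_distances(pts)
  ord <- pcoa(d)
  # embedded coordinates reproduce the original inter-point distances
  expect_lt(max(abs(as.matrix(stats::dist(ord$points)) - d)), 1e-9)
  # PCoA of Euclidean distances = PCA scores up to sign
  pc <- stats::prcomp(pts)
  expect_lt(max(abs(abs(ord$points[, 1:2]) - abs(pc$x[, 1:2]))), 1e-8)
  # eigenvalues non-increasing, explained sums to 1 over positive axes
  expect_true(all(diff(ord$positive_eigenvalues) <= 1e-12))
  expect_equal(sum(ord$explained), 1)
  # coordinates centred at origin
  expect_lt(max(abs(colMeans(ord$points))), 1e-10)

  # two samples at distance 2 -> coordinates +/- 1
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(sort(pcoa(d2)$points[, 1]), c(a = -1, b = 1),
               ignore_attr = TRUE)
  # zero matrix
  dz <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(oz <- pcoa(dz), "all-zero")
  expect_true(all(oz$points == 0))
})

test_that("pcoa corrections handle non-Euclidean distances", {
  # a metric but non-Euclidean configuration yields negative eigenvalues
  d <- matrix(c(0, 1, 1, 1.9,
                1, 0, 1.9, 1,
                1, 1.9, 0, 1,
                1.9, 1, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- pcoa(d, "NONE")
  expect_lt(min(raw$eigenvalues), 0)
  lin <- pcoa(d, "LINGOES")
  expect_gte(min(lin$eigenvalues), -1e-8 * max(lin$eigenvalues))
})

test_that("rda_partition fractions behave like sequential projections", {
  set.seed(8)
  g <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"))
  g <- g[rep(1:4, each = 5), ]
  y <- matrix(rnorm(20 * 3), 20)
  p1 <- rda_partition(y, ~ f1 + f2, g)
  p2 <- rda_partition(y, ~ f2 + f1, g)
  # orthogonal balanced factors: order invariant
  expect_equal(p1$f1, p2$f1, tolerance = 1e-9)
  expect_equal(p1$f2, p2$f2, tolerance = 1e-9)
  expect_equal(p1$combined + p1$residual, 1)

  # a term identical to the (univariate) response explains everything
  yy <- matrix(rnorm(20), 20)
  pf <- rda_partition(yy, ~ z, data.frame(z = yy[, 1]))
  expect_equal(pf$combined, 1)

  # duplicated term adds nothing
  expect_warning(pd <- rda_partition(y, ~ f1 + f1b,
                                     transform(g, f1b = f1)), "no rank")
  expect_lt(pd$f1b, 1e-12)
})

test_that("rda_partition agrees with vegan::rda constrained inertia", {
  skip_if_not_installed("vegan")
  set.seed(10)
  g <- data.frame(f1 = rep(c("a", "b"), 10), z = rnorm(20))
  y <- matrix(rnorm(20 * 4), 20)
  p <- rda_partition(y, ~ f1 + z, g)
  vr <- vegan::rda(y ~ f1 + z, data = g)
  expect_equal(p$combined, vr$CCA$tot.chi / vr$tot.chi, tolerance = 1e-10)
})

test_that("dbrda recovers constructed structure and matches capscale", {
  skip_if_not_installed("vegan")
  set.seed(6)
  x <- matrix(rnorm(25 * 6), 25)
  d <- pairwise_distances(x)
  pred <- data.frame(a = rnorm(25), b = rnorm(25))
  db <- epimsap::dbrda(d, pred, permutations = 99, seed = 4)
  cap <- vegan::capscale(stats::as.dist(d) ~ a + b, data = pred)
  expect_equal(db$constrained_fraction, cap$CCA$tot.chi / cap$tot.chi,
               tolerance = 1e-10)

  # single predictor equal to PCoA axis 1: constrained fraction = axis-1 share
  ord <- pcoa(d)
  db1 <- epimsap::dbrda(d, data.frame(ax1 = ord$points[, 1]),
                        permutations = 49, seed = 1)
  expect_equal(db1$constrained_fraction, ord$explained[1], tolerance = 1e-10)

  expect_error(epimsap::dbrda(d, data.frame(k = rep(1, 25)), 49), "k")
})

test_that("group centroids are arithmetic means with edge handling", {
  pts <- rbind(a = c(1, 1), b = c(3, 5), c = c(10, -2))
  ord <- list(points = pts)
  g <- factor(c("g1", "g1", "g2"))
  ce <- group_centroids(ord, g)
  expect_equal(ce["g1", ], colMeans(pts[1:2, ]), ignore_attr = TRUE)
  expect_equal(ce["g2", ], pts["c", ], ignore_attr = TRUE)   # singleton
  # two symmetric points -> midpoint at origin
  ce2 <- group_centroids(list(points = rbind(c(-2, 1), c(2, -1))),
                         factor(c("g", "g")))
  expect_equal(unname(ce2[1, ]), c(0, 0))
  # matches direct mean oracle
  set.seed(2)
  P <- matrix(rnorm(30), 10)
  gg <- factor(rep(1:2, 5))
  ce3 <- group_centroids(list(points = P), gg)
  expect_equal(ce3["1", ], colMeans(P[gg == "1", ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(group_centroids(list(points = P),
                                 factor(rep("a", 10), levels = c("a", "b"))),
                 "empty")
})
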