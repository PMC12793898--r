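test_that("sedimentation rate follows the trap-area formula", {
  area <- pi * 3.2^2
  expect_equal(sedimentation_rate(1351.2, 6.4, 42), 1351.2 / (area * 42))
  expect_equal(sedimentation_rate(1351.2, 6.4, 42), 1.0, tolerance = 1e-3)
  expect_equal(sedimentation_rate(0, 6.4, 10), 0)
  # doubling days halves the rate
  expect_equal(sedimentation_rate(500, 6.4, 84),
               sedimentation_rate(500, 6.4, 42) / 2)
  expect_error(sedimentation_rate(100, 6.4, 0), "days")
  expect_error(sedimentation_rate(-1, 6.4, 10), "mass")
})

test_that("N:P status uses the 16 and 22 thresholds with stated bounds", {
  expect_equal(as.character(np_status(160, 10)$status), "N_LIMITED")  # ratio 16
  expect_equal(np_status(160, 10)$ratio, 16)
  expect_equal(as.character(np_status(200, 10)$status), "TRANSITION") # ratio 20
  expect_equal(as.character(np_status(220, 10)$status), "TRANSITION") # ratio 22
  expect_equal(as.character(np_status(300, 10)$status), "P_LIMITED")  # ratio 30
  expect_error(np_status(10, 0), "totalP")
  # partition: exactly one status for any ratio on a dense grid
  ratios <- seq(0.5, 40, by = 0.25)
  st <- np_status(ratios, 1)$status
  expect_false(anyNA(st))
  expect_equal(nlevels(st), 3L)
})

test_that("season assignment covers Jan-Nov and rejects December", {
  expect_equal(season_of(as.Date("2023-03-15")), "DRY")
  expect_equal(season_of(as.Date("2023-07-01")), "WET")
  expect_equal(season_of(as.Date("2023-04-30")), "DRY")
  expect_equal(season_of(as.Date("2023-05-01")), "WET")
  expect_error(season_of(as.Date("2023-12-25")), "December")
  # property: all Jan-Nov dates classify without gaps
  days <- seq(as.Date("2023-01-01"), as.Date("2023-11-30"), by = "week")
  expect_false(anyNA(season_of(days)))
})

test_that("size classes use inclusive 40-60 mm medium bounds", {
  expect_equal(as.character(size_class(39.9)), "SMALL")
  expect_equal(as.character(size_class(40.0)), "MEDIUM")
  expect_equal(as.character(size_class(60.0)), "MEDIUM")
  expect_equal(as.character(size_class(60.1)), "LARGE")
  expect_error(size_class(0), "diameter")
  # partition of a dense grid: no NA, all three classes hit
  grid <- seq(1, 120, by = 0.1)
  cls <- size_class(grid)
  expect_false(anyNA(cls))
  expect_equal(sort(unique(as.character(cls))),
               sort(c("SMALL", "MEDIUM", "LARGE")))
})

test_that("transect density and its summaries are exact", {
  expect_equal(transect_density(4), 0.2)
  expect_equal(transect_density(0), 0)
  expect_error(transect_density(-1), "counts")
  counts <- c(2, 5, 3, 8, 1, 4)
  by <- rep(c("TG", "AH"), each = 3)
  s <- transect_density(counts, by = by)
  for (g in c("TG", "AH")) {
    expect_equal(s$mean[s$group == g], mean(counts[by == g] / 20))
    expect_equal(s$sd[s$group == g], stats::sd(counts[by == g] / 20))
  }
})

test_that("survival series chain correctly", {
  s <- survival_series(c(14, 7))
  expect_equal(s$table$SR, 0.5)
  s2 <- survival_series(c(5, 5, 5))
  expect_equal(s2$table$SR, c(1, 1))
  expect_equal(s2$mean_SR, 1)
  s3 <- survival_series(c(12, 9, 6))
  expect_equal(s3$table$SR, c(0.75, 2 / 3))
  expect_equal(s3$mean_SR, mean(c(0.75, 2 / 3)))
  # chaining: product of monthly SRs = terminal fraction
  set.seed(31)
  cts <- c(40, sort(sample(0:39, 4), decreasing = TRUE))
  cts <- cts[c(TRUE, cts[-1] > 0)]
  if (length(cts) >= 2) {
    sc <- survival_series(cts)
    expect_equal(prod(sc$table$SR), sc$terminal_fraction)
  }
  expect_warning(survival_series(c(5, 8)), "recruitment")
  s0 <- survival_series(c(6, 0, 0))
  expect_true(s0$terminated)
  expect_equal(nrow(s0$table), 1L)
})

test_that("spearman_corr matches cor.test and the exact enumeration", {
  expect_equal(spearman_corr(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_corr(1:5, 5:1)$rho, -1)
  expect_warning(out <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  # n = 6 with a tie: matches the exhaustive 720-permutation oracle
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1, 4.1)
  y <- c(0.3, 1.1, 0.9, 2.0, 1.4, 1.9)
  out <- spearman_corr(x, y)
  rx <- rank(x); ry <- rank(y)
  expect_equal(out$rho, stats::cor(rx, ry))
  perms <- combinat_perms(6)
  rhos <- vapply(perms, function(i) stats::cor(rx, ry[i]), numeric(1))
  expect_equal(out$p, mean(abs(rhos) >= abs(out$rho) - 1e-12))
  expect_equal(out$method, "exact")
  # rho agrees with cor.test for larger n; p via t-approximation
  set.seed(33)
  x2 <- rnorm(25); y2 <- 0.5 * x2 + rnorm(25)
  out2 <- spearman_corr(x2, y2)
  ct <- suppressWarnings(stats::cor.test(x2, y2, method = "spearman"))
  expect_equal(out2$rho, unname(ct$estimate))
  expect_equal(out2$method, "t-approx")
  expect_lt(abs(out2$p - ct$p.value), 0.02)
})
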