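test_that("binarize_peaks applies the size window and strict RFU filter", {
  mk <- function(size, height) {
    df <- data.frame(sample_id = "S01", digest = "HPA",
                     size = size, height = height, stringsAsFactors = FALSE)
    df <- rbind(df, data.frame(sample_id = "S01", digest = "MSP",
                               size = 100, height = 100))
    class(df) <- c("peak_table", "data.frame")
    df
  }
  # 41 RFU survives the strict > 40 filter
  fm <- binarize_peaks(mk(100, 41))
  expect_true("L100" %in% fm$loci)
  expect_equal(fm$hpa["S01", "L100"], 1)
  # exactly 40 RFU does not
  fm <- binarize_peaks(mk(100.4, 40))
  expect_false(any(fm$hpa == 1))
  # outside the 50-1500 bp window
  fm <- binarize_peaks(mk(1600, 500))
  expect_false("L1600" %in% fm$loci)
  # window bounds are inclusive
  fm <- binarize_peaks(mk(50, 50))
  expect_true("L50" %in% fm$loci)
  fm <- binarize_peaks(mk(1500, 50))
  expect_true("L1500" %in% fm$loci)
  # empty table warns, does not error
  empty <- tiny_peaks()[0, ]
  expect_warning(fm0 <- binarize_peaks(empty), "empty")
  expect_equal(dim(fm0), c(0L, 0L))
})

test_that("peaks bin into fixed-width integer-anchored loci", {
  pt <- tiny_peaks()
  fm <- binarize_peaks(pt)
  # 100.1-100.3 all fall into the 100 bp bin across digests
  expect_true("L100" %in% fm$loci)
  expect_equal(unname(fm$hpa[, "L100"]), c(1, 1))
  expect_equal(unname(fm$msp[, "L100"]), c(1, 0))
  # a sample absent from a digest would be NA; here both digests present
  expect_false(anyNA(fm$hpa))
})

test_that("prevalence filter keeps >= 15% inclusively and is idempotent", {
  # 20 samples; locus A present in 3 (15%), locus B in 2 (10%), locus C in 0
  hpa <- named_mat(0, 20, prefix_c = "A")
  hpa <- cbind(hpa, B = 0, C = 0)
  colnames(hpa)[1] <- "A"
  hpa[1:3, "A"] <- 1
  hpa[1:2, "B"] <- 1
  msp <- hpa * 0
  fm <- fragment_matrix(hpa, msp)
  out <- filter_prevalence(fm, 0.15)
  expect_equal(out$loci, "A")
  expect_equal(out$samples, fm$samples)
  expect_equal(filter_prevalence(out, 0.15)$loci, out$loci)
  # presence in either digest counts (pooled)
  msp2 <- msp; msp2[4, "B"] <- 1
  fm2 <- fragment_matrix(hpa, msp2)
  expect_equal(filter_prevalence(fm2, 0.15)$loci, c("A", "B"))
  # per-digest mode requires each layer separately
  expect_equal(filter_prevalence(fm2, 0.10, per_digest = TRUE)$loci, character(0))
})

test_that("classify_states is the exact truth table and total on {0,1,NA}^2", {
  sts <- named_mat(c("NMT", "HMM", "ICM", "HPM"), 2)
  fm <- fm_from_states(sts)
  sm <- classify_states(fm)
  expect_equal(unname(as.vector(sm$states)), c("NMT", "HMM", "ICM", "HPM"))
  # any NA in either digest gives MISSING
  hpa <- named_mat(c(NA, 1, 0, NA), 2)
  msp <- named_mat(c(1, NA, NA, NA), 2)
  sm2 <- classify_states(fragment_matrix(hpa, msp))
  expect_true(all(sm2$states == "MISSING"))
  # totality: the four states partition all digit pairs
  grid <- expand.grid(h = c(0, 1), m = c(0, 1))
  st <- classify_states(fragment_matrix(
    named_mat(grid$h, 4, prefix_c = "X"),
    named_mat(grid$m, 4, prefix_c = "X")))$states
  expect_setequal(as.vector(st), c("HPM", "HMM", "ICM", "NMT"))
})

test_that("partition_msl flags methylation-susceptible and polymorphic loci", {
  sts <- cbind(pure_nmt = rep("NMT", 20),
               mostly_nmt = c(rep("ICM", 2), rep("NMT", 18)),
               pure_hpm = rep("HPM", 20))
  rownames(sts) <- paste0("s", 1:20)
  sm <- partition_msl(classify_states(fm_from_states(sts)))
  expect_false(sm$is_msl[["pure_nmt"]])      # no methylation evidence
  expect_true(sm$is_msl[["mostly_nmt"]])     # 10% ICM > 5% threshold
  expect_true(sm$is_msl[["pure_hpm"]])       # fully methylated yet monomorphic
  expect_true(sm$is_polymorphic[["mostly_nmt"]])
  expect_false(sm$is_polymorphic[["pure_hpm"]])
  # MSL + non-MSL = locus count
  expect_equal(sum(sm$is_msl) + sum(!sm$is_msl), length(sm$loci))
  # exactly at the threshold is not "exceeds"
  sts2 <- cbind(at_thr = c(rep("ICM", 1), rep("NMT", 19)))
  rownames(sts2) <- paste0("s", 1:20)
  sm2 <- partition_msl(classify_states(fm_from_states(sts2)))
  expect_false(sm2$is_msl[["at_thr"]])       # 5% is not > 5%

  # all-MISSING locus is dropped with a warning
  hpa <- named_mat(c(1, 1, NA, NA), 2)
  msp <- named_mat(c(1, 0, NA, NA), 2)
  expect_warning(sm3 <- partition_msl(classify_states(fragment_matrix(hpa, msp))),
                 "no sample")
  expect_equal(sm3$loci, "L1")
})

test_that("encode_matrix implements both schemes with mean imputation", {
  sts <- cbind(L1 = c("NMT", "HPM", "ICM", "MISSING"),
               L2 = c("HMM", "HMM", "NMT", "NMT"))
  rownames(sts) <- paste0("s", 1:4)
  fm <- fm_from_states(sts)
  sm <- partition_msl(classify_states(fm))
  x <- encode_matrix(sm, "METH_BINARY")
  expect_equal(unname(x[1:3, "L1"]), c(0, 1, 1))
  # MISSING imputed with the feature mean of scored samples
  expect_equal(unname(x[4, "L1"]), mean(c(0, 1, 1)))
  expect_equal(attr(x, "n_imputed"), 1L)

  oh <- encode_matrix(sm, "ONEHOT4")
  # ICM one-hot in fixed NMT, HMM, ICM, HPM order
  expect_equal(unname(oh[3, paste0("L1.", c("NMT", "HMM", "ICM", "HPM"))]),
               c(0, 0, 1, 0))
  expect_error(encode_matrix(sm, "SOMETHING"))
  expect_error(encode_matrix(classify_states(fm)), "partition_msl")
})

test_that("state matrices round-trip through CSV with flags", {
  sim <- gen_msap(sim_config(n_samples_per_group = 3, n_loci = 12), seed = 4)
  sm <- partition_msl(classify_states(sim$fragments))
  f <- tempfile(fileext = ".csv")
  write_state_matrix(sm, f)
  back <- read_state_matrix(f)
  expect_equal(back$states, sm$states)
  expect_equal(back$is_msl, sm$is_msl)
  expect_equal(back$is_polymorphic, sm$is_polymorphic)
})
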