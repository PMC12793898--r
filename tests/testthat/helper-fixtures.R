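# Small in-code fixtures shared across tests.

# a tiny well-formed peak table covering both digests
tiny_peaks <- function() {
  df <- data.frame(
    sample_id = rep(c("S01", "S02"), each = 4),
    digest = rep(c("HPA", "HPA", "MSP", "MSP"), 2),
    size = c(100.2, 250.4, 100.1, 420.0,
             100.3, 250.1, 250.2, 420.2),
    height = c(55, 80, 120, 60, 45, 90, 70, 41),
    stringsAsFactors = FALSE)
  class(df) <- c("peak_table", "data.frame")
  df
}

# fragment matrix built directly from digit pairs; states is a character
# matrix of intended states, "MISSING" rows get NA digests
fm_from_states <- function(states) {
  hpa <- matrix(NA_real_, nrow(states), ncol(states), dimnames = dimnames(states))
  msp <- hpa
  hpa[states == "NMT"] <- 1; msp[states == "NMT"] <- 1
  hpa[states == "HMM"] <- 1; msp[states == "HMM"] <- 0
  hpa[states == "ICM"] <- 0; msp[states == "ICM"] <- 1
  hpa[states == "HPM"] <- 0; msp[states == "HPM"] <- 0
  fragment_matrix(hpa, msp)
}

named_mat <- function(data, nr, prefix_r = "s", prefix_c = "L") {
  m <- matrix(data, nr)
  dimnames(m) <- list(paste0(prefix_r, seq_len(nr)),
                      paste0(prefix_c, seq_len(ncol(m))))
  m
}

# independent brute-force PERMANOVA for one 2-level factor: classic group
# sum-of-squares formula over all distinct label splits
brute_permanova_p <- function(D, groups) {
  D2 <- D^2
  n <- nrow(D)
  ss_within <- function(g) {
    s <- 0
    for (lv in unique(g)) {
      i <- which(g == lv)
      s <- s + sum(D2[i, i]) / (2 * length(i))
    }
    s
  }
  ss_tot <- sum(D2) / (2 * n)
  k <- length(unique(groups))
  f_of <- function(g) {
    ssw <- ss_within(g)
    ((ss_tot - ssw) / (k - 1)) / (ssw / (n - k))
  }
  F_obs <- f_of(groups)
  n1 <- sum(groups == unique(groups)[1])
  splits <- utils::combn(n, n1)
  Fs <- apply(splits, 2, function(i) {
    g <- rep("b", n); g[i] <- "a"
    f_of(g)
  })
  mean(Fs >= F_obs - 1e-12)
}

# exhaustive permutations via grid filtering (independent of the package's
# internal generator); fine for n <= 6
combinat_perms <- function(n) {
  g <- do.call(expand.grid, rep(list(seq_len(n)), n))
  g <- g[apply(g, 1, function(r) length(unique(r)) == n), ]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}
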