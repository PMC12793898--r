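# MSAP scoring: peak filtering/binning into a two-digest binary fragment
# matrix, methylation-state classification from the HpaII/MspI pattern, and
# the methylation-susceptible-locus (MSL) partition.
#
# State code (HpaII/MspI):
#   1/1 NMT  non-methylated           (signal in both digests)
#   1/0 HMM  hemimethylated           (HpaII only)
#   0/1 ICM  internal CpG methylation (MspI only)
#   0/0 HPM  hypermethylated          (no signal; conservatively methylation,
#                                      not fragment loss)

#' Binarize a peak table into a fragment matrix
#'
#' Applies the scoring window and intensity filter, bins surviving peaks into
#' fixed-width fragment-size loci, and marks a locus present (1) for a
#' sample/digest when at least one surviving peak falls in its bin. Defaults
#' follow common MSAP scoring practice: fragments between 50 and 1500 bp with
#' signal intensity strictly greater than 40 RFU, 1 bp bins anchored at
#' integer sizes.
#'
#' Samples seen in only one digest get NA across the other digest's layer
#' (unscored), with a warning.
#'
#' @param peaks a `peak_table` from [read_peak_table()].
#' @param size_min,size_max inclusive fragment-size window in bp.
#' @param rfu_min peaks must exceed this intensity (strict `>`), in RFU.
#' @param bin_width locus bin width in bp; bins are centred on multiples of
#'   `bin_width`.
#' @return a [fragment_matrix()]; empty peak table gives an empty matrix with
#'   a warning. Bins with no surviving peak in any sample do not appear.
#' @export
binarize_peaks <- function(peaks, size_min = 50, size_max = 1500,
                           rfu_min = 40, bin_width = 1.0) {
  stopifnot(size_min < size_max, rfu_min >= 0, bin_width > 0)
  pk <- as.data.frame(peaks)
  if (nrow(pk) == 0L) {
    warnf("empty peak table: returning empty fragment matrix")
    m <- matrix(numeric(0), 0, 0, dimnames = list(character(0), character(0)))
    return(fragment_matrix(m, m))
  }
  keep <- pk$size >= size_min & pk$size <= size_max & pk$height > rfu_min
  pk <- pk[keep, , drop = FALSE]
  samples <- sort(unique(as.character(peaks$sample_id)))
  if (nrow(pk) == 0L) {
    warnf("no peaks survive the size/RFU filters")
    m <- matrix(NA_real_, length(samples), 0,
                dimnames = list(samples, character(0)))
    return(fragment_matrix(m, m))
  }
  centre <- round(pk$size / bin_width) * bin_width
  loci <- sort(unique(centre))
  locus_id <- paste0("L", format(loci, trim = TRUE, scientific = FALSE))
  layer <- function(dg) {
    m <- matrix(0, length(samples), length(loci),
                dimnames = list(samples, locus_id))
    sub <- pk[pk$digest == dg, , drop = FALSE]
    # samples never seen in this digest are unscored, not absent
    seen <- unique(as.character(peaks$sample_id[peaks$digest == dg]))
    unseen <- setdiff(samples, seen)
    if (length(unseen)) {
      warnf("%d sample(s) have no peaks in the %s digest; scored NA there",
            length(unseen), dg)
      m[unseen, ] <- NA_real_
    }
    if (nrow(sub)) {
      i <- match(as.character(sub$sample_id), samples)
      j <- match(round(sub$size / bin_width) * bin_width, loci)
      m[cbind(i, j)] <- 1
    }
    m
  }
  fragment_matrix(layer("HPA"), layer("MSP"))
}

#' Filter loci by sample prevalence
#'
#' Retains loci whose fragment is present (1 in either digest) in at least
#' `min_prevalence` of samples (inclusive; the default keeps a locus present
#' in exactly 15% of samples). The sample set is unchanged. Idempotent.
#'
#' @param fm a `fragment_matrix`.
#' @param min_prevalence fraction in \[0, 1\]; default 0.15.
#' @param per_digest if TRUE, a locus must meet the prevalence in each digest
#'   separately rather than pooled across digests.
#' @return the filtered `fragment_matrix`.
#' @export
filter_prevalence <- function(fm, min_prevalence = 0.15, per_digest = FALSE) {
  stopifnot(inherits(fm, "fragment_matrix"),
            min_prevalence >= 0, min_prevalence <= 1)
  n <- length(fm$samples)
  if (n == 0L || length(fm$loci) == 0L) return(fm)
  count1 <- function(m) colSums(m == 1, na.rm = TRUE)
  if (per_digest) {
    keep <- count1(fm$hpa) / n >= min_prevalence &
            count1(fm$msp) / n >= min_prevalence
  } else {
    pooled <- (fm$hpa == 1) | (fm$msp == 1)
    keep <- colSums(pooled, na.rm = TRUE) / n >= min_prevalence
  }
  fragment_matrix(fm$hpa[, keep, drop = FALSE], fm$msp[, keep, drop = FALSE])
}

#' Classify methylation states from the two-digest pattern
#'
#' Total mapping on \{0, 1, NA\} pairs per sample x locus: (1,1) NMT, (1,0)
#' HMM, (0,1) ICM, (0,0) HPM (joint absence is conservatively treated as
#' hypermethylation rather than fragment loss); any NA in either digest gives
#' MISSING.
#'
#' @param fm a `fragment_matrix` with both digest layers.
#' @return a `state_matrix`: character matrix of states plus per-locus flag
#'   placeholders, completed by [partition_msl()].
#' @export
classify_states <- function(fm) {
  stopifnot(inherits(fm, "fragment_matrix"))
  code <- fm$hpa * 2 + fm$msp           # 3=NMT, 2=HMM, 1=ICM, 0=HPM
  states <- matrix("MISSING", nrow(code), ncol(code), dimnames = dimnames(code))
  ok <- !is.na(code)
  states[ok] <- c("HPM", "ICM", "HMM", "NMT")[code[ok] + 1L]
  structure(list(states = states,
                 samples = fm$samples, loci = fm$loci,
                 is_msl = NULL, is_polymorphic = NULL,
                 meth_threshold = NA_real_),
            class = "state_matrix")
}

#' Partition loci into methylation-susceptible loci (MSL)
#'
#' A locus is methylation-susceptible when the fraction of scored
#' (non-MISSING) samples showing a methylated state (HMM, ICM or HPM)
#' exceeds `meth_threshold`; the 5% default follows the usual MSL
#' error-threshold convention. Also flags polymorphic loci (at least two
#' distinct non-MISSING states observed). Loci scored in no sample are
#' dropped with a warning.
#'
#' @param sm a `state_matrix` from [classify_states()].
#' @param meth_threshold fraction in \[0, 1\]; default 0.05 (strict `>`).
#' @return the `state_matrix` with `is_msl`, `is_polymorphic` and a `counts`
#'   summary (MSL, polymorphic MSL, percentages) filled in.
#' @export
partition_msl <- function(sm, meth_threshold = 0.05) {
  stopifnot(inherits(sm, "state_matrix"),
            meth_threshold >= 0, meth_threshold <= 1)
  st <- sm$states
  scored <- st != "MISSING"
  n_scored <- colSums(scored)
  empty <- n_scored == 0L
  if (any(empty)) {
    warnf("%d locus/loci scored in no sample; excluded", sum(empty))
    st <- st[, !empty, drop = FALSE]
    scored <- scored[, !empty, drop = FALSE]
    n_scored <- n_scored[!empty]
    sm$loci <- colnames(st)
    sm$states <- st
  }
  meth_frac <- vapply(seq_len(ncol(st)), function(j) {
    s <- st[scored[, j], j]
    if (!length(s)) 0 else mean(s %in% c("HMM", "ICM", "HPM"))
  }, numeric(1))
  is_msl <- meth_frac > meth_threshold
  is_poly <- vapply(seq_len(ncol(st)), function(j) {
    length(unique(st[scored[, j], j])) >= 2L
  }, logical(1))
  names(is_msl) <- names(is_poly) <- colnames(st)
  sm$is_msl <- is_msl
  sm$is_polymorphic <- is_poly
  sm$meth_threshold <- meth_threshold
  n_msl <- sum(is_msl)
  n_poly_msl <- sum(is_msl & is_poly)
  sm$counts <- list(
    n_loci = ncol(st),
    n_msl = n_msl,
    n_polymorphic_msl = n_poly_msl,
    pct_msl = 100 * n_msl / max(ncol(st), 1L),
    pct_polymorphic_of_msl = if (n_msl) 100 * n_poly_msl / n_msl else NA_real_)
  sm
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("MSAP state matrix: %d samples x %d loci\n",
              length(x$samples), length(x$loci)))
  tab <- table(factor(x$states, levels = c(STATES, "MISSING")))
  cat("  states: ", paste(sprintf("%s %.1f%%", names(tab),
                                  100 * tab / sum(tab)), collapse = "  "), "\n")
  if (!is.null(x$is_msl))
    cat(sprintf("  MSL: %d (%.1f%%), of which polymorphic: %d (%.1f%%)\n",
                x$counts$n_msl, x$counts$pct_msl,
                x$counts$n_polymorphic_msl, x$counts$pct_polymorphic_of_msl))
  invisible(x)
}

#' @export
dim.state_matrix <- function(x) dim(x$states)

#' Encode a state matrix numerically for multivariate analysis
#'
#' Only methylation-susceptible loci are encoded. `METH_BINARY` scores 1 for
#' any methylated state (HMM, ICM, HPM) and 0 for NMT; `ONEHOT4` expands each
#' locus into four indicator columns in the fixed order NMT, HMM, ICM, HPM.
#' MISSING cells are imputed with the feature-wise mean of scored samples;
#' the imputed count is recorded in `attr(, "n_imputed")`.
#'
#' @param sm a `state_matrix` with the MSL partition computed.
#' @param scheme `"METH_BINARY"` (default) or `"ONEHOT4"`.
#' @param polymorphic_only restrict to polymorphic MSL (as used for
#'   ordination and DAPC); default FALSE encodes all MSL.
#' @return numeric matrix, samples x features.
#' @export
encode_matrix <- function(sm, scheme = c("METH_BINARY", "ONEHOT4"),
                          polymorphic_only = FALSE) {
  stopifnot(inherits(sm, "state_matrix"))
  if (is.null(sm$is_msl))
    stopf("run partition_msl() before encode_matrix()")
  scheme <- match.arg(scheme)
  keep <- sm$is_msl
  if (polymorphic_only) keep <- keep & sm$is_polymorphic
  st <- sm$states[, keep, drop = FALSE]
  if (scheme == "METH_BINARY") {
    x <- matrix(NA_real_, nrow(st), ncol(st), dimnames = dimnames(st))
    x[st %in% c("HMM", "ICM", "HPM")] <- 1
    x[st == "NMT"] <- 0
  } else {
    cols <- as.vector(t(outer(colnames(st), STATES, paste, sep = ".")))
    x <- matrix(NA_real_, nrow(st), 4L * ncol(st),
                dimnames = list(rownames(st), cols))
    for (k in seq_along(STATES)) {
      sub <- matrix(NA_real_, nrow(st), ncol(st))
      sub[st != "MISSING"] <- as.numeric(st[st != "MISSING"] == STATES[k])
      x[, seq(k, ncol(x), by = 4L)] <- sub
    }
  }
  n_imp <- sum(is.na(x))
  if (n_imp) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  attr(x, "scheme") <- scheme
  attr(x, "n_imputed") <- n_imp
  x
}

#' Write / read a state matrix as CSV
#'
#' The CSV holds one sample per row (`sample_id` column then one column per
#' locus with the state label); MSL/polymorphism flags travel in two extra
#' header-like rows tagged `.is_msl` / `.is_polymorphic`.
#'
#' @param sm a `state_matrix`.
#' @param path CSV path.
#' @return `path` invisibly for the writer, a `state_matrix` for the reader.
#' @export
write_state_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "state_matrix"))
  df <- data.frame(sample_id = sm$samples, sm$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(sm$is_msl)) {
    df <- rbind(c(".is_msl", as.integer(sm$is_msl)),
                c(".is_polymorphic", as.integer(sm$is_polymorphic)),
                df)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path) {
  raw <- read_delim_auto(path)
  if (!"sample_id" %in% names(raw)) stopf("missing 'sample_id' column")
  flags <- raw$sample_id %in% c(".is_msl", ".is_polymorphic")
  body <- raw[!flags, , drop = FALSE]
  st <- as.matrix(body[, -1, drop = FALSE])
  rownames(st) <- as.character(body$sample_id)
  if (!all(st %in% c(STATES, "MISSING")))
    stopf("invalid state labels in '%s'", path)
  sm <- structure(list(states = st, samples = rownames(st),
                       loci = colnames(st), is_msl = NULL,
                       is_polymorphic = NULL, meth_threshold = NA_real_),
                  class = "state_matrix")
  if (any(flags)) {
    get_flag <- function(tag) {
      v <- as.logical(as.integer(raw[raw$sample_id == tag, -1]))
      names(v) <- colnames(st)
      v
    }
    sm$is_msl <- get_flag(".is_msl")
    sm$is_polymorphic <- get_flag(".is_polymorphic")
    n_msl <- sum(sm$is_msl); n_poly <- sum(sm$is_msl & sm$is_polymorphic)
    sm$counts <- list(n_loci = ncol(st), n_msl = n_msl,
                      n_polymorphic_msl = n_poly,
                      pct_msl = 100 * n_msl / max(ncol(st), 1L),
                      pct_polymorphic_of_msl =
                        if (n_msl) 100 * n_poly / n_msl else NA_real_)
  }
  sm
}
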