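# Epigenetic heterogeneity: Shannon diversity over methylation-state
# frequencies at methylation-susceptible loci, and grouped state-frequency
# profiles.

#' Shannon diversity of methylation states
#'
#' For each methylation-susceptible locus, computes the Shannon index
#' H = -sum(p_s log p_s) over the four state frequencies (NMT, HMM, ICM,
#' HPM) among scored samples, in nats by default, so 0 <= H <= log(4).
#' Reports the per-locus values with their mean and SD across loci; a
#' sample-wise reduction (H over states within each sample, across loci)
#' is available via `by = "sample"`.
#'
#' @param sm a `state_matrix` with the MSL partition computed.
#' @param base logarithm base; default `exp(1)` (nats).
#' @param by aggregate over `"locus"` (default) or `"sample"`.
#' @return a `diversity_report`: `H` (named vector), `mean_H`, `sd_H`,
#'   `n_loci` (or `n_samples`).
#' @export
shannon_diversity <- function(sm, base = exp(1), by = c("locus", "sample")) {
  stopifnot(inherits(sm, "state_matrix"))
  if (is.null(sm$is_msl)) stopf("run partition_msl() before shannon_diversity()")
  by <- match.arg(by)
  st <- sm$states[, sm$is_msl, drop = FALSE]
  H_of <- function(s) {
    s <- s[s != "MISSING"]
    if (length(s) < 2L) return(NA_real_)
    p <- table(factor(s, levels = STATES)) / length(s)
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  }
  H <- if (by == "locus") apply(st, 2L, H_of) else apply(st, 1L, H_of)
  if (anyNA(H)) {
    warnf("%d %s(es/i) with < 2 scored entries excluded from H", sum(is.na(H)), by)
    H <- H[!is.na(H)]
  }
  structure(list(H = H, mean_H = mean(H), sd_H = stats::sd(H),
                 n_loci = if (by == "locus") length(H) else NA_integer_,
                 n_samples = if (by == "sample") length(H) else NA_integer_,
                 by = by, base = base),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  n <- if (x$by == "locus") x$n_loci else x$n_samples
  cat(sprintf("Shannon diversity over methylation states (%s-wise, n = %d)\n",
              x$by, n))
  cat(sprintf("  mean +/- SD: %.3f +/- %.3f  (max possible %.3f)\n",
              x$mean_H, x$sd_H, log(4, base = x$base)))
  invisible(x)
}

#' Methylation-state frequency profiles by group
#'
#' For each level of a grouping factor, the mean fraction of each
#' methylation state across loci (scored cells only; the four fractions sum
#' to 1 per group) with the standard error across loci, as plotted in
#' state-distribution bar charts.
#'
#' @param sm a `state_matrix` (MSL partition computed; frequencies use
#'   polymorphic MSL, the usual plotting substrate).
#' @param groups factor of length `nrow(sm)` (one level per sample), e.g.
#'   season or transplant status; `NULL` treats all samples as one group.
#' @param polymorphic_only restrict to polymorphic MSL; default TRUE.
#' @return data frame with columns `group`, `state`, `fraction`, `se`.
#' @export
state_frequencies <- function(sm, groups = NULL, polymorphic_only = TRUE) {
  stopifnot(inherits(sm, "state_matrix"))
  if (is.null(sm$is_msl)) stopf("run partition_msl() before state_frequencies()")
  keep <- sm$is_msl
  if (polymorphic_only) keep <- keep & sm$is_polymorphic
  st <- sm$states[, keep, drop = FALSE]
  if (is.null(groups)) groups <- factor(rep("all", nrow(st)))
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(st))
  out <- NULL
  for (g in levels(groups)) {
    sub <- st[groups == g, , drop = FALSE]
    if (nrow(sub) == 0L) { warnf("empty group '%s' excluded", g); next }
    # per-locus state fractions among scored cells
    frac_l <- vapply(seq_len(ncol(sub)), function(j) {
      s <- sub[, j]; s <- s[s != "MISSING"]
      if (!length(s)) return(rep(NA_real_, 4L))
      as.numeric(table(factor(s, levels = STATES)) / length(s))
    }, numeric(4L))
    mu <- rowMeans(frac_l, na.rm = TRUE)
    mu <- mu / sum(mu)                       # renormalize over loci means
    se <- apply(frac_l, 1L, stats::sd, na.rm = TRUE) /
      sqrt(rowSums(!is.na(frac_l)))
    out <- rbind(out, data.frame(group = g, state = STATES,
                                 fraction = mu, se = se,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
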