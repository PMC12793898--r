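# Phenotype-epigenotype plasticity coupling: for paired sample groups
# (e.g. the same site in the dry vs. wet season), the Euclidean distance
# between their centroids in PCoA methylation space is set against the
# absolute difference of their mean log(x+1) righting times, and the two
# distance lists are rank-correlated.

#' Phenotype-epigenotype plasticity coupling
#'
#' Builds group centroids in the epigenetic ordination (first `n_axes`
#' axes), computes for each group pair the Euclidean centroid distance
#' (epigenetic plasticity) and the absolute difference of mean log(x+1)
#' righting time (phenotypic plasticity), and rank-correlates the two with
#' Spearman's rho (exact permutation p for up to 8 pairs, t-approximation
#' otherwise).
#'
#' @param epi_ord an `ordination` of the methylation data (typically
#'   [pcoa()] output), rows in sample order.
#' @param pheno phenotype table with `sample_id` and `righting_time` (s).
#' @param meta sample metadata with `sample_id`, `site` and `season` and/or
#'   `status`; rows of `epi_ord$points` are matched by `sample_id` when
#'   rownames are present, else by position.
#' @param pairing
#'   `"within_site_across_season"`: one pair per site (dry vs wet centroid);
#'   `"across_status"`: all status-level pairs within each site;
#'   `"all_pairs"`: every pair of site-by-timepoint groups (site
#'   combination centroids).
#' @param n_axes leading ordination axes used for centroids; default all
#'   positive axes.
#' @param multivariate_phenotype also include log(x+1) test diameter in the
#'   phenotype distance (Euclidean over both traits); default FALSE
#'   (righting only).
#' @return a `plasticity_coupling` object: `pairs` data frame (pair id,
#'   `epi_dist`, `pheno_dist`), `rho`, `p`, `n_pairs`, and
#'   `insufficient = TRUE` with `rho = NA` when fewer than 3 pairs exist.
#' @export
plasticity_coupling <- function(epi_ord, pheno, meta,
                                pairing = c("within_site_across_season",
                                            "across_status", "all_pairs"),
                                n_axes = NULL,
                                multivariate_phenotype = FALSE) {
  pairing <- match.arg(pairing)
  pts <- epi_ord$points
  stopifnot(nrow(pts) == nrow(meta))
  if (!is.null(rownames(pts)) && all(rownames(pts) %in% meta$sample_id))
    meta <- meta[match(rownames(pts), meta$sample_id), , drop = FALSE]
  if (!is.null(n_axes)) pts <- pts[, seq_len(min(n_axes, ncol(pts))), drop = FALSE]
  ph <- pheno[match(meta$sample_id, pheno$sample_id), , drop = FALSE]
  if (anyNA(ph$righting_time)) stopf("righting_time missing for some samples")
  lrt <- log1p(ph$righting_time)
  ptraits <- cbind(righting = lrt)
  if (multivariate_phenotype)
    ptraits <- cbind(ptraits, diameter = log1p(ph$test_diameter))

  grp <- switch(pairing,
    within_site_across_season = ,
    all_pairs = interaction(meta$site, meta$season, drop = TRUE, sep = ":"),
    across_status = interaction(meta$site, meta$status, drop = TRUE, sep = ":"))
  sizes <- table(grp)
  if (any(sizes < 2L))
    stopf("every group needs >= 2 samples (too small: %s)",
          paste(names(sizes)[sizes < 2L], collapse = ", "))

  cent_epi <- rowsum(pts, grp) / as.vector(sizes)
  cent_phe <- rowsum(ptraits, grp) / as.vector(sizes)
  gl <- rownames(cent_epi)
  part <- do.call(rbind, strsplit(gl, ":", fixed = TRUE))
  pair_rows <- switch(pairing,
    within_site_across_season = {
      idx <- NULL
      for (s in unique(part[, 1L])) {
        i <- which(part[, 1L] == s)
        if (length(i) == 2L) idx <- rbind(idx, i)
      }
      idx
    },
    across_status = {
      idx <- NULL
      for (s in unique(part[, 1L])) {
        i <- which(part[, 1L] == s)
        if (length(i) >= 2L) idx <- rbind(idx, t(utils::combn(i, 2L)))
      }
      idx
    },
    all_pairs = t(utils::combn(length(gl), 2L)))
  n_pairs <- NROW(pair_rows)
  if (n_pairs < 3L) {
    warnf("only %d group pair(s); rho undefined", n_pairs)
    return(structure(list(pairs = NULL, rho = NA_real_, p = NA_real_,
                          n_pairs = n_pairs, insufficient = TRUE,
                          pairing = pairing),
                     class = "plasticity_coupling"))
  }
  epi_d <- sqrt(rowSums((cent_epi[pair_rows[, 1L], , drop = FALSE] -
                         cent_epi[pair_rows[, 2L], , drop = FALSE])^2))
  phe_d <- sqrt(rowSums((cent_phe[pair_rows[, 1L], , drop = FALSE] -
                         cent_phe[pair_rows[, 2L], , drop = FALSE])^2))
  pairs <- data.frame(pair = paste(gl[pair_rows[, 1L]], gl[pair_rows[, 2L]],
                                   sep = " vs "),
                      epi_dist = epi_d, pheno_dist = phe_d,
                      stringsAsFactors = FALSE)
  ct <- spearman_corr(epi_d, phe_d)
  structure(list(pairs = pairs, rho = ct$rho, p = ct$p, n_pairs = n_pairs,
                 insufficient = FALSE, pairing = pairing,
                 p_method = ct$method),
            class = "plasticity_coupling")
}

#' @export
print.plasticity_coupling <- function(x, ...) {
  cat(sprintf("plasticity coupling (%s): %d group pairs\n", x$pairing, x$n_pairs))
  if (isTRUE(x$insufficient)) {
    cat("  too few pairs; rho undefined\n")
  } else {
    cat(sprintf("  Spearman rho = %.3f, p = %.4g (%s)\n", x$rho, x$p, x$p_method))
  }
  invisible(x)
}

#' @export
plot.plasticity_coupling <- function(x, ...) {
  if (isTRUE(x$insufficient)) stopf("nothing to plot: too few pairs")
  graphics::plot(x$pairs$epi_dist, x$pairs$pheno_dist, pch = 19,
                 xlab = "epigenetic centroid distance",
                 ylab = "phenotype centroid distance (log s)", ...)
  graphics::abline(stats::lm(pheno_dist ~ epi_dist, data = x$pairs), lty = 2)
  invisible(x)
}
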