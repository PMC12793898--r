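# Discriminant analysis of principal components (DAPC): a PCA reduction
# followed by linear discriminant axes maximizing the between/within group
# variance ratio, with feature loadings back-projected through the PCA
# rotation so loci can be ranked by their group-discriminating contribution.

#' Fit a DAPC model
#'
#' Reduces `x` to `n_pc` principal components, then finds `n_da` linear
#' discriminant axes from the generalized eigenproblem of the between- and
#' within-group scatter of the PC scores. A singular within-group scatter is
#' ridge-stabilized with a warning. Per convention, `n_pc` defaults to the
#' number of groups minus one and two discriminant axes are retained.
#'
#' Feature loadings are back-projected (`rotation %*% discriminant
#' directions`) and reported as squared, axis-wise normalized contributions
#' summing to 1 per axis, which makes the percentile selection rule of
#' [select_influential()] scale-free.
#'
#' @param x numeric matrix, samples x features (centred internally).
#' @param groups a priori grouping factor (>= 2 levels); unsupervised
#'   cluster detection is out of scope.
#' @param n_pc number of principal components retained; default
#'   `nlevels(groups) - 1`.
#' @param n_da number of discriminant axes; default
#'   `min(2, n_pc, nlevels(groups) - 1)`.
#' @return a `dapc_fit`: `scores` (samples x DA axes), `loadings`
#'   (features x DA axes, squared normalized contributions), `raw_loadings`,
#'   `groups`, `assigned` (nearest-centroid assignment), `separation`
#'   (between/within variance ratio on axis 1), `n_pc`, `n_da`.
#' @export
fit_dapc <- function(x, groups, n_pc = NULL, n_da = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stopf("need >= 2 groups")
  stopifnot(length(groups) == nrow(x))
  n <- nrow(x)
  n_pc <- as.integer(n_pc %||% (k - 1L))
  if (n_pc < 1L) stopf("n_pc must be >= 1")
  if (n_pc >= n) stopf("n_pc (%d) must be < sample count (%d)", n_pc, n)
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, sum(pca$sdev > 1e-10))
  n_da <- as.integer(n_da %||% min(2L, n_pc, k - 1L))
  n_da <- min(n_da, n_pc, k - 1L)
  S <- pca$x[, seq_len(n_pc), drop = FALSE]

  m_all <- colMeans(S)
  W <- matrix(0, n_pc, n_pc); B <- matrix(0, n_pc, n_pc)
  for (g in levels(groups)) {
    i <- which(groups == g)
    mg <- colMeans(S[i, , drop = FALSE])
    cs <- sweep(S[i, , drop = FALSE], 2L, mg)
    W <- W + crossprod(cs)
    B <- B + length(i) * tcrossprod(mg - m_all)
  }
  W <- W / (n - k); B <- B / (k - 1L)
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) {
    warnf("singular within-group scatter; ridge-stabilized")
    W <- W + diag(1e-6 * mean(diag(W)) + 1e-12, n_pc)
    R <- chol(W)
  }
  # solve W^-1 B via whitening: M = R'^-1 B R^-1 (symmetric)
  M <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  A <- backsolve(R, eg$vectors[, seq_len(n_da), drop = FALSE])
  colnames(A) <- paste0("DA", seq_len(n_da))

  scores <- S %*% A
  rownames(scores) <- rownames(x)
  raw_load <- pca$rotation[, seq_len(n_pc), drop = FALSE] %*% A
  contrib <- raw_load^2
  contrib <- sweep(contrib, 2L, colSums(contrib), "/")
  cent <- rowsum(scores, groups) / as.vector(table(groups))
  d2 <- outer(rowSums(scores^2), rowSums(cent^2), "+") -
    2 * scores %*% t(cent)
  assigned <- factor(levels(groups)[max.col(-d2)], levels = levels(groups))
  structure(list(scores = scores, loadings = contrib,
                 raw_loadings = raw_load, groups = groups,
                 assigned = assigned,
                 separation = eg$values[1L],
                 eigenvalues = eg$values[seq_len(n_da)],
                 n_pc = n_pc, n_da = n_da, pca = pca),
            class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat(sprintf("DAPC: %d groups, %d PCs retained, %d discriminant axes\n",
              nlevels(x$groups), x$n_pc, x$n_da))
  cat(sprintf("  axis-1 between/within ratio: %.3f\n", x$separation))
  cat(sprintf("  reassignment accuracy: %.1f%%\n",
              100 * mean(x$assigned == x$groups)))
  invisible(x)
}

#' @export
plot.dapc_fit <- function(x, ...) {
  if (x$n_da >= 2L) {
    graphics::plot(x$scores[, 1:2], col = as.integer(x$groups), pch = 19,
                   xlab = "DA1", ylab = "DA2", ...)
  } else {
    d <- stats::density(x$scores[, 1])
    graphics::plot(d, main = "DA1 scores", ...)
  }
  invisible(x)
}

#' Select influential loci from DAPC loadings
#'
#' Influential loci are those whose maximum per-axis loading contribution
#' reaches the given empirical percentile of all loci (ties at the threshold
#' are all included). An alternative threshold-free rule selects loci whose
#' contribution exceeds the mean contribution.
#'
#' @param fit a `dapc_fit`.
#' @param percentile percentile threshold in (0, 1); default 0.90.
#' @param rule `"percentile"` (default) or `"above_mean"`.
#' @return an `influential_loci` list: `loci` (character), `scores` (max
#'   per-axis contribution for every feature), `threshold`, `n`, `fraction`.
#' @export
select_influential <- function(fit, percentile = 0.90,
                               rule = c("percentile", "above_mean")) {
  stopifnot(inherits(fit, "dapc_fit"), percentile > 0, percentile < 1)
  rule <- match.arg(rule)
  scores <- apply(fit$loadings, 1L, max)
  if (length(scores) < 10L)
    warnf("fewer than 10 features; percentile selection is coarse")
  thr <- if (rule == "percentile") {
    stats::quantile(scores, percentile, names = FALSE)
  } else mean(scores)
  sel <- scores >= thr - 1e-15
  structure(list(loci = names(scores)[sel], scores = scores,
                 threshold = thr, rule = rule, percentile = percentile,
                 n = sum(sel), fraction = mean(sel)),
            class = "influential_loci")
}

#' @export
print.influential_loci <- function(x, ...) {
  cat(sprintf("influential loci (%s rule): %d of %d (%.1f%%), threshold %.4g\n",
              x$rule, x$n, length(x$scores), 100 * x$fraction, x$threshold))
  invisible(x)
}
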