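# Distance-based multivariate statistics, implemented from the Gower
# centering identities rather than delegated: with A = -d^2/2 and
# G = (I - 11'/n) A (I - 11'/n), the total sum of squares is tr(G) and the
# sum of squares explained by a model with hat matrix H is tr(H G). All
# permutation tests use free exchange of sample labels and report
# p = (1 + #{stat_perm >= stat_obs}) / (1 + n_perm).

#' Validate / coerce a distance matrix
#'
#' Accepts a `dist` object or a square matrix; checks symmetry, zero
#' diagonal, non-negativity and finiteness.
#'
#' @param d `dist` or square numeric matrix.
#' @return symmetric matrix with `samples` attribute.
#' @export
as_distance_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
  if (!all(is.finite(m))) stopf("distance matrix has non-finite entries")
  if (any(m < 0)) stopf("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) stopf("distance matrix must be symmetric")
  if (max(abs(diag(m))) > 1e-8) stopf("distance matrix diagonal must be zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  m
}

#' Pairwise sample distances
#'
#' @param x numeric matrix, samples in rows; binary metrics require 0/1
#'   entries.
#' @param metric `"EUCLIDEAN"` (default), `"JACCARD"` (1 - intersection /
#'   union over asymmetric binary features) or `"SIMPLE_MATCHING"`
#'   (fraction of mismatching features).
#' @return symmetric distance matrix (see [as_distance_matrix()]).
#' @export
pairwise_distances <- function(x, metric = c("EUCLIDEAN", "JACCARD",
                                             "SIMPLE_MATCHING")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (any(rowSums(!is.na(x)) == 0L)) stopf("all-missing row in input")
  d <- switch(metric,
    EUCLIDEAN = stats::dist(x),
    JACCARD = {
      if (!is_binary(x)) stopf("JACCARD requires binary (0/1) input")
      stats::dist(x, method = "binary")
    },
    SIMPLE_MATCHING = {
      if (!is_binary(x)) stopf("SIMPLE_MATCHING requires binary (0/1) input")
      n <- ncol(x)
      stats::dist(x, method = "manhattan") / n
    })
  as_distance_matrix(d)
}

# Gower-centered inner-product matrix of squared distances.
gower_center <- function(D) {
  A <- -0.5 * D * D
  n <- nrow(A)
  rm_ <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1L, rm_), 2L, rm_) + gm
}

# Hat matrix of a model matrix via QR (rank aware).
hat_matrix <- function(X) {
  qr_ <- qr(X)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  tcrossprod(Q)
}

# Build the sequential (Type I) projector list for a RHS formula.
sequential_projectors <- function(formula, data) {
  tl <- attr(stats::terms(formula), "term.labels")
  if (!length(tl)) stopf("formula has no terms")
  n <- nrow(data)
  for (v in all.vars(formula)) {
    if (!v %in% names(data)) stopf("term variable '%s' not in data", v)
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L)
      stopf("term '%s' has a single level", v)
  }
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  P <- list(); dfs <- integer()
  for (j in seq_along(tl)) {
    X <- stats::model.matrix(stats::reformulate(tl[seq_len(j)]), data)
    qr_ <- qr(X)
    H <- hat_matrix(X)
    df <- qr_$rank - rank_prev
    if (df == 0L) warnf("term '%s' adds no rank (collinear); df = 0", tl[j])
    P[[tl[j]]] <- H - H_prev
    dfs[j] <- df
    H_prev <- H; rank_prev <- qr_$rank
  }
  list(P = P, df = dfs, H_full = H_prev, df_model = rank_prev - 1L,
       terms = tl)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared distances among sequential (Type I)
#' model terms using the Gower-centered inner-product identity, and tests
#' each term's pseudo-F by free permutation of sample labels.
#'
#' @param d distance matrix or `dist` (samples in the order of `data` rows).
#' @param formula right-hand-side formula of factors/covariates, e.g.
#'   `~ site + season`; terms are tested sequentially in the given order.
#' @param data data frame holding the term variables, one row per sample.
#' @param permutations number of random label permutations (default 999), or
#'   `"exhaustive"` to enumerate all `n!` label orders (n <= 9); exhaustive
#'   p-values include the identity and equal the enumeration over distinct
#'   group splits.
#' @param seed optional integer seed for the permutation stream.
#' @return a `permanova` object: per-term SS, df, R2, pseudo-F and p, plus
#'   residual and total rows. Term and residual R2 sum to 1.
#' @examples
#' x <- matrix(rnorm(40), 20)
#' g <- data.frame(grp = rep(c("a", "b"), each = 10))
#' permanova(pairwise_distances(x), ~ grp, g, permutations = 99, seed = 1)
#' @export
permanova <- function(d, formula, data, permutations = 999, seed = NULL) {
  D <- as_distance_matrix(d)
  n <- nrow(D)
  stopifnot(nrow(data) == n)
  G <- gower_center(D)
  sp <- sequential_projectors(formula, data)
  k <- length(sp$P)
  SS_total <- sum(diag(G))
  SS_terms <- vapply(sp$P, function(P) sum(P * G), numeric(1))
  df_terms <- sp$df
  df_res <- n - 1L - sp$df_model
  SS_res <- SS_total - sum(SS_terms)
  if (df_res <= 0L) stopf("no residual degrees of freedom")
  F_obs <- (SS_terms / pmax(df_terms, 1L)) / (SS_res / df_res)
  F_obs[df_terms == 0L] <- NA_real_

  perm_F <- function(idx) {
    Gp <- G[idx, idx]
    ss <- vapply(sp$P, function(P) sum(P * Gp), numeric(1))
    (ss / pmax(df_terms, 1L)) / ((SS_total - sum(ss)) / df_res)
  }
  exhaustive <- identical(permutations, "exhaustive")
  if (exhaustive) {
    if (n > 9L) stopf("exhaustive permutation limited to n <= 9")
    perms <- all_perms(n)
    Fp <- apply(perms, 1L, perm_F)
    Fp <- matrix(Fp, nrow = k)
    p <- rowMeans(Fp >= F_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    n_perm <- as.integer(permutations)
    if (is.na(n_perm) || n_perm < 1L) stopf("permutations must be >= 1")
    count <- numeric(k)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        Fp <- perm_F(sample.int(n))
        count <- count + (Fp >= F_obs - 1e-12)
      }
    })
    p <- (1 + count) / (1 + n_perm)
  }
  tab <- data.frame(
    term = c(sp$terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    SS = c(SS_terms, SS_res, SS_total),
    R2 = c(SS_terms, SS_res, SS_total) / SS_total,
    F = c(F_obs, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(aov_table = tab, n = n, n_perm = n_perm,
                 exhaustive = exhaustive, seed = seed,
                 formula = formula),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %s permutations of sample labels)\n",
              if (x$exhaustive) sprintf("exhaustive %d", x$n_perm) else x$n_perm))
  tab <- x$aov_table
  tab$SS <- signif(tab$SS, 6); tab$R2 <- signif(tab$R2, 4)
  tab$F <- signif(tab$F, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates (keeping negative
#' eigenvalue axes as the imaginary part), computes each sample's distance
#' to its group centroid as sqrt(real part - imaginary part) of the squared
#' centroid distance, and tests the one-way F statistic on those distances
#' by permutation.
#'
#' @param d distance matrix or `dist`.
#' @param groups grouping factor; groups of size 1 are excluded with a
#'   warning.
#' @param permutations number of permutations of the dispersion distances
#'   (default 999).
#' @param seed optional integer seed.
#' @return a `permdisp` object with `F`, `p`, and per-sample `distances`.
#' @export
permdisp <- function(d, groups, permutations = 999, seed = NULL) {
  D <- as_distance_matrix(d)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(D))
  small <- names(which(table(groups) < 2L))
  if (length(small)) {
    warnf("excluding size-1 group(s): %s", paste(small, collapse = ", "))
    keep <- !groups %in% small
    D <- D[keep, keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stopf("need >= 2 groups of size >= 2")
  G <- gower_center(D)
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > 1e-8 * max(abs(eg$values))
  neg <- eg$values < -1e-8 * max(abs(eg$values))
  Cr <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), sum(pos))
  Ci <- eg$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eg$values[neg]), sum(neg))
  z <- numeric(nrow(D))
  for (g in levels(groups)) {
    i <- which(groups == g)
    cr <- colMeans(Cr[i, , drop = FALSE])
    ci <- if (ncol(Ci)) colMeans(Ci[i, , drop = FALSE]) else numeric(0)
    d2r <- rowSums(sweep(Cr[i, , drop = FALSE], 2L, cr)^2)
    d2i <- if (ncol(Ci)) rowSums(sweep(Ci[i, , drop = FALSE], 2L, ci)^2) else 0
    z[i] <- sqrt(pmax(d2r - d2i, 0))
  }
  f_stat <- function(z, g) {
    m <- tapply(z, g, mean); nG <- table(g)
    ssb <- sum(nG * (m - mean(z))^2)
    ssw <- sum((z - m[g])^2)
    (ssb / (nlevels(g) - 1L)) / (ssw / (length(z) - nlevels(g)))
  }
  F_obs <- f_stat(z, groups)
  n_perm <- as.integer(permutations)
  count <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (f_stat(z[sample.int(length(z))], groups) >= F_obs - 1e-12)
        count <- count + 1L
    }
  })
  structure(list(F = F_obs, p = (1 + count) / (1 + n_perm),
                 distances = stats::setNames(z, rownames(D)),
                 groups = groups, n_perm = n_perm, seed = seed),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.4g, p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_perm))
  print(signif(tapply(x$distances, x$groups, mean), 4))
  invisible(x)
}

#' Principal coordinates analysis (PCoA)
#'
#' Eigendecomposition of the Gower-centered matrix of squared distances.
#' Axes are ordered by decreasing eigenvalue; explained fractions are
#' relative to the sum of retained positive eigenvalues. Negative
#' eigenvalues (non-Euclidean distances) are dropped by default; the
#' Lingoes additive correction is available.
#'
#' @param d distance matrix or `dist`.
#' @param correction `"DROP_NEGATIVE"` (default), `"NONE"` (identical
#'   coordinates, but all eigenvalues reported) or `"LINGOES"`.
#' @return an `ordination` object: `points` (samples x axes, centred at the
#'   origin), `eigenvalues`, `explained`, `kind = "PCOA"`.
#' @export
pcoa <- function(d, correction = c("DROP_NEGATIVE", "NONE", "LINGOES")) {
  correction <- match.arg(correction)
  D <- as_distance_matrix(d)
  if (all(D == 0)) {
    warnf("all-zero distance matrix: zero coordinates")
    pts <- matrix(0, nrow(D), 1L, dimnames = list(rownames(D), "PCo1"))
    return(structure(list(points = pts, eigenvalues = 0, explained = 0,
                          kind = "PCOA", correction = correction),
                     class = "ordination"))
  }
  G <- gower_center(D)
  eg <- eigen(G, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eg$values))
  if (correction == "LINGOES" && min(eg$values) < -tol) {
    cc <- -min(eg$values)
    D2 <- sqrt(D^2 + 2 * cc); diag(D2) <- 0
    G <- gower_center(D2)
    eg <- eigen(G, symmetric = TRUE)
    tol <- 1e-8 * max(abs(eg$values))
  }
  pos <- which(eg$values > tol)
  lam <- eg$values[pos]
  pts <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), length(pos))
  dimnames(pts) <- list(rownames(D), paste0("PCo", seq_along(pos)))
  structure(list(points = pts, eigenvalues = eg$values,
                 positive_eigenvalues = lam,
                 explained = lam / sum(lam),
                 kind = "PCOA", correction = correction),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n",
              x$kind, nrow(x$points), ncol(x$points)))
  k <- min(5L, ncol(x$points))
  cat("  explained:", paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]),
                            collapse = " "), "\n")
  if (!is.null(x$constrained_fraction))
    cat(sprintf("  constrained fraction: %.3f (p = %.4g)\n",
                x$constrained_fraction, x$p_overall))
  invisible(x)
}

#' @export
plot.ordination <- function(x, axes = c(1, 2), groups = NULL, ...) {
  a <- x$points[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1L else as.integer(as.factor(groups))
  graphics::plot(a, col = col, pch = 19,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1], 100 * x$explained[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2], 100 * x$explained[axes[2]]),
                 ...)
  invisible(x)
}

#' Sequential RDA variance partitioning
#'
#' Partitions the total variance of a centred multivariate response among
#' ordered model terms by sequential least-squares projection, as used to
#' quantify the separate and combined influence of site and season.
#'
#' @param y numeric response matrix (samples x variables); centred
#'   column-wise internally.
#' @param formula RHS formula of terms in testing order.
#' @param data data frame with the term variables.
#' @return a named list: per-term explained fractions, `combined`, and
#'   `residual`.
#' @export
rda_partition <- function(y, formula, data) {
  y <- as.matrix(y)
  y <- sweep(y, 2L, colMeans(y))
  sp <- sequential_projectors(formula, data)
  SS_total <- sum(y^2)
  if (SS_total == 0) stopf("response has zero variance")
  fr <- vapply(sp$P, function(P) sum((P %*% y)^2), numeric(1)) / SS_total
  c(as.list(fr), combined = sum(fr), residual = 1 - sum(fr))
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' RDA of the principal-coordinate embedding (positive-eigenvalue axes) on a
#' table of predictors: the constrained fraction is constrained inertia over
#' total inertia, with overall and sequential per-predictor significance by
#' permutation.
#'
#' @param d distance matrix or `dist`.
#' @param predictors data frame of predictors (numeric or factors), one row
#'   per sample, complete; zero-variance predictors are an error.
#' @param permutations number of permutations (default 999).
#' @param seed optional integer seed.
#' @param method `"labels"` permutes predictor rows (default);
#'   `"residuals"` permutes reduced-model residuals for term tests.
#' @return an `ordination` of kind `"DBRDA"` with constrained axes, plus
#'   `constrained_fraction`, `p_overall` and `term_table` (sequential F and
#'   p per predictor).
#' @export
dbrda <- function(d, predictors, permutations = 999, seed = NULL,
                  method = c("labels", "residuals")) {
  method <- match.arg(method)
  D <- as_distance_matrix(d)
  n <- nrow(D)
  predictors <- as.data.frame(predictors)
  stopifnot(nrow(predictors) == n)
  for (v in names(predictors)) {
    pv <- predictors[[v]]
    if (anyNA(pv)) stopf("predictor '%s' has missing values", v)
    if (is.character(pv)) predictors[[v]] <- pv <- factor(pv)
    bad <- if (is.factor(pv)) nlevels(droplevels(pv)) < 2L else
      stats::var(pv) == 0
    if (bad) stopf("zero-variance predictor: '%s'", v)
  }
  ord <- pcoa(D)
  Y <- ord$points                      # centred; total inertia = sum(Y^2)
  total <- sum(Y^2)
  form <- stats::reformulate(names(predictors))
  X <- stats::model.matrix(form, predictors)
  qr_ <- qr(X)
  q <- qr_$rank - 1L
  if (q < 1L) stopf("predictors add no rank")
  if (n - q - 1L <= 0L) stopf("too few samples for %d predictor df", q)
  H <- hat_matrix(X)
  fit <- H %*% Y
  constrained <- sum(fit^2)
  F_obs <- (constrained / q) / ((total - constrained) / (n - q - 1L))

  # overall test: permute rows of Y (equivalently, sample labels)
  n_perm <- as.integer(permutations)
  count <- 0L
  sp <- sequential_projectors(form, predictors)
  SS_terms <- vapply(sp$P, function(P) sum((P %*% Y)^2), numeric(1))
  df_terms <- sp$df
  SS_res <- total - sum(SS_terms)
  df_res <- n - 1L - sp$df_model
  F_terms <- (SS_terms / pmax(df_terms, 1L)) / (SS_res / df_res)
  count_t <- numeric(length(F_terms))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      Yp <- Y[idx, , drop = FALSE]
      cp <- sum((H %*% Yp)^2)
      if ((cp / q) / ((total - cp) / (n - q - 1L)) >= F_obs - 1e-12)
        count <- count + 1L
      ssp <- vapply(sp$P, function(P) sum((P %*% Yp)^2), numeric(1))
      Fp <- (ssp / pmax(df_terms, 1L)) / ((total - sum(ssp)) / df_res)
      count_t <- count_t + (Fp >= F_terms - 1e-12)
    }
  })
  p_overall <- (1 + count) / (1 + n_perm)
  p_terms <- (1 + count_t) / (1 + n_perm)

  sv <- svd(fit)
  keep <- sv$d^2 > 1e-10 * max(sv$d^2, 1e-300)
  pts <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  dimnames(pts) <- list(rownames(D), paste0("dbRDA", seq_len(sum(keep))))
  structure(list(points = pts,
                 eigenvalues = sv$d[keep]^2,
                 explained = sv$d[keep]^2 / total,
                 kind = "DBRDA",
                 constrained_fraction = constrained / total,
                 F = F_obs, p_overall = p_overall,
                 term_table = data.frame(term = sp$terms, df = df_terms,
                                         F = F_terms, p = p_terms,
                                         stringsAsFactors = FALSE),
                 n_perm = n_perm, seed = seed, method = method),
            class = "ordination")
}

#' Group centroids in ordination space
#'
#' @param ord an `ordination` (or any object with a `points` matrix).
#' @param groups factor over samples; empty levels are omitted with a
#'   warning.
#' @param n_axes number of leading axes to use (default: all).
#' @return matrix of centroids, groups x axes (arithmetic means).
#' @export
group_centroids <- function(ord, groups, n_axes = NULL) {
  pts <- if (is.list(ord)) ord$points else as.matrix(ord)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(pts))
  if (any(table(groups) == 0L)) {
    warnf("empty group level(s) omitted: %s",
          paste(names(which(table(groups) == 0L)), collapse = ", "))
    groups <- droplevels(groups)
  }
  if (!is.null(n_axes)) pts <- pts[, seq_len(min(n_axes, ncol(pts))), drop = FALSE]
  cent <- rowsum(pts, groups) / as.vector(table(groups))
  cent
}
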