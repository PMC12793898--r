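# Ecological field metrics defined by the monitoring protocol: sediment-trap
# deposition rate, nutrient-limitation regime from molar N:P, hydroclimatic
# season, urchin size classes, belt-transect density, caged survival series,
# and Spearman rank correlation with exact small-n p-values.

#' Sedimentation rate from a sediment trap
#'
#' Dried sediment mass divided by the trap-opening area and deployment
#' duration. The default aperture matches the 6.4 cm PVC traps used in reef
#' monitoring.
#'
#' @param mass dried sediment mass in mg (>= 0).
#' @param aperture_diameter trap opening diameter in cm (default 6.4).
#' @param days deployment duration in days (> 0).
#' @return rate in mg cm^-2 day^-1.
#' @examples
#' sedimentation_rate(1351.2, 6.4, 42)  # ~1 mg cm^-2 day^-1
#' @export
sedimentation_rate <- function(mass, aperture_diameter = 6.4, days) {
  if (any(days <= 0)) stopf("deployment days must be > 0")
  if (any(aperture_diameter <= 0)) stopf("aperture diameter must be > 0")
  if (any(mass < 0)) stopf("sediment mass must be >= 0")
  mass / (pi * (aperture_diameter / 2)^2 * days)
}

#' Nutrient-limitation status from molar N:P
#'
#' Ratios at or below the Redfield value (16) indicate potential nitrogen
#' limitation; ratios above 16 up to the phosphorus-limitation threshold
#' (22) are a transition zone; above 22 indicates phosphorus limitation.
#'
#' @param totalN,totalP molar concentrations (uM); `totalP` must be > 0.
#' @return data frame with `ratio` and `status` in
#'   \{N_LIMITED, TRANSITION, P_LIMITED\}.
#' @export
np_status <- function(totalN, totalP) {
  if (any(totalP <= 0)) stopf("totalP must be > 0")
  ratio <- totalN / totalP
  status <- ifelse(ratio <= 16, "N_LIMITED",
                   ifelse(ratio <= 22, "TRANSITION", "P_LIMITED"))
  data.frame(ratio = ratio,
             status = factor(status, levels = c("N_LIMITED", "TRANSITION",
                                                "P_LIMITED")))
}

#' Hydroclimatic season of a date
#'
#' January-April is the dry season, May-November the wet season; December
#' falls outside the defined sampling window and is an error.
#'
#' @param date a `Date` (or string coercible to one).
#' @return `"DRY"` or `"WET"`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  if (any(m == 12L)) stopf("December is outside the defined season window")
  ifelse(m <= 4L, "DRY", "WET")
}

#' Urchin size class from test diameter
#'
#' Small < 40 mm, medium 40-60 mm (bounds inclusive), large > 60 mm.
#'
#' @param test_diameter diameter in mm (> 0).
#' @return factor in \{SMALL, MEDIUM, LARGE\}.
#' @export
size_class <- function(test_diameter) {
  if (any(test_diameter <= 0)) stopf("test diameter must be > 0")
  cls <- ifelse(test_diameter < 40, "SMALL",
                ifelse(test_diameter <= 60, "MEDIUM", "LARGE"))
  factor(cls, levels = c("SMALL", "MEDIUM", "LARGE"))
}

#' Belt-transect density
#'
#' @param count individuals counted (>= 0), vectorized over transects.
#' @param transect_area transect area in m^2 (default 20).
#' @param by optional grouping factor (site-period); when given, returns
#'   mean +/- SD of density over transects per group.
#' @return densities in individuals m^-2, or a per-group summary data frame.
#' @export
transect_density <- function(count, transect_area = 20, by = NULL) {
  if (any(count < 0)) stopf("counts must be >= 0")
  if (any(transect_area <= 0)) stopf("transect area must be > 0")
  dens <- count / transect_area
  if (is.null(by)) return(dens)
  by <- as.factor(by)
  data.frame(group = levels(by),
             mean = as.vector(tapply(dens, by, mean)),
             sd = as.vector(tapply(dens, by, stats::sd)),
             n = as.vector(table(by)))
}

#' Monthly survival series from chained live counts
#'
#' Each month's survival rate is SR = N_f / N_i with N_i the previous
#' month's final count (chained), so the product of monthly SRs equals the
#' terminal fraction. Counts that increase raise a warning (recruitment is
#' impossible in cages); a zero count terminates the series with a flag.
#'
#' @param counts vector of live counts, first entry the initial cohort.
#' @return a `survival_series` list: `table` (month, N_i, N_f, SR),
#'   `mean_SR` (simple mean over months), `terminal_fraction`,
#'   `terminated` flag.
#' @examples
#' survival_series(c(12, 9, 6))  # SRs 0.75, 0.667; mean 0.708
#' @export
survival_series <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stopf("need at least two monthly counts")
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (any(diff(counts) > 0))
    warnf("increasing counts: recruitment is impossible in cages")
  terminated <- FALSE
  rows <- NULL
  for (t in seq_len(length(counts) - 1L)) {
    Ni <- counts[t]; Nf <- counts[t + 1L]
    if (Ni == 0) { terminated <- TRUE; break }
    rows <- rbind(rows, data.frame(month = t, N_i = Ni, N_f = Nf,
                                   SR = Nf / Ni))
  }
  if (is.null(rows)) stopf("initial count is zero")
  structure(list(table = rows, mean_SR = mean(rows$SR),
                 terminal_fraction = rows$N_f[nrow(rows)] / rows$N_i[1L],
                 terminated = terminated),
            class = "survival_series")
}

#' @export
print.survival_series <- function(x, ...) {
  print(transform(x$table, SR = signif(SR, 4)), row.names = FALSE)
  cat(sprintf("mean SR = %.4g; terminal fraction = %.4g%s\n",
              x$mean_SR, x$terminal_fraction,
              if (x$terminated) " (series terminated at zero)" else ""))
  invisible(x)
}

#' Spearman rank correlation with exact small-sample p
#'
#' Average-rank ties; two-sided p by exhaustive enumeration of all n!
#' rank permutations for n <= 8, t-approximation otherwise. A constant
#' vector leaves rho undefined (NA with a warning) rather than NaN.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n`, `method` ("exact" or "t-approx").
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_perms(n)
    rho_perm <- as.vector(stats::cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approx"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}
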