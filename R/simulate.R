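# Synthetic MSAP, phenotype, and transplant data with known ground truth.
# The generator emulates the structure of a reef monitoring study: two-digest
# binary fragment profiles with almost all loci polymorphic,
# hypermethylation-predominant state frequencies (per-locus frequencies drawn
# from a low-concentration Dirichlet so per-locus Shannon diversity is
# strongly right-skewed), a seasonal effect touching a configurable fraction
# of loci with site effects an order of magnitude weaker, righting times
# positively rank-correlated with test diameter and slowed by sedimentation,
# and binomially thinned caged-survival series.

#' Simulation configuration
#'
#' Defaults describe the emulated monitoring study: three sites by two
#' seasons with 14 samples per group (84 samples), 300 fragment loci,
#' HPM-heavy mean state priors (NMT .10 / HMM .25 / ICM .15 / HPM .50) with
#' Dirichlet concentration 1 across loci, 20% of loci carrying a seasonal
#' state shift of probability 0.3 with site effects 10 times weaker, a 2%
#' per-digest-bit scoring error, and a target diameter-righting Spearman
#' correlation of 0.3.
#'
#' @param n_samples_per_group samples per design cell.
#' @param n_loci number of fragment loci.
#' @param state_priors mean state frequencies (NMT, HMM, ICM, HPM); must sum
#'   to 1.
#' @param dirichlet_conc concentration of the per-locus Dirichlet around
#'   `state_priors`; smaller = more skewed per-locus frequencies.
#' @param frac_affected_loci fraction of loci carrying the seasonal (and,
#'   independently, the site) effect.
#' @param effect_size probability that an affected cell's state is replaced
#'   by the locus's shifted target state in the affected condition.
#' @param site_effect_ratio site effect strength relative to the seasonal
#'   effect (default 0.1).
#' @param noise_rate per-digest-bit flip probability after state encoding.
#' @param pheno_coupling latent-scale coupling between group-level
#'   epigenetic and righting-time shifts, in \[0, 1\].
#' @param rho_diameter target Spearman correlation between test diameter and
#'   righting time.
#' @param seed integer seed recorded in the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples_per_group = 14L,
                       n_loci = 300L,
                       state_priors = c(NMT = 0.10, HMM = 0.25,
                                        ICM = 0.15, HPM = 0.50),
                       dirichlet_conc = 1.0,
                       frac_affected_loci = 0.2,
                       effect_size = 0.3,
                       site_effect_ratio = 0.1,
                       noise_rate = 0.02,
                       pheno_coupling = 0.9,
                       rho_diameter = 0.3,
                       seed = 1L) {
  stopifnot(abs(sum(state_priors) - 1) < 1e-8,
            all(state_priors >= 0),
            frac_affected_loci >= 0, frac_affected_loci <= 1,
            effect_size >= 0, effect_size <= 1,
            noise_rate >= 0, noise_rate <= 1,
            pheno_coupling >= 0, pheno_coupling <= 1)
  structure(list(n_samples_per_group = as.integer(n_samples_per_group),
                 n_loci = as.integer(n_loci),
                 state_priors = state_priors,
                 dirichlet_conc = dirichlet_conc,
                 frac_affected_loci = frac_affected_loci,
                 effect_size = effect_size,
                 site_effect_ratio = site_effect_ratio,
                 noise_rate = noise_rate,
                 pheno_coupling = pheno_coupling,
                 rho_diameter = rho_diameter,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

# state label -> (HpaII, MspI) digit pair; exact inverse of classify_states
state_to_digests <- function(states) {
  hpa <- matrix(NA_real_, nrow(states), ncol(states), dimnames = dimnames(states))
  msp <- hpa
  hpa[states == "NMT"] <- 1; msp[states == "NMT"] <- 1
  hpa[states == "HMM"] <- 1; msp[states == "HMM"] <- 0
  hpa[states == "ICM"] <- 0; msp[states == "ICM"] <- 1
  hpa[states == "HPM"] <- 0; msp[states == "HPM"] <- 0
  list(hpa = hpa, msp = msp)
}

#' Generate a synthetic MSAP dataset with known truth
#'
#' Draws per-locus state frequencies from a Dirichlet around the configured
#' priors, samples each cell's methylation state, applies seasonal shifts
#' (probability `effect_size` of replacement by a locus-specific target
#' state in the wet season, on an `frac_affected_loci` subset) and site
#' shifts ten times weaker by default, maps states to HpaII/MspI digest
#' pairs via the exact inverse of [classify_states()], and finally flips
#' digest bits at `noise_rate` so the scoring stage is exercised.
#'
#' @param cfg a [sim_config()].
#' @param design data frame of design cells with columns `site` and
#'   `season` (or `status`); default 3 sites x 2 seasons. A single-cell
#'   design is an error.
#' @param seed overrides `cfg$seed` when given.
#' @return list with `fragments` (a `fragment_matrix` with noise),
#'   `truth_states` (noise-free `state_matrix`), `affected_loci`
#'   (seasonal), `affected_loci_site`, `meta` (sample metadata data frame),
#'   and `manifest` (generator settings for the reproducibility record).
#' @export
gen_msap <- function(cfg = sim_config(),
                     design = expand.grid(site = c("TG", "PM", "AH"),
                                          season = c("DRY", "WET"),
                                          stringsAsFactors = FALSE),
                     seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(design) < 2L) stopf("degenerate design: need >= 2 cells")
  seed <- seed %||% cfg$seed
  with_seed(seed, {
    n_per <- cfg$n_samples_per_group
    meta <- design[rep(seq_len(nrow(design)), each = n_per), , drop = FALSE]
    n <- nrow(meta)
    meta$sample_id <- sprintf("S%03d", seq_len(n))
    rownames(meta) <- NULL
    L <- cfg$n_loci
    loci <- sprintf("L%04d", seq_len(L))
    priors <- rdirichlet(L, cfg$dirichlet_conc * cfg$state_priors)
    colnames(priors) <- STATES

    n_aff <- round(cfg$frac_affected_loci * L)
    aff_season <- sort(sample.int(L, n_aff))
    aff_site <- sort(sample.int(L, n_aff))
    # a shift target equal to the locus's modal state would produce no
    # realized change, so targets are drawn from the other three states
    modal <- max.col(priors)
    pick_target <- function() vapply(seq_len(L), function(j)
      sample(STATES[-modal[j]], 1L), character(1))
    target_season <- pick_target()
    target_site <- pick_target()
    # each site-affected locus shifts in one randomly chosen site
    site_levels <- unique(as.character(meta$site))
    shift_site <- sample(site_levels, L, replace = TRUE)

    states <- matrix(NA_character_, n, L,
                     dimnames = list(meta$sample_id, loci))
    # affected condition: wet season, or (transplant designs) any status
    # departing from the first design cell's baseline status
    wet <- if ("season" %in% names(meta)) {
      meta$season == "WET"
    } else if ("status" %in% names(meta)) {
      meta$status != as.character(design$status[1L])
    } else rep(FALSE, n)
    for (j in seq_len(L)) {
      s <- sample(STATES, n, replace = TRUE, prob = priors[j, ])
      if (j %in% aff_season && any(wet)) {
        hit <- wet & stats::runif(n) < cfg$effect_size
        s[hit] <- target_season[j]
      }
      if (j %in% aff_site) {
        at <- as.character(meta$site) == shift_site[j]
        hit <- at & stats::runif(n) < cfg$effect_size * cfg$site_effect_ratio
        s[hit] <- target_site[j]
      }
      states[, j] <- s
    }
    dg <- state_to_digests(states)
    if (cfg$noise_rate > 0) {
      flip <- function(m) {
        idx <- stats::runif(length(m)) < cfg$noise_rate
        m[idx] <- 1 - m[idx]
        m
      }
      dg$hpa <- flip(dg$hpa); dg$msp <- flip(dg$msp)
    }
    truth <- structure(list(states = states, samples = meta$sample_id,
                            loci = loci, is_msl = NULL,
                            is_polymorphic = NULL,
                            meth_threshold = NA_real_),
                       class = "state_matrix")
    list(fragments = fragment_matrix(dg$hpa, dg$msp),
         truth_states = truth,
         affected_loci = loci[aff_season],
         affected_loci_site = loci[aff_site],
         meta = meta,
         manifest = list(generator = "gen_msap", seed = seed,
                         config = unclass(cfg),
                         design = design,
                         n_samples = n, n_loci = L))
  })
}

#' Generate synthetic phenotypes tied to metadata and environment
#'
#' Log righting time is baseline + site/season effects + a sedimentation
#' slope + a diameter component + noise; the diameter coefficient is tuned
#' from the realized variance of the other components so the marginal
#' Spearman correlation between diameter and righting time approaches
#' `cfg$rho_diameter` at large n. Sedimentation strictly slows righting
#' (positive slope on the log scale).
#'
#' @param cfg a [sim_config()].
#' @param meta metadata data frame with `sample_id`, `site`, and `season`.
#' @param env optional data frame with `site` and `sedimentation`
#'   (mg cm^-2 day^-1); defaults emulate contrasting reef sedimentation
#'   regimes (TG 33.4, PM 14.3, AH 6.2, PS 3.6).
#' @param seed overrides `cfg$seed` when given.
#' @return a phenotype data frame (`sample_id`, `righting_time` s,
#'   `test_diameter` mm) with the generating components in attributes.
#' @export
gen_phenotypes <- function(cfg = sim_config(), meta, env = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- seed %||% cfg$seed
  if (is.null(env))
    env <- data.frame(site = c("TG", "PM", "AH", "PS"),
                      sedimentation = c(33.4, 14.3, 6.2, 3.6),
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    n <- nrow(meta)
    sed <- env$sedimentation[match(as.character(meta$site), env$site)]
    if (anyNA(sed)) stopf("no sedimentation value for some site(s)")
    beta_sed <- 0.01                    # log-s per mg cm^-2 day^-1
    site_eff <- stats::rnorm(length(unique(meta$site)), 0, 0.10)
    names(site_eff) <- unique(as.character(meta$site))
    seas_eff <- c(DRY = -0.08, WET = 0.08)
    base <- log1p(10)                   # ~10 s typical righting time
    fixed <- base + site_eff[as.character(meta$site)] +
      seas_eff[as.character(meta$season)] + beta_sed * sed
    sigma_e <- 0.25
    z1 <- stats::rnorm(n)               # latent size driver
    # Pearson latent correlation giving the target Spearman for normals
    r <- 2 * sin(pi * cfg$rho_diameter / 6)
    sig_other <- sqrt(stats::var(fixed) + sigma_e^2)
    gamma <- if (r < 1) r * sig_other / sqrt(1 - r^2) else sig_other * 1e3
    lrt <- fixed + gamma * z1 + sigma_e * stats::rnorm(n)
    diameter <- pmax(5, 50 + 10 * z1)
    data.frame(sample_id = meta$sample_id,
               righting_time = expm1(lrt),
               test_diameter = diameter,
               stringsAsFactors = FALSE)
  })
}

#' Generate a caged-transplant survival count series
#'
#' Monthly binomial thinning of a cohort: each month's live count is
#' Binomial(previous count, p_month). The [survival_series()] estimator
#' applied to the output recovers the product of monthly probabilities
#' within binomial error.
#'
#' @param survival_monthly vector of per-month survival probabilities.
#' @param n_caged initial cohort size (default 14, one cage).
#' @param seed optional integer seed.
#' @return integer vector of monthly live counts, starting at `n_caged`.
#' @export
gen_transplant <- function(survival_monthly, n_caged = 14L, seed = NULL) {
  stopifnot(all(survival_monthly >= 0), all(survival_monthly <= 1),
            n_caged >= 1)
  with_seed(seed, {
    counts <- integer(length(survival_monthly) + 1L)
    counts[1L] <- as.integer(n_caged)
    for (t in seq_along(survival_monthly)) {
      counts[t + 1L] <- stats::rbinom(1L, counts[t], survival_monthly[t])
    }
    counts
  })
}

#' Generate coupled group-level epigenetic and phenotypic shifts
#'
#' Builds a dataset in which each site's seasonal epigenetic shift magnitude
#' and its seasonal righting-time shift share a lognormal latent scale with
#' coupling strength `coupling` (1 = identical latent, 0 = independent), for
#' validating the plasticity-coupling statistic. Samples scatter around
#' their group centroid in a small Euclidean feature space.
#'
#' @param n_sites number of sites (default 6; one seasonal pair each).
#' @param n_per_group samples per site-season group (default 10).
#' @param n_features epigenetic feature dimension (default 5).
#' @param coupling latent coupling strength in \[0, 1\].
#' @param sigma_within within-group scatter SD (default 0.2).
#' @param latent_sd SD of the log latent shift scale (default 0.75).
#' @param seed integer seed.
#' @return list with `x` (numeric matrix), `meta`, `pheno`, and
#'   `latent` (per-site latent scales).
#' @export
gen_coupled_groups <- function(n_sites = 6L, n_per_group = 10L,
                               n_features = 5L, coupling = 0.9,
                               sigma_within = 0.2, latent_sd = 0.75,
                               seed = NULL) {
  stopifnot(coupling >= 0, coupling <= 1)
  with_seed(seed, {
    sites <- sprintf("X%02d", seq_len(n_sites))
    meta <- expand.grid(site = sites, season = c("DRY", "WET"),
                        stringsAsFactors = FALSE)
    meta <- meta[rep(seq_len(nrow(meta)), each = n_per_group), ]
    n <- nrow(meta)
    meta$sample_id <- sprintf("C%03d", seq_len(n))
    rownames(meta) <- NULL
    z <- stats::rnorm(n_sites)                       # shared latent
    e <- stats::rnorm(n_sites)
    m_epi <- exp(latent_sd * z)                      # epi shift magnitude
    m_phe <- exp(latent_sd * (coupling * z + sqrt(1 - coupling^2) * e))
    dirs <- matrix(stats::rnorm(n_sites * n_features), n_sites)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    x <- matrix(stats::rnorm(n * n_features, sd = sigma_within), n)
    lrt <- log1p(10) + stats::rnorm(n, sd = sigma_within)
    for (k in seq_len(n_sites)) {
      wet_k <- meta$site == sites[k] & meta$season == "WET"
      x[wet_k, ] <- sweep(x[wet_k, , drop = FALSE], 2L,
                          -m_epi[k] * dirs[k, ])
      lrt[wet_k] <- lrt[wet_k] + m_phe[k]
    }
    pheno <- data.frame(sample_id = meta$sample_id,
                        righting_time = expm1(lrt),
                        test_diameter = rep(50, n),
                        stringsAsFactors = FALSE)
    list(x = x, meta = meta, pheno = pheno,
         latent = data.frame(site = sites, m_epi = m_epi, m_phe = m_phe))
  })
}
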