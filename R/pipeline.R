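# End-to-end orchestration: YAML (or list) config -> staged outputs
# (scoring, diversity, PERMANOVA/PERMDISP, PCoA, dbRDA, DAPC, plasticity)
# plus a reproducibility manifest. Every scoring/analysis threshold is a
# config key with the standard value as default.

default_pipeline_config <- function() {
  list(
    preset = "monitoring",      # or "transplant"; ignored when inputs given
    inputs = list(fragments = NULL, states = NULL, meta = NULL, pheno = NULL),
    out_dir = NULL,
    seed = 1L,
    params = list(size_min = 50, size_max = 1500, rfu_min = 40,
                  bin_width = 1.0, prevalence = 0.15, meth_threshold = 0.05,
                  metric = "EUCLIDEAN", permutations = 999,
                  percentile = 0.90,
                  pairing = "within_site_across_season",
                  terms = c("site", "season", "status")),
    sim = list()                # overrides for sim_config()
  )
}

load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: '%s'", config)
    yaml::read_yaml(config)
  } else as.list(config)
  out <- default_pipeline_config()
  for (nm in names(cfg)) {
    out[[nm]] <- if (is.list(out[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(out[[nm]], cfg[[nm]]) else cfg[[nm]]
  }
  out
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

#' Run the full MSAP analysis pipeline
#'
#' Chains scoring, diversity, PERMANOVA/PERMDISP, PCoA, dbRDA, DAPC and
#' plasticity coupling, writing one report file per stage plus a
#' reproducibility manifest (`manifest.json`) recording the config, seed,
#' package version, per-stage row/locus counts and output file digests.
#' With `resume = TRUE`, stages whose output file already exists are
#' skipped.
#'
#' @param config path to a YAML config file, or an equivalent list. Keys:
#'   `preset` (`"monitoring"` or `"transplant"` simulation when no inputs
#'   are given), `inputs` (paths: `fragments` or `states`, `meta`, `pheno`),
#'   `out_dir`, `seed`, `params` (scoring window `size_min`/`size_max`,
#'   `rfu_min`, `bin_width`, `prevalence`, `meth_threshold`, `metric`,
#'   `permutations`, `percentile`, `pairing`, `terms`), and `sim`
#'   (overrides for [sim_config()]).
#' @param resume skip stages whose output file exists (default FALSE).
#' @return the output directory, invisibly; stage results as the
#'   `"results"` attribute.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- load_pipeline_config(config)
  out_dir <- cfg$out_dir %||% stopf("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  seed <- as.integer(cfg$seed)
  log_line <- function(fmt, ...) message(sprintf(paste0("[epimsap] ", fmt), ...))

  have <- function(x) !is.null(x) && nzchar(x)
  simulated <- !have(cfg$inputs$fragments) && !have(cfg$inputs$states)

  # --- acquire inputs ------------------------------------------------------
  meta <- pheno <- NULL
  if (simulated) {
    if (!cfg$preset %in% c("monitoring", "transplant"))
      stopf("no input fragments/states and unknown preset '%s'", cfg$preset)
    sc <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                as.list(cfg$sim)))
    design <- if (cfg$preset == "monitoring") {
      expand.grid(site = c("TG", "PM", "AH"), season = c("DRY", "WET"),
                  stringsAsFactors = FALSE)
    } else {
      expand.grid(site = c("TG", "PS"), status = c("BT", "DA", "AA"),
                  stringsAsFactors = FALSE)
    }
    sim <- gen_msap(sc, design, seed = seed)
    fm <- sim$fragments
    meta <- sim$meta
    if (!"season" %in% names(meta)) meta$season <- "DRY"  # transplant preset
    pheno <- gen_phenotypes(sc, meta, seed = seed + 1L)
    log_line("simulated %s preset: %d samples x %d loci (seed %d)",
             cfg$preset, nrow(meta), sc$n_loci, seed)
  } else {
    if (!have(cfg$inputs$meta)) stopf("config missing input: meta")
    meta <- read_sample_metadata(cfg$inputs$meta)
    pheno <- if (have(cfg$inputs$pheno)) read_phenotype_table(cfg$inputs$pheno)
    fm <- if (have(cfg$inputs$fragments)) read_fragment_matrix(cfg$inputs$fragments)
  }

  results <- list()
  counts <- list()

  # --- stage 1: scoring ----------------------------------------------------
  f_states <- stage_file(out_dir, "01_states.csv")
  if (resume && file.exists(f_states)) {
    log_line("stage 1 (scoring): resumed from %s", f_states)
    sm <- read_state_matrix(f_states)
  } else {
    if (!simulated && have(cfg$inputs$states)) {
      sm <- read_state_matrix(cfg$inputs$states)
      if (is.null(sm$is_msl)) sm <- partition_msl(sm, p$meth_threshold)
    } else {
      fm <- filter_prevalence(fm, p$prevalence)
      sm <- partition_msl(classify_states(fm), p$meth_threshold)
    }
    write_state_matrix(sm, f_states)
    log_line("stage 1 (scoring): %d loci, %d MSL (%.1f%% polymorphic)",
             sm$counts$n_loci, sm$counts$n_msl, sm$counts$pct_polymorphic_of_msl)
  }
  meta <- meta[match(sm$samples, meta$sample_id), , drop = FALSE]
  counts$n_samples <- length(sm$samples)
  counts$scoring <- sm$counts
  results$states <- sm

  # --- stage 2: diversity --------------------------------------------------
  f_div <- stage_file(out_dir, "02_diversity.csv")
  if (!(resume && file.exists(f_div))) {
    div <- shannon_diversity(sm)
    freq <- state_frequencies(sm, groups = meta$season %||% NULL)
    utils::write.csv(
      rbind(data.frame(quantity = "mean_H", value = div$mean_H),
            data.frame(quantity = "sd_H", value = div$sd_H),
            data.frame(quantity = paste("fraction", freq$group, freq$state,
                                        sep = "_"),
                       value = freq$fraction)),
      f_div, row.names = FALSE)
    results$diversity <- div
    log_line("stage 2 (diversity): mean H = %.3f +/- %.3f", div$mean_H, div$sd_H)
  }

  x <- encode_matrix(sm, "METH_BINARY")
  d <- pairwise_distances(x, p$metric)
  terms_present <- intersect(p$terms, names(meta))
  terms_present <- terms_present[vapply(terms_present, function(v)
    length(unique(meta[[v]])) > 1L, logical(1))]
  if (!length(terms_present)) stopf("no usable model terms in metadata")
  form <- stats::reformulate(terms_present)

  # --- stage 3: permanova + permdisp --------------------------------------
  f_perm <- stage_file(out_dir, "03_permanova.tsv")
  if (!(resume && file.exists(f_perm))) {
    pm <- permanova(d, form, meta, permutations = p$permutations,
                    seed = seed + 2L)
    pd <- permdisp(d, interaction(meta[terms_present], drop = TRUE),
                   permutations = p$permutations, seed = seed + 3L)
    tab <- pm$aov_table
    tab$permdisp_F <- c(pd$F, rep(NA, nrow(tab) - 1L))
    tab$permdisp_p <- c(pd$p, rep(NA, nrow(tab) - 1L))
    utils::write.table(tab, f_perm, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    results$permanova <- pm; results$permdisp <- pd
    log_line("stage 3 (permanova): %s",
             paste(sprintf("%s R2=%.3f p=%.3g", tab$term[seq_along(terms_present)],
                           tab$R2[seq_along(terms_present)],
                           tab$p[seq_along(terms_present)]), collapse = "; "))
  }

  # --- stage 4: pcoa -------------------------------------------------------
  f_pcoa <- stage_file(out_dir, "04_pcoa.tsv")
  ord <- pcoa(d)
  if (!(resume && file.exists(f_pcoa))) {
    utils::write.table(
      data.frame(sample_id = rownames(ord$points),
                 signif(ord$points[, seq_len(min(4L, ncol(ord$points))),
                                   drop = FALSE], 6)),
      f_pcoa, sep = "\t", row.names = FALSE, quote = FALSE)
    results$pcoa <- ord
    log_line("stage 4 (pcoa): axis 1 explains %.1f%%", 100 * ord$explained[1])
  }

  # --- stage 5: dbrda ------------------------------------------------------
  f_dbrda <- stage_file(out_dir, "05_dbrda.json")
  if (!(resume && file.exists(f_dbrda))) {
    if (is.null(pheno)) stopf("config missing input: pheno")
    pred <- data.frame(righting = log1p(pheno$righting_time[
                         match(sm$samples, pheno$sample_id)]),
                       diameter = log1p(pheno$test_diameter[
                         match(sm$samples, pheno$sample_id)]))
    db <- dbrda(d, pred, permutations = p$permutations, seed = seed + 4L)
    jsonlite::write_json(
      list(constrained_fraction = db$constrained_fraction,
           F = db$F, p_overall = db$p_overall, terms = db$term_table),
      f_dbrda, auto_unbox = TRUE, digits = 8)
    results$dbrda <- db
    log_line("stage 5 (dbrda): %.2f%% constrained, p = %.3g",
             100 * db$constrained_fraction, db$p_overall)
  }

  # --- stage 6: dapc -------------------------------------------------------
  f_dapc <- stage_file(out_dir, "06_dapc_loadings.tsv")
  if (!(resume && file.exists(f_dapc))) {
    grp <- interaction(meta[terms_present], drop = TRUE)
    xp <- encode_matrix(sm, "METH_BINARY", polymorphic_only = TRUE)
    fit <- fit_dapc(xp, grp)
    infl <- select_influential(fit, p$percentile)
    utils::write.table(
      data.frame(locus = rownames(fit$loadings),
                 signif(fit$loadings, 6),
                 influential = rownames(fit$loadings) %in% infl$loci),
      f_dapc, sep = "\t", row.names = FALSE, quote = FALSE)
    results$dapc <- fit; results$influential <- infl
    counts$dapc <- list(n_pc = fit$n_pc, n_da = fit$n_da,
                        n_influential = infl$n)
    log_line("stage 6 (dapc): %d influential loci (%.1f%%)",
             infl$n, 100 * infl$fraction)
  }

  # --- stage 7: plasticity -------------------------------------------------
  f_plas <- stage_file(out_dir, "07_plasticity.tsv")
  if (!(resume && file.exists(f_plas))) {
    pairing <- if ("season" %in% terms_present) p$pairing else "across_status"
    pc <- plasticity_coupling(ord, pheno, meta, pairing = pairing)
    hdr <- sprintf("# rho=%s p=%s n_pairs=%d",
                   format(pc$rho), format(pc$p), pc$n_pairs)
    writeLines(hdr, f_plas)
    if (!is.null(pc$pairs))
      suppressWarnings(utils::write.table(pc$pairs, f_plas, sep = "\t",
                                          row.names = FALSE, quote = FALSE,
                                          append = TRUE))
    results$plasticity <- pc
    log_line("stage 7 (plasticity): rho = %.3f, p = %.3g", pc$rho, pc$p)
  }

  # --- manifest ------------------------------------------------------------
  stage_files <- c(f_states, f_div, f_perm, f_pcoa, f_dbrda, f_dapc, f_plas)
  manifest <- list(
    tool = "epimsap",
    version = as.character(utils::packageVersion("epimsap")),
    seed = seed,
    config = cfg[c("preset", "params", "sim")],
    counts = counts,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(stage_files)), basename(stage_files))))
  jsonlite::write_json(manifest, stage_file(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  attr(out_dir, "results") <- results
  invisible(out_dir)
}
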