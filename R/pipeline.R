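#' Run the full dosage-effect analysis on simulated or supplied data
#'
#' Orchestrates the stages end to end: simulate feature tables, flow counts
#' and mass pairs (or load user-supplied files); run the three-step filter
#' with log2(x+1) normalization; per-feature differential abundance with
#' strain-by-ploidy classification and cross-strain DAF intersections; fit
#' the relative-cell-density flow model and the dry-fraction mass model;
#' combine them into rcd_dm draws; and renormalize each strain's per-dry-mass
#' fold changes to per-cell fold changes with dosage classes. One seed in the
#' configuration determines every stage, so identical configurations yield
#' identical manifests.
#'
#' @param config A [sim_config()], or a path to a YAML/JSON file readable by
#'   [read_sim_config()].
#' @param outdir Optional directory; when given, every stage's inputs and
#'   outputs are written there (TSV/CSV/JSON) and recorded in the manifest.
#' @param platforms Named integer vector, platform tag -> feature count.
#' @param rsd_frac,iqr_frac Removal fractions of the filter steps.
#' @param alpha Adjusted-p cut-off for DAFs and ANOVA flags.
#' @param n_draws Posterior draws per model entering [combine_rcd_dm()].
#' @param paired_draws Pair rcd and rf_dry draws instead of crossing them.
#' @param settings [mcmc_settings()]; its seed defaults to the config seed.
#' @return A list of class `run_manifest`: `config_hash`, `seed`, `stages`
#'   (per-stage paths and summary scalars), and `results` holding the
#'   in-memory stage outputs (`tables`, `filtered`, `contrasts`, `anova`,
#'   `upset`, `cell_fit`, `mass_fit`, `rcd_dm`, `fold_changes`).
#' @export
run_pipeline <- function(config, outdir = NULL,
                         platforms = c("ESI-" = 1000L),
                         rsd_frac = 0.20, iqr_frac = 0.20, alpha = 0.05,
                         n_draws = 500L, paired_draws = FALSE,
                         settings = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  if (is.null(settings)) settings <- mcmc_settings(seed = config$seed)
  hash <- config_hash(unclass(config))
  emit <- !is.null(outdir)
  if (emit) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(name) if (emit) file.path(outdir, name) else NULL
  stages <- list()

  # -- simulate ---------------------------------------------------------
  tables <- lapply(names(platforms), function(p) {
    simulate_feature_table(config, platform = p,
                           n_features = platforms[[p]])
  })
  names(tables) <- names(platforms)
  flow_design <- study_flow_design(config)
  flow <- simulate_flow_observations(config, flow_design)
  mass <- study_mass_observations(config)
  if (emit) {
    for (p in names(tables)) {
      write_feature_table(tables[[p]],
                          pth(sprintf("features_%s.tsv", safe_tag(p))),
                          seed = config$seed, hash = hash)
    }
    write_flow_observations(flow, pth("flow.csv"), config$seed, hash)
    write_mass_observations(mass, pth("mass.csv"), config$seed, hash)
    write_sim_config(config, pth("config.yaml"))
  }
  stages$simulate <- list(
    outputs = if (emit) list.files(outdir, full.names = FALSE) else NULL,
    summary = list(n_features = vapply(tables, function(t)
      ncol(t$abundances), integer(1)),
      n_flow = nrow(flow), n_mass = nrow(mass))
  )

  # -- filter -----------------------------------------------------------
  filtered <- lapply(tables, filter_pipeline,
                     rsd_frac = rsd_frac, iqr_frac = iqr_frac)
  filter_counts <- lapply(filtered, function(f) {
    stats::setNames(c(f$report$features_in[1], f$report$features_out),
                    c("detected", f$report$step))
  })
  if (emit) {
    jsonlite::write_json(
      lapply(filtered, function(f) {
        list(counts = f$report[c("step", "features_in", "features_out")])
      }),
      pth("filter_report.json"), auto_unbox = TRUE, digits = NA)
  }
  stages$filter <- list(summary = filter_counts)

  # -- differential abundance ------------------------------------------
  contrasts <- lapply(filtered, function(f) contrast_tests(f$table, alpha))
  anova_cls <- lapply(filtered, function(f)
    two_way_anova_classify(f$table, alpha))
  upset <- lapply(contrasts, daf_intersections)
  daf_counts <- lapply(contrasts, function(d) {
    vapply(split(d, d$contrast), function(g) sum(g$daf), integer(1))
  })
  if (emit) {
    utils::write.table(do.call(rbind, contrasts),
                       pth("contrasts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(daf_counts = daf_counts,
                              venn = lapply(anova_cls, `[[`, "venn"),
                              upset = upset),
                         pth("diffabund.json"), auto_unbox = TRUE, digits = NA)
  }
  stages$diffabund <- list(summary = list(daf_counts = daf_counts))

  # -- cell density and dry mass ---------------------------------------
  cell_fit <- fit_cell_density(flow, settings)
  mass_fit <- fit_dry_fraction(mass, settings)
  if (emit) {
    utils::write.table(cell_fit$diagnostics, pth("celldensity_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(mass_fit$diagnostics, pth("drymass_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rcd_means <- vapply(config$strains, function(s)
    mean(posterior_draws(cell_fit, sprintf("rcd[%s]", s))), numeric(1))
  stages$celldensity <- list(summary = list(
    rcd_posterior_mean = rcd_means,
    max_rhat = max(cell_fit$diagnostics$rhat, na.rm = TRUE)))
  stages$drymass <- list(summary = list(
    f_dry_posterior_mean = vapply(names(mass_fit$fits), function(k)
      mean(mass_fit$fits[[k]]$f_dry), numeric(1))))

  # -- dosage conversion ------------------------------------------------
  rcd_dm <- combine_rcd_dm(cell_fit, mass_fit, n_draws = n_draws,
                           paired = paired_draws)
  reference <- tables[[1L]]
  fold_changes <- lapply(config$strains, function(s) {
    paired_tab <- log2_transform(pair_presence_filter(reference, s))
    lfc <- log2_fold_changes(paired_tab, strain = s)
    fc_per_cell(lfc, rcd_dm[[s]])
  })
  names(fold_changes) <- config$strains
  medians <- data.frame(
    strain = config$strains,
    mean_rcd_dm = vapply(fold_changes, `[[`, numeric(1), "mean_rcd_dm"),
    median_FCdm = vapply(fold_changes, `[[`, numeric(1), "median_FCdm"),
    median_FCcell = vapply(fold_changes, `[[`, numeric(1), "median_FCcell"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (emit) {
    utils::write.table(
      do.call(rbind, lapply(config$strains, function(s)
        cbind(strain = s, fold_changes[[s]]$features))),
      pth("fold_changes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(medians, pth("fold_change_medians.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  stages$dosage <- list(summary = list(medians = medians))

  manifest <- structure(
    list(config_hash = hash, seed = config$seed, stages = stages,
         results = list(tables = tables, filtered = filtered,
                        contrasts = contrasts, anova = anova_cls,
                        upset = upset, flow = flow, mass = mass,
                        cell_fit = cell_fit, mass_fit = mass_fit,
                        rcd_dm = rcd_dm, fold_changes = fold_changes,
                        medians = medians)),
    class = "run_manifest"
  )
  if (emit) {
    jsonlite::write_json(manifest_scalars(manifest), pth("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}

safe_tag <- function(p) gsub("[^A-Za-z0-9]", "", chartr("+-", "pn", p))

#' Scalar view of a run manifest (what lands in manifest.json)
#' @param manifest A `run_manifest`.
#' @return Nested list of the manifest's scalar summaries only.
#' @export
manifest_scalars <- function(manifest) {
  list(config_hash = manifest$config_hash, seed = manifest$seed,
       stages = lapply(manifest$stages, function(s) s["summary"]))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest (seed %d, config %s)\n", x$seed, x$config_hash))
  cat("filter counts:\n")
  print(x$stages$filter$summary)
  cat("median fold changes:\n")
  print(x$stages$dosage$summary$medians, digits = 4)
  invisible(x)
}
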