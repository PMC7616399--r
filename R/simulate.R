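#' Configuration for the synthetic mixed-ploidy study generator
#'
#' Collects the generative truth for a simulated diploid/neotetraploid
#' metabolomics study: log-normal feature abundances with strain, ploidy and
#' strain-by-ploidy effects plus structurally absent (ploidy-specific)
#' features; mixed-ploidy flow-cytometry nucleus counts whose 4C-peak
#' proportion follows a logit-scale normal around
#' `ln(rcd * rmass + pG2/(1-pG2))`; and fresh/dry mass pairs with dry mass
#' proportional to fresh mass through a strain-by-cytotype fraction `f_dry`.
#'
#' Defaults mirror the study design the generator emulates: four strains,
#' eight replicates per strain-by-ploidy group, five pooled QC samples,
#' twelve mass samples spanning 28-909 mg, nucleus counts of 5,000 per flow
#' sample, a true relative cell density (`rcd`, tetraploid:diploid nuclei per
#' fresh mass) near 0.5-0.65, a diploid G2/endopolyploidy fraction `pG2` of
#' 0.05, and a tetraploid dry-mass fraction slightly below the diploid one so
#' that `rcd_dm = rcd / rf_dry` lands in the 0.6-0.7 range.
#'
#' @param seed Integer seed; every generator call derives its RNG stream from
#'   it, so identical configs give identical data.
#' @param n_strains Number of strains (each with a 2n and a 4n cytotype).
#' @param strains Strain labels; defaults to the four clonal duckweed strains
#'   of the emulated design.
#' @param n_replicates Replicates per strain-by-ploidy group.
#' @param n_qc Pooled quality-control samples appended to feature tables.
#' @param n_features Features per simulated platform table.
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of per-feature
#'   baseline abundance on the log2 scale.
#' @param strain_effect_sd,ploidy_effect_sd,interaction_effect_sd Standard
#'   deviations (log2 scale) of per-feature strain, ploidy, and
#'   strain-by-ploidy effects. Zero switches an effect off.
#' @param noise_sd Residual replicate noise sd on the log2 scale.
#' @param frac_ploidy_specific Fraction of features forced to exactly zero in
#'   all replicates of one randomly chosen strain-by-ploidy cytotype
#'   (structural absence) while remaining positive in the paired cytotype.
#' @param true_rcd Named vector, strain -> true relative cell density per
#'   fresh mass (tetraploid:diploid, positive).
#' @param true_pG2 Named vector, strain -> proportion of diploid nuclei in
#'   the 4C peak (G2/endopolyploidy), in (0,1).
#' @param true_theta Logit-scale residual sd of the flow model (positive).
#' @param nuclei_per_sample Gated nuclei counted per flow sample.
#' @param true_f_dry Named vector, `"<strain>:<ploidy>"` -> dry:fresh mass
#'   fraction in (0,1).
#' @param mass_noise_sd Residual sd of dry mass (mg).
#' @param n_mass_samples Fresh/dry mass pairs per strain-by-cytotype.
#' @param mass_range Range (mg) the fresh masses span.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_strains = 4L,
                       strains = c("0013", "9242", "9316", "9346")[seq_len(n_strains)],
                       n_replicates = 8L,
                       n_qc = 5L,
                       n_features = 2000L,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 2,
                       strain_effect_sd = 1,
                       ploidy_effect_sd = 0.5,
                       interaction_effect_sd = 0.5,
                       noise_sd = 0.5,
                       frac_ploidy_specific = 0.01,
                       true_rcd = stats::setNames(
                         seq(0.50, 0.65, length.out = n_strains), strains),
                       true_pG2 = stats::setNames(
                         rep(0.05, n_strains), strains),
                       true_theta = 0.05,
                       nuclei_per_sample = 5000L,
                       true_f_dry = default_f_dry(strains),
                       mass_noise_sd = 0.5,
                       n_mass_samples = 12L,
                       mass_range = c(28, 909)) {
  if (length(strains) != n_strains || anyDuplicated(strains)) {
    stop("`strains` must hold n_strains unique labels")
  }
  cfg <- list(
    seed = as.integer(seed), n_strains = as.integer(n_strains),
    strains = as.character(strains), n_replicates = as.integer(n_replicates),
    n_qc = as.integer(n_qc), n_features = as.integer(n_features),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    strain_effect_sd = strain_effect_sd,
    ploidy_effect_sd = ploidy_effect_sd,
    interaction_effect_sd = interaction_effect_sd,
    noise_sd = noise_sd,
    frac_ploidy_specific = frac_ploidy_specific,
    true_rcd = true_rcd, true_pG2 = true_pG2, true_theta = true_theta,
    nuclei_per_sample = as.integer(nuclei_per_sample),
    true_f_dry = true_f_dry, mass_noise_sd = mass_noise_sd,
    n_mass_samples = as.integer(n_mass_samples), mass_range = mass_range
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_f_dry <- function(strains) {
  # WGD lowers the dry:fresh fraction, so rf_dry < 1 and rcd_dm > rcd.
  vals <- c(rbind(rep(0.060, length(strains)), rep(0.050, length(strains))))
  stats::setNames(vals, paste(rep(strains, each = 2), c("2n", "4n"), sep = ":"))
}

validate_sim_config <- function(cfg) {
  num_fields <- c("baseline_log2_mean", "baseline_log2_sd", "strain_effect_sd",
                  "ploidy_effect_sd", "interaction_effect_sd", "noise_sd",
                  "frac_ploidy_specific", "true_theta", "mass_noise_sd")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || any(!is.finite(cfg[[f]]))) {
      stop("non-finite value for `", f, "`")
    }
  }
  sds <- c(cfg$baseline_log2_sd, cfg$strain_effect_sd, cfg$ploidy_effect_sd,
           cfg$interaction_effect_sd, cfg$noise_sd, cfg$mass_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$true_theta < 0) stop("true_theta must be >= 0")
  if (cfg$frac_ploidy_specific < 0 || cfg$frac_ploidy_specific > 1) {
    stop("frac_ploidy_specific must lie in [0,1]")
  }
  counts <- c(cfg$n_strains, cfg$n_replicates, cfg$n_features,
              cfg$nuclei_per_sample, cfg$n_mass_samples)
  if (any(counts < 1L)) stop("counts must be >= 1")
  if (cfg$n_qc < 0L) stop("n_qc must be >= 0")
  if (!all(cfg$strains %in% names(cfg$true_rcd)) ||
      !all(cfg$strains %in% names(cfg$true_pG2))) {
    stop("true_rcd and true_pG2 must be named by strain")
  }
  if (any(!is.finite(cfg$true_rcd)) || any(cfg$true_rcd <= 0)) {
    stop("true_rcd must be positive and finite")
  }
  if (any(cfg$true_pG2 <= 0) || any(cfg$true_pG2 >= 1)) {
    stop("true_pG2 must lie in (0,1)")
  }
  expected_fd <- paste(rep(cfg$strains, each = 2), c("2n", "4n"), sep = ":")
  if (!all(expected_fd %in% names(cfg$true_f_dry))) {
    stop("true_f_dry must be named '<strain>:<ploidy>' for every cytotype")
  }
  if (any(cfg$true_f_dry <= 0) || any(cfg$true_f_dry >= 1)) {
    stop("true_f_dry must lie in (0,1)")
  }
  if (length(cfg$mass_range) != 2L || any(cfg$mass_range <= 0) ||
      diff(cfg$mass_range) < 0) {
    stop("mass_range must be two positive increasing values")
  }
  invisible(cfg)
}

# Deterministic per-purpose RNG substream from the config seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97003 * offset) %% 2147483647)
}

#' Simulate a samples-by-features abundance table
#'
#' Draws raw-scale abundances `2^(baseline_f + strain_{f,s} + ploidy_{f} +
#' interaction_{f,s} + eps)` where the ploidy and interaction effects act on
#' the tetraploid cytotype and `eps ~ Normal(0, noise_sd)` is replicate
#' noise. A fraction `frac_ploidy_specific` of features is made structurally
#' absent (exact zeros) in all replicates of one randomly chosen
#' strain-by-ploidy cytotype, emulating qualitative presence/absence change
#' after genome doubling. Pooled QC samples (per-feature means of the
#' biological samples) are appended when `n_qc > 0`.
#'
#' @param config A [sim_config()].
#' @param platform Platform tag; each tag gets its own reproducible
#'   substream, so one config yields distinct ESI+/ESI-/GC-MS tables.
#' @param n_features Optional override of `config$n_features` (platforms
#'   differ in feature counts).
#' @return A [feature_table()] with raw-scale abundances.
#' @export
simulate_feature_table <- function(config, platform = "ESI-",
                                   n_features = config$n_features) {
  validate_sim_config(config)
  plat_off <- match(platform, c("ESI+", "ESI-", "GCMS"), nomatch = 0L) +
    sum(utf8ToInt(platform))
  set.seed(derive_seed(config$seed, plat_off))

  ns <- config$n_strains
  nr <- config$n_replicates
  nf <- as.integer(n_features)
  strains <- config$strains
  grid <- expand.grid(replicate = seq_len(nr), ploidy = c("2n", "4n"),
                      strain = strains, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$strain, grid$ploidy, grid$replicate),
    strain = grid$strain, ploidy = grid$ploidy, replicate = grid$replicate,
    is_qc = FALSE, stringsAsFactors = FALSE
  )
  n_bio <- nrow(meta)

  baseline <- stats::rnorm(nf, config$baseline_log2_mean, config$baseline_log2_sd)
  strain_eff <- matrix(stats::rnorm(nf * ns, 0, config$strain_effect_sd),
                       nrow = nf, ncol = ns, dimnames = list(NULL, strains))
  ploidy_eff <- stats::rnorm(nf, 0, config$ploidy_effect_sd)
  inter_eff <- matrix(stats::rnorm(nf * ns, 0, config$interaction_effect_sd),
                      nrow = nf, ncol = ns, dimnames = list(NULL, strains))

  s_idx <- match(meta$strain, strains)
  is_4n <- meta$ploidy == "4n"
  log2_mu <- matrix(baseline, nrow = n_bio, ncol = nf, byrow = TRUE) +
    t(strain_eff[, s_idx, drop = FALSE]) +
    outer(as.numeric(is_4n), ploidy_eff) +
    t(inter_eff[, s_idx, drop = FALSE]) * as.numeric(is_4n)
  noise <- matrix(stats::rnorm(n_bio * nf, 0, config$noise_sd),
                  nrow = n_bio, ncol = nf)
  abund <- 2^(log2_mu + noise)

  n_ps <- round(config$frac_ploidy_specific * nf)
  ps_features <- integer(0)
  if (n_ps > 0L) {
    ps_features <- sample.int(nf, n_ps)
    ps_strain <- sample(strains, n_ps, replace = TRUE)
    ps_absent <- sample(c("2n", "4n"), n_ps, replace = TRUE)
    for (k in seq_len(n_ps)) {
      rows <- meta$strain == ps_strain[k] & meta$ploidy == ps_absent[k]
      abund[rows, ps_features[k]] <- 0
    }
  }

  if (config$n_qc > 0L) {
    qc <- matrix(colMeans(abund), nrow = config$n_qc, ncol = nf, byrow = TRUE)
    abund <- rbind(abund, qc)
    meta <- rbind(meta, data.frame(
      sample_id = sprintf("QC_%d", seq_len(config$n_qc)),
      strain = "QC", ploidy = NA_character_,
      replicate = seq_len(config$n_qc), is_qc = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  colnames(abund) <- sprintf("F%05d", seq_len(nf))
  tab <- feature_table(abund, meta, platform = platform)
  attr(tab, "ploidy_specific_truth") <- if (n_ps > 0L) {
    data.frame(feature_id = colnames(abund)[ps_features],
               strain = ps_strain, absent_ploidy = ps_absent,
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = character(0), strain = character(0),
               absent_ploidy = character(0), stringsAsFactors = FALSE)
  }
  tab
}

#' Simulate gated flow-cytometry nucleus counts
#'
#' Forward simulation of the mixed-ploidy flow model: for a sample of strain
#' `s` with tetraploid:diploid fresh-mass ratio `rmass`, the proportion of
#' nuclei in the 4C peak has
#' `logit(p) ~ Normal(ln(rcd_s * rmass + pG2_s/(1-pG2_s)), theta)`, and the
#' gated counts are `count_4C ~ Binomial(nuclei_per_sample, p)` with
#' `count_2C` the complement. `rmass = 0` encodes the pure-diploid samples
#' used to pin down `pG2`.
#'
#' @param config A [sim_config()].
#' @param design Data frame with columns `strain` and `rmass` (>= 0), one row
#'   per flow sample.
#' @return Data frame with columns `strain`, `rmass`, `count_2C`, `count_4C`.
#' @export
simulate_flow_observations <- function(config, design) {
  validate_sim_config(config)
  design <- as.data.frame(design)
  stopifnot(all(c("strain", "rmass") %in% names(design)))
  if (any(design$rmass < 0)) stop("rmass must be >= 0")
  if (!all(design$strain %in% config$strains)) {
    stop("design contains strains absent from the config")
  }
  set.seed(derive_seed(config$seed, 7L))
  rcd <- config$true_rcd[design$strain]
  pg2 <- config$true_pG2[design$strain]
  odds <- rcd * design$rmass + pg2 / (1 - pg2)
  mu <- log(odds)
  logit_p <- stats::rnorm(nrow(design), mu, config$true_theta)
  p <- stats::plogis(logit_p)
  n4 <- stats::rbinom(nrow(design), config$nuclei_per_sample, p)
  data.frame(strain = design$strain, rmass = design$rmass,
             count_2C = config$nuclei_per_sample - n4, count_4C = n4,
             stringsAsFactors = FALSE)
}

#' Flow-cytometry design of the emulated study
#'
#' Eight mixed-ploidy samples (fresh-mass ratio drawn uniformly on
#' `rmass_range`) and five pure-diploid samples (`rmass = 0`) per strain.
#'
#' @param config A [sim_config()].
#' @param n_mixed,n_diploid Samples per strain of each kind.
#' @param rmass_range Range of the mixed samples' tetraploid:diploid
#'   fresh-mass ratio.
#' @return Design data frame for [simulate_flow_observations()].
#' @export
study_flow_design <- function(config, n_mixed = 8L, n_diploid = 5L,
                              rmass_range = c(0.5, 2)) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 11L))
  do.call(rbind, lapply(config$strains, function(s) {
    data.frame(
      strain = s,
      rmass = c(stats::runif(n_mixed, rmass_range[1], rmass_range[2]),
                rep(0, n_diploid)),
      stringsAsFactors = FALSE
    )
  }))
}

#' Simulate fresh/dry mass pairs for one cytotype
#'
#' Dry mass is `f_dry * m` plus normal noise, resampled until it falls in
#' `(0, m)` so the pair stays physically valid.
#'
#' @param config A [sim_config()].
#' @param fresh_masses Positive fresh masses (mg).
#' @param strain,ploidy Cytotype whose `true_f_dry` applies.
#' @return Data frame with columns `strain`, `ploidy`, `m`, `dm`.
#' @export
simulate_mass_observations <- function(config, fresh_masses, strain, ploidy) {
  validate_sim_config(config)
  if (length(fresh_masses) == 0L) stop("fresh_masses must be non-empty")
  if (any(fresh_masses <= 0)) stop("fresh masses must be positive")
  key <- paste(strain, ploidy, sep = ":")
  if (!key %in% names(config$true_f_dry)) {
    stop("no true_f_dry entry for cytotype ", key)
  }
  set.seed(derive_seed(config$seed,
                       13L + sum(utf8ToInt(key))))
  f <- config$true_f_dry[[key]]
  dm <- vapply(fresh_masses, function(m) {
    repeat {
      d <- f * m + stats::rnorm(1, 0, config$mass_noise_sd)
      if (d > 0 && d < m) return(d)
    }
  }, numeric(1))
  data.frame(strain = strain, ploidy = ploidy, m = fresh_masses, dm = dm,
             stringsAsFactors = FALSE)
}

#' Mass observations for every strain-by-cytotype of the study design
#'
#' Fresh masses are spaced log-uniformly over `config$mass_range` (the
#' emulated study weighed 12 samples spanning roughly 28-909 mg per
#' cytotype).
#'
#' @param config A [sim_config()].
#' @return Data frame of [simulate_mass_observations()] rows for all
#'   cytotypes.
#' @export
study_mass_observations <- function(config) {
  validate_sim_config(config)
  masses <- exp(seq(log(config$mass_range[1]), log(config$mass_range[2]),
                    length.out = config$n_mass_samples))
  combos <- expand.grid(ploidy = c("2n", "4n"), strain = config$strains,
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    simulate_mass_observations(config, masses,
                               combos$strain[i], combos$ploidy[i])
  }))
}
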