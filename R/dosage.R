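#' Expected 4C-peak proportion of a mixed-ploidy flow sample
#'
#' The mixed-ploidy flow model puts the proportion of nuclei in the 4C peak
#' on the odds scale: `odds(p) = rcd * rmass + pG2/(1 - pG2)`, where `rcd`
#' is the tetraploid:diploid cell density per fresh mass (the slope),
#' `rmass` the tetraploid:diploid fresh-mass ratio of the sample, and the
#' intercept is the odds of the diploid G2/endopolyploidy fraction `pG2`.
#' This returns the proportion itself, the inverse logit of
#' `ln(rcd * rmass + pG2/(1-pG2))`.
#'
#' @param rcd Positive relative cell density.
#' @param pG2 Diploid G2/endopolyploid fraction, in (0,1).
#' @param rmass Non-negative fresh-mass ratio (0 for pure-diploid samples).
#' @return Expected proportion of 4C nuclei.
#' @export
predict_p4n <- function(rcd, pG2, rmass) {
  stopifnot(rcd > 0, pG2 > 0, pG2 < 1, rmass >= 0)
  odds <- rcd * rmass + pG2 / (1 - pG2)
  if (any(odds == 0)) {
    warning("zero odds: returning p = 0 (limit of the logit link)")
    return(ifelse(odds == 0, 0, stats::plogis(log(odds))))
  }
  stats::plogis(log(odds))
}

# continuity-corrected observed 4C proportion and its logit
observed_logit_p4n <- function(observations) {
  total <- observations$count_2C + observations$count_4C
  if (any(total <= 0)) stop("each observation needs a positive nucleus total")
  p_hat <- (observations$count_4C + 0.5) / (total + 1)
  stats::qlogis(p_hat)
}

#' Log-likelihood of the mixed-ploidy flow model
#'
#' Sum of normal log-densities of the continuity-corrected observed
#' logit-proportions `logit((count_4C + 0.5)/(total + 1))` around the model
#' mean `ln(rcd[strain] * rmass + pG2[strain]/(1 - pG2[strain]))` with
#' logit-scale sd `theta`.
#'
#' @param params List with `rcd` (named by strain), `pG2` (named by strain),
#'   and scalar `theta`.
#' @param observations Data frame with columns `strain`, `rmass`,
#'   `count_2C`, `count_4C` (see [simulate_flow_observations()]).
#' @return The log-likelihood; `-Inf` for non-finite or out-of-domain
#'   parameters.
#' @export
model1_loglik <- function(params, observations) {
  rcd <- params$rcd[observations$strain]
  pg2 <- params$pG2[observations$strain]
  theta <- params$theta
  if (any(!is.finite(rcd)) || any(!is.finite(pg2)) || !is.finite(theta) ||
      any(rcd <= 0) || any(pg2 <= 0) || any(pg2 >= 1) || theta <= 0) {
    return(-Inf)
  }
  y <- observed_logit_p4n(observations)
  mu <- log(rcd * observations$rmass + pg2 / (1 - pg2))
  sum(stats::dnorm(y, mu, theta, log = TRUE))
}

#' Default MCMC settings
#'
#' Two chains of 2,000 iterations with the first 1,000 as warm-up, plus the
#' weakly regularizing priors: `rcd ~ Normal(1, 1)` truncated to positive
#' values, `pG2 ~ Beta(1.5, 10)`, `theta ~ HalfNormal(1)`,
#' `f_dry ~ Uniform(0, 1)`, residual mass sd `~ HalfNormal(10 mg)`.
#'
#' @param chains,iter,warmup,seed Sampler controls.
#' @param ... Overrides for prior hyperparameters (`rcd_prior_mean`,
#'   `rcd_prior_sd`, `pG2_prior_shape1`, `pG2_prior_shape2`,
#'   `theta_prior_scale`, `sigma_prior_scale`).
#' @return Settings list consumed by [fit_cell_density()] and
#'   [fit_dry_fraction()].
#' @export
mcmc_settings <- function(chains = 2L, iter = 2000L, warmup = 1000L,
                          seed = 1L, ...) {
  out <- list(chains = as.integer(chains), iter = as.integer(iter),
              warmup = as.integer(warmup), seed = as.integer(seed),
              rcd_prior_mean = 1, rcd_prior_sd = 1,
              pG2_prior_shape1 = 1.5, pG2_prior_shape2 = 10,
              theta_prior_scale = 1, sigma_prior_scale = 10)
  dots <- list(...)
  out[names(dots)] <- dots
  out
}

#' Fit the relative-cell-density flow model
#'
#' Joint Bayesian fit across strains of the logit-scale flow model: strain-
#' indexed slope `rcd` and intercept odds `pG2/(1-pG2)` with a shared
#' residual sd `theta`, sampled by adaptive random-walk Metropolis on
#' unconstrained scales (log rcd, logit pG2, log theta) with two chains of
#' 2,000 iterations (1,000 warm-up) by default. Convergence is reported as
#' split-R-hat and effective sample size per parameter; R-hat above 1.05
#' triggers a warning, not an error.
#'
#' @param observations Flow data frame (`strain`, `rmass`, `count_2C`,
#'   `count_4C`); each strain should contribute both mixed (`rmass > 0`) and
#'   pure-diploid (`rmass = 0`) samples — without the latter `pG2` is only
#'   weakly identified and a warning is issued.
#' @param settings [mcmc_settings()].
#' @return Object of class `cell_density_fit`: `draws` array
#'   `[draw, chain, parameter]` on the natural scale, `parameters` names
#'   (`rcd[strain]`, `pG2[strain]`, `theta`), `diagnostics` data frame
#'   (posterior mean, sd, R-hat, ESS), `strains`, and the `settings` used.
#' @export
fit_cell_density <- function(observations, settings = mcmc_settings()) {
  observations <- as.data.frame(observations)
  stopifnot(all(c("strain", "rmass", "count_2C", "count_4C") %in%
                  names(observations)))
  if (any(observations$rmass < 0)) stop("rmass must be >= 0")
  strains <- sort(unique(observations$strain))
  ns <- length(strains)
  no_diploid <- strains[!strains %in%
                          observations$strain[observations$rmass == 0]]
  if (length(no_diploid) > 0L) {
    warning("no pure-diploid (rmass = 0) samples for strain(s) ",
            paste(no_diploid, collapse = ", "),
            ": pG2 weakly identified")
  }
  y <- observed_logit_p4n(observations)
  s_idx <- match(observations$strain, strains)
  rmass <- observations$rmass

  # unconstrained parameter vector: log rcd (ns) | logit pG2 (ns) | log theta
  unpack <- function(u) {
    list(rcd = exp(u[seq_len(ns)]),
         pG2 = stats::plogis(u[ns + seq_len(ns)]),
         theta = exp(u[2L * ns + 1L]))
  }
  trunc_const <- stats::pnorm(0, settings$rcd_prior_mean,
                              settings$rcd_prior_sd, lower.tail = FALSE)
  log_post <- function(u) {
    if (any(!is.finite(u))) return(-Inf)
    p <- unpack(u)
    if (any(p$rcd <= 0) || any(p$pG2 <= 0) || any(p$pG2 >= 1) ||
        p$theta <= 0 || !is.finite(p$theta)) {
      return(-Inf)
    }
    mu <- log(p$rcd[s_idx] * rmass + p$pG2[s_idx] / (1 - p$pG2[s_idx]))
    ll <- sum(stats::dnorm(y, mu, p$theta, log = TRUE))
    lp <- ll +
      sum(stats::dnorm(p$rcd, settings$rcd_prior_mean, settings$rcd_prior_sd,
                       log = TRUE) - log(trunc_const) + log(p$rcd)) +
      sum(stats::dbeta(p$pG2, settings$pG2_prior_shape1,
                       settings$pG2_prior_shape2, log = TRUE) +
            log(p$pG2) + log1p(-p$pG2)) +
      stats::dnorm(p$theta, 0, settings$theta_prior_scale, log = TRUE) +
      log(2) + log(p$theta)
    if (!is.finite(lp)) -Inf else lp
  }

  # moment-based starting values
  p_hat <- stats::plogis(y)
  init_pg2 <- vapply(strains, function(s) {
    rows <- observations$strain == s & rmass == 0
    if (any(rows)) max(min(mean(p_hat[rows]), 0.5), 1e-3) else 0.05
  }, numeric(1))
  init_rcd <- vapply(seq_along(strains), function(i) {
    rows <- observations$strain == strains[i] & rmass > 0
    if (!any(rows)) return(1)
    est <- (p_hat[rows] / (1 - p_hat[rows]) -
              init_pg2[i] / (1 - init_pg2[i])) / rmass[rows]
    max(stats::median(est), 0.05)
  }, numeric(1))
  init <- c(log(init_rcd), stats::qlogis(init_pg2), log(0.1))

  run <- metropolis_sample(log_post, init, chains = settings$chains,
                           iter = settings$iter, warmup = settings$warmup,
                           seed = settings$seed, init_jitter = 0.2)
  # back-transform to the natural scale
  nat <- run$draws
  nat[, , seq_len(ns)] <- exp(nat[, , seq_len(ns), drop = FALSE])
  nat[, , ns + seq_len(ns)] <- stats::plogis(nat[, , ns + seq_len(ns),
                                                 drop = FALSE])
  nat[, , 2L * ns + 1L] <- exp(nat[, , 2L * ns + 1L, drop = FALSE])
  par_names <- c(sprintf("rcd[%s]", strains), sprintf("pG2[%s]", strains),
                 "theta")
  diag <- mcmc_diagnostics(nat, par_names)
  if (any(diag$rhat > 1.05, na.rm = TRUE)) {
    warning("split-R-hat > 1.05 for: ",
            paste(diag$parameter[diag$rhat > 1.05], collapse = ", "))
  }
  structure(
    list(draws = nat, parameters = par_names, strains = strains,
         diagnostics = diag, settings = settings,
         accept_rate = run$accept_rate),
    class = "cell_density_fit"
  )
}

#' @export
print.cell_density_fit <- function(x, ...) {
  cat(sprintf("cell_density_fit: %d strain(s), %d chains x %d kept draws\n",
              length(x$strains), dim(x$draws)[2], dim(x$draws)[1]))
  print(x$diagnostics, digits = 3)
  invisible(x)
}

#' Pooled posterior draws of one parameter
#'
#' @param fit A `cell_density_fit`.
#' @param parameter Parameter name as in `fit$parameters` (e.g.
#'   `"rcd[0013]"`).
#' @return Numeric vector pooling all chains.
#' @export
posterior_draws <- function(fit, parameter) {
  j <- match(parameter, fit$parameters)
  if (is.na(j)) stop("unknown parameter: ", parameter)
  as.vector(fit$draws[, , j])
}

#' Fit the dry-to-fresh mass fraction
#'
#' Bayesian regression of dry mass on fresh mass through the origin,
#' `dm ~ Normal(f_dry * m, sigma)`, fitted independently per
#' strain-by-ploidy cytotype with `f_dry ~ Uniform(0,1)` (flat) and
#' `sigma ~ HalfNormal(sigma_prior_scale)`. Under the flat slope prior the
#' posterior mean of `f_dry` coincides with the weighted least-squares slope
#' `sum(dm * m) / sum(m^2)`.
#'
#' @param observations Mass data frame (`strain`, `ploidy`, `m`, `dm`),
#'   masses in mg; at least 3 pairs per cytotype.
#' @param settings [mcmc_settings()].
#' @return Object of class `dry_mass_fit`: per-cytotype draw matrices of
#'   `f_dry` (`[draw, chain]`), `diagnostics`, and per-strain access to
#'   `rf_dry = f_dry,4n / f_dry,2n` via [rf_dry_draws()].
#' @export
fit_dry_fraction <- function(observations, settings = mcmc_settings()) {
  observations <- as.data.frame(observations)
  stopifnot(all(c("strain", "ploidy", "m", "dm") %in% names(observations)))
  if (all(observations$m == 0)) stop("all fresh masses are zero")
  if (any(observations$m <= 0) || any(observations$dm <= 0)) {
    stop("masses must be positive")
  }
  if (any(observations$dm >= observations$m)) {
    stop("dry mass must be below fresh mass")
  }
  key <- paste(observations$strain, observations$ploidy, sep = ":")
  fits <- list()
  diags <- list()
  for (k in unique(key)) {
    rows <- key == k
    if (sum(rows) < 3L) stop("cytotype ", k, " has fewer than 3 mass pairs")
    m <- observations$m[rows]
    dm <- observations$dm[rows]
    slope0 <- sum(dm * m) / sum(m^2)
    log_post <- function(u) {
      if (any(!is.finite(u))) return(-Inf)
      f <- stats::plogis(u[1])
      sigma <- exp(u[2])
      if (f <= 0 || f >= 1 || sigma <= 0 || !is.finite(sigma)) return(-Inf)
      lp <- sum(stats::dnorm(dm, f * m, sigma, log = TRUE)) +
        log(f) + log1p(-f) +                      # flat prior + Jacobian
        stats::dnorm(sigma, 0, settings$sigma_prior_scale, log = TRUE) +
        log(2) + log(sigma)
      if (!is.finite(lp)) -Inf else lp
    }
    init <- c(stats::qlogis(min(max(slope0, 1e-4), 1 - 1e-4)),
              log(max(stats::sd(dm - slope0 * m), 1e-3)))
    run <- metropolis_sample(log_post, init, chains = settings$chains,
                             iter = settings$iter, warmup = settings$warmup,
                             seed = derive_seed(settings$seed,
                                                sum(utf8ToInt(k))),
                             init_jitter = 0.2, scale0 = 0.1)
    f_draws <- stats::plogis(run$draws[, , 1, drop = TRUE])
    f_draws <- matrix(f_draws, ncol = settings$chains)
    sigma_draws <- matrix(exp(run$draws[, , 2, drop = TRUE]),
                          ncol = settings$chains)
    fits[[k]] <- list(f_dry = f_draws, sigma = sigma_draws)
    d <- mcmc_diagnostics(run$draws, c("u_f", "u_sigma"))
    diags[[k]] <- data.frame(
      cytotype = k,
      parameter = c("f_dry", "sigma"),
      mean = c(mean(f_draws), mean(sigma_draws)),
      sd = c(stats::sd(as.vector(f_draws)), stats::sd(as.vector(sigma_draws))),
      rhat = d$rhat, ess = d$ess,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  diagnostics <- do.call(rbind, diags)
  rownames(diagnostics) <- NULL
  if (any(diagnostics$rhat > 1.05, na.rm = TRUE)) {
    warning("split-R-hat > 1.05 in dry-mass fit")
  }
  structure(list(fits = fits, diagnostics = diagnostics,
                 settings = settings),
            class = "dry_mass_fit")
}

#' @export
print.dry_mass_fit <- function(x, ...) {
  cat(sprintf("dry_mass_fit: %d cytotype(s)\n", length(x$fits)))
  print(x$diagnostics, digits = 3)
  invisible(x)
}

#' Pooled posterior draws of f_dry for one cytotype
#' @param fit A `dry_mass_fit`.
#' @param strain,ploidy Cytotype.
#' @return Numeric vector of pooled draws.
#' @export
f_dry_draws <- function(fit, strain, ploidy) {
  k <- paste(strain, ploidy, sep = ":")
  if (!k %in% names(fit$fits)) stop("no fit for cytotype ", k)
  as.vector(fit$fits[[k]]$f_dry)
}

#' Posterior draws of the tetraploid:diploid dry-fraction ratio
#'
#' `rf_dry = f_dry,4n / f_dry,2n`, with the two cytotypes' draws paired by
#' position (the fits are independent, so positional pairing is an arbitrary
#' but fixed coupling of two independent posteriors).
#'
#' @param fit A `dry_mass_fit`.
#' @param strain Strain label.
#' @return Numeric vector of rf_dry draws.
#' @export
rf_dry_draws <- function(fit, strain) {
  f_dry_draws(fit, strain, "4n") / f_dry_draws(fit, strain, "2n")
}

#' Combine cell-density and dry-fraction posteriors into rcd_dm draws
#'
#' The relative cell density per dry mass is `rcd_dm = rcd / rf_dry`. The
#' draws are combined as the full Cartesian product of `n_draws` draws from
#' each posterior (`n_draws^2` ratios), or pairwise (`n_draws` ratios) with
#' `paired = TRUE`; the mean is the same in expectation either way.
#'
#' @param cell A `cell_density_fit`, or a numeric vector of rcd draws.
#' @param mass A `dry_mass_fit`, or a numeric vector of rf_dry draws.
#' @param n_draws Draws taken from each posterior (evenly spaced through the
#'   pooled post-warm-up draws, so the subset is deterministic).
#' @param paired Pair draws positionally instead of crossing them.
#' @param strain Required when `cell` is a fit with several strains and a
#'   single strain's draws are wanted; with fit inputs and `strain = NULL`
#'   a named list over strains is returned.
#' @return Numeric vector of rcd_dm draws, or a named list of such vectors.
#' @export
combine_rcd_dm <- function(cell, mass, n_draws = 500L, paired = FALSE,
                           strain = NULL) {
  if (is.numeric(cell) && is.numeric(mass)) {
    return(combine_draw_vectors(cell, mass, n_draws, paired))
  }
  stopifnot(inherits(cell, "cell_density_fit"), inherits(mass, "dry_mass_fit"))
  strains <- if (is.null(strain)) cell$strains else strain
  out <- lapply(strains, function(s) {
    combine_draw_vectors(posterior_draws(cell, sprintf("rcd[%s]", s)),
                         rf_dry_draws(mass, s), n_draws, paired)
  })
  names(out) <- strains
  if (length(strains) == 1L && !is.null(strain)) out[[1L]] else out
}

combine_draw_vectors <- function(rcd, rf, n_draws, paired) {
  if (length(rcd) < n_draws || length(rf) < n_draws) {
    stop("insufficient posterior draws: need at least ", n_draws)
  }
  take <- function(v) v[round(seq(1L, length(v), length.out = n_draws))]
  rcd <- take(rcd)
  rf <- take(rf)
  if (any(rf <= 0)) stop("rf_dry draws must be positive")
  if (paired) rcd / rf else as.vector(outer(rcd, rf, "/"))
}

#' Pair-presence filter for fold-change estimation
#'
#' Before estimating a strain's tetraploid:diploid fold changes the
#' unfiltered table is reduced to the features detected (abundance > 0,
#' non-missing) in every sample — both cytotypes — of that strain, so the
#' subsequent plain log2 transform is defined everywhere. The returned table
#' is restricted to the strain's non-QC samples.
#'
#' @param unfiltered_table Raw-scale [feature_table()].
#' @param strain Strain label.
#' @return A raw-scale [feature_table()] of the strain's samples and its
#'   everywhere-present features.
#' @export
pair_presence_filter <- function(unfiltered_table, strain) {
  stopifnot(inherits(unfiltered_table, "feature_table"))
  assert_raw(unfiltered_table)
  bio <- drop_qc(unfiltered_table)
  rows <- bio$sample_meta$strain == strain
  if (!any(rows)) stop("unknown strain: ", strain)
  bio$abundances <- bio$abundances[rows, , drop = FALSE]
  bio$sample_meta <- bio$sample_meta[rows, , drop = FALSE]
  keep <- colSums(!is.na(bio$abundances) & bio$abundances > 0) ==
    nrow(bio$abundances)
  subset_features(bio, keep)
}

#' Plain log2 transform of a strictly positive table
#'
#' Used after [pair_presence_filter()], which guarantees positivity, so no
#' +1 offset is needed.
#'
#' @param table Raw-scale [feature_table()] with all abundances > 0.
#' @return The table on the log2 scale.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  assert_raw(table)
  if (any(is.na(table$abundances)) || any(table$abundances <= 0)) {
    stop("log2_transform requires strictly positive abundances; run pair_presence_filter first")
  }
  table$abundances <- log2(table$abundances)
  table$log_transformed <- TRUE
  table
}

#' Convert per-dry-mass fold changes to per-cell fold changes
#'
#' `FCdm = 2^lfc` is the tetraploid:diploid fold change per dry mass;
#' dividing by the posterior mean of `rcd_dm` (cells per dry mass,
#' tetraploid:diploid) converts it to the per-cell fold change
#' `FCcell = FCdm / mean(rcd_dm)`. Because the conversion is one positive
#' scalar, `median(FCcell) = median(FCdm) / mean(rcd_dm)` exactly.
#'
#' @param lfc Named per-feature log2 fold changes (4n vs 2n) from
#'   [log2_fold_changes()] on the pair-presence-filtered table.
#' @param rcd_dm Numeric vector of rcd_dm posterior draws for the strain
#'   (see [combine_rcd_dm()]), or a single pre-computed mean.
#' @return List of class `fold_change_result`: `features` data frame
#'   (`feature_id`, `lfc`, `FCdm`, `FCcell`, `dosage_class`),
#'   `mean_rcd_dm`, `median_FCdm`, `median_FCcell`, and `class_proportions`.
#' @export
fc_per_cell <- function(lfc, rcd_dm) {
  if (length(lfc) == 0L) stop("empty feature set")
  if (any(!is.finite(lfc))) stop("non-finite log fold changes")
  mean_rcd_dm <- mean(rcd_dm)
  if (!is.finite(mean_rcd_dm) || mean_rcd_dm <= 0) {
    stop("mean rcd_dm must be positive")
  }
  fcdm <- 2^lfc
  fccell <- fcdm / mean_rcd_dm
  cls <- classify_dosage(fccell)
  structure(
    list(
      features = data.frame(
        feature_id = if (is.null(names(lfc))) seq_along(lfc) else names(lfc),
        lfc = as.numeric(lfc), FCdm = as.numeric(fcdm),
        FCcell = as.numeric(fccell), dosage_class = cls$labels,
        stringsAsFactors = FALSE, row.names = NULL
      ),
      mean_rcd_dm = mean_rcd_dm,
      median_FCdm = stats::median(fcdm),
      median_FCcell = stats::median(fccell),
      class_proportions = cls$proportions
    ),
    class = "fold_change_result"
  )
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf(
    "fold_change_result: %d features | median FCdm %.3f -> median FCcell %.3f (mean rcd_dm %.3f)\n",
    nrow(x$features), x$median_FCdm, x$median_FCcell, x$mean_rcd_dm))
  print(round(x$class_proportions, 3))
  invisible(x)
}

#' Classify per-cell fold changes into dosage-response categories
#'
#' `FCcell = 1` is full dosage compensation (per-cell abundance unchanged
#' despite doubled dosage) and `FCcell = 2` a 1:1 dosage effect. Values
#' below 1 are overcompensation (negative dosage effect), values in `[1, 2]`
#' partial-to-full compensation, and values above 2 positive dosage effects.
#'
#' @param fccell Non-negative per-cell fold changes.
#' @return List with `labels` (per value: `overcompensation`,
#'   `full_compensation`, `partial_compensation`, `one_to_one_dosage`,
#'   `positive_dosage_effect`) and `proportions` over the three regions
#'   `FCcell < 1`, `1 <= FCcell <= 2`, `FCcell > 2`.
#' @export
classify_dosage <- function(fccell) {
  stopifnot(all(fccell >= 0))
  labels <- character(length(fccell))
  labels[fccell < 1] <- "overcompensation"
  labels[fccell == 1] <- "full_compensation"
  labels[fccell > 1 & fccell < 2] <- "partial_compensation"
  labels[fccell == 2] <- "one_to_one_dosage"
  labels[fccell > 2] <- "positive_dosage_effect"
  proportions <- c(
    overcompensation = mean(fccell < 1),
    partial_to_full = mean(fccell >= 1 & fccell <= 2),
    positive_dosage = mean(fccell > 2)
  )
  list(labels = labels, proportions = proportions)
}
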