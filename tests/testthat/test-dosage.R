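test_that("predict_p4n reproduces the closed-form limits", {
  # intercept-only limit: p = pG2 for any rcd
  expect_equal(predict_p4n(rcd = 3, pG2 = 0.07, rmass = 0), 0.07)
  # unit odds with vanishing pG2: p = 1/2
  expect_equal(predict_p4n(rcd = 1, pG2 = 1e-15, rmass = 1), 0.5,
               tolerance = 1e-12)
  # hand evaluation: odds = 0.5*2 + (1/11)/(10/11) = 1.1 -> p = 1.1/2.1
  expect_equal(predict_p4n(rcd = 0.5, pG2 = 1 / 11, rmass = 2), 1.1 / 2.1)
  # forward/inverse consistency
  p <- predict_p4n(0.62, 0.04, 1.3)
  expect_equal(qlogis(p) - log(0.62 * 1.3 + 0.04 / 0.96), 0)
})

test_that("model1_loglik matches per-observation normal densities", {
  obs1 <- data.frame(strain = "S", rmass = 1, count_2C = 2500, count_4C = 2500)
  # mean exactly at the observed logit: density reduces to the normalizer
  p_hat <- (2500 + 0.5) / 5001
  y <- qlogis(p_hat)
  # choose rcd so that mu = y with pG2 tiny
  pg2 <- 1e-9
  rcd <- (exp(y) - pg2 / (1 - pg2))
  theta <- 0.3
  ll <- model1_loglik(list(rcd = c(S = rcd), pG2 = c(S = pg2), theta = theta),
                      obs1)
  expect_equal(ll, -0.5 * log(2 * pi * theta^2))
  # doubling theta at zero residual lowers the log-likelihood by ln 2
  ll2 <- model1_loglik(list(rcd = c(S = rcd), pG2 = c(S = pg2),
                            theta = 2 * theta), obs1)
  expect_equal(ll - ll2, log(2))
  # non-finite or out-of-domain parameters give -Inf
  expect_identical(model1_loglik(list(rcd = c(S = -1), pG2 = c(S = 0.1),
                                      theta = 1), obs1), -Inf)
  expect_identical(model1_loglik(list(rcd = c(S = NA), pG2 = c(S = 0.1),
                                      theta = 1), obs1), -Inf)
})

test_that("model1_loglik sums term-by-term over observations", {
  set.seed(10)
  obs <- data.frame(
    strain = c("A", "A", "B", "B", "B"),
    rmass = c(0, 1.2, 0.8, 0, 2.0),
    count_2C = c(4700, 3000, 3300, 4600, 2000),
    count_4C = c(300, 2000, 1700, 400, 3000)
  )
  params <- list(rcd = c(A = 0.6, B = 0.5), pG2 = c(A = 0.05, B = 0.08),
                 theta = 0.2)
  brute <- 0
  for (i in seq_len(nrow(obs))) {
    p_hat <- (obs$count_4C[i] + 0.5) / (obs$count_2C[i] + obs$count_4C[i] + 1)
    mu <- log(params$rcd[[obs$strain[i]]] * obs$rmass[i] +
                params$pG2[[obs$strain[i]]] / (1 - params$pG2[[obs$strain[i]]]))
    brute <- brute + dnorm(qlogis(p_hat), mu, params$theta, log = TRUE)
  }
  expect_equal(model1_loglik(params, obs), brute)
})

test_that("cell-density fit recovers simulated parameters and converges", {
  cfg <- sim_config(seed = 314, n_strains = 2, strains = c("A", "B"),
                    true_rcd = c(A = 0.55, B = 0.65),
                    true_pG2 = c(A = 0.05, B = 0.08), true_theta = 0.05)
  obs <- simulate_flow_observations(cfg, study_flow_design(cfg))
  fit <- fit_cell_density(obs, mcmc_settings(seed = 314))
  for (s in c("A", "B")) {
    expect_lt(abs(mean(posterior_draws(fit, sprintf("rcd[%s]", s))) -
                    cfg$true_rcd[[s]]), 0.08)
    expect_lt(abs(mean(posterior_draws(fit, sprintf("pG2[%s]", s))) -
                    cfg$true_pG2[[s]]), 0.03)
  }
  expect_true(all(fit$diagnostics$rhat < 1.05))
  expect_true(all(fit$diagnostics$ess > 50))
  # MAP from a dense grid search as an independent oracle for rcd[A]
  grid_rcd <- seq(0.4, 0.8, by = 0.002)
  obsA <- obs[obs$strain == "A", ]
  pg2_hat <- mean(posterior_draws(fit, "pG2[A]"))
  theta_hat <- mean(posterior_draws(fit, "theta"))
  prof <- vapply(grid_rcd, function(r)
    model1_loglik(list(rcd = c(A = r), pG2 = c(A = pg2_hat),
                       theta = theta_hat), obsA), numeric(1))
  expect_lt(abs(grid_rcd[which.max(prof)] -
                  mean(posterior_draws(fit, "rcd[A]"))), 0.03)
})

test_that("posterior is invariant to observation order", {
  cfg <- sim_config(seed = 9, n_strains = 2, strains = c("A", "B"))
  obs <- simulate_flow_observations(cfg, study_flow_design(cfg))
  fit1 <- fit_cell_density(obs, mcmc_settings(seed = 5))
  fit2 <- fit_cell_density(obs[rev(seq_len(nrow(obs))), ],
                           mcmc_settings(seed = 5))
  # same likelihood, same seed stream, same moment-based inits -> same draws
  expect_equal(fit1$draws, fit2$draws, tolerance = 1e-12)
})

test_that("a missing pure-diploid stratum only warns", {
  cfg <- sim_config(seed = 12, n_strains = 1, strains = "A",
                    true_rcd = c(A = 0.6), true_pG2 = c(A = 0.05))
  design <- data.frame(strain = "A", rmass = runif(8, 0.5, 2))
  obs <- simulate_flow_observations(cfg, design)
  w <- capture_warnings(
    fit_cell_density(obs, mcmc_settings(iter = 200, warmup = 100)))
  expect_true(any(grepl("weakly identified", w)))
})

test_that("flat-prior dry-fraction posterior matches the closed-form slope", {
  # two points (10,1), (20,1): slope = 30/500 = 0.06
  obs <- data.frame(strain = "A", ploidy = "2n",
                    m = c(10, 20, 15), dm = c(1, 1, 1))
  fit <- fit_dry_fraction(obs, mcmc_settings(seed = 2))
  closed <- sum(obs$dm * obs$m) / sum(obs$m^2)
  draws <- f_dry_draws(fit, "A", "2n")
  mcse <- sd(draws) / sqrt(ess(matrix(draws, ncol = 2)))
  expect_lt(abs(mean(draws) - closed), 3 * mcse)
  # noise-free line through the origin concentrates at the true slope
  obs0 <- data.frame(strain = "A", ploidy = "4n", m = c(100, 200, 300),
                     dm = 0.05 * c(100, 200, 300) + c(1e-4, -1e-4, 0))
  fit0 <- fit_dry_fraction(obs0, mcmc_settings(seed = 3))
  expect_lt(abs(mean(f_dry_draws(fit0, "A", "4n")) - 0.05), 1e-3)
})

test_that("dry-fraction recovery over repeated simulated datasets", {
  hits <- 0L
  for (rep in 1:10) {
    cfg <- sim_config(seed = 4000 + rep, mass_noise_sd = 0.5,
                      true_f_dry = stats::setNames(
                        rep(0.04, 8),
                        paste(rep(c("0013", "9242", "9316", "9346"), each = 2),
                              c("2n", "4n"), sep = ":")))
    obs <- simulate_mass_observations(
      cfg, exp(seq(log(28), log(909), length.out = 12)), "0013", "2n")
    fit <- fit_dry_fraction(obs, mcmc_settings(seed = rep, iter = 1000,
                                               warmup = 500))
    if (abs(mean(f_dry_draws(fit, "0013", "2n")) - 0.04) < 0.005) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("combine_rcd_dm enumerates the Cartesian ratios", {
  rcd <- c(0.5, 0.6, 0.7)
  rf <- c(0.8, 1.0, 1.25)
  got <- combine_rcd_dm(rcd, rf, n_draws = 3)
  brute <- as.vector(vapply(rf, function(b) rcd / b, numeric(3)))
  expect_equal(sort(got), sort(brute))
  expect_length(got, 9)
  # paired mode divides positionally
  expect_equal(combine_rcd_dm(rcd, rf, n_draws = 3, paired = TRUE), rcd / rf)
  # degenerate posteriors: all ratios identical
  expect_true(all(combine_rcd_dm(rep(0.6, 4), rep(1.2, 4), n_draws = 4) == 0.5))
  # rf_dry of one leaves the rcd distribution untouched
  expect_equal(sort(combine_rcd_dm(rcd, rep(1, 3), n_draws = 3)),
               rep(sort(rcd), each = 3))
  expect_error(combine_rcd_dm(rcd, rf, n_draws = 10), "insufficient")
})

test_that("pair-presence filter retains only everywhere-present features", {
  vals <- cbind(c(1, 2, 3, 4, 5, 6),     # all present
                c(1, 0, 3, 4, 5, 6),     # one zero in 2n
                c(1, 2, 3, 4, NA, 6),    # one missing in 4n
                c(2, 2, 2, 0, 0, 0))     # absent cytotype
  tab <- make_table(ifelse(is.na(vals), NA, vals), strains = "S1", n_rep = 3L)
  out <- pair_presence_filter(tab, "S1")
  expect_identical(feature_ids(out), "F0001")
  # brute force on a random zero pattern
  set.seed(30)
  vals10 <- matrix(rexp(60), nrow = 6)
  vals10[sample(60, 12)] <- 0
  tab10 <- make_table(vals10, strains = "S1", n_rep = 3L)
  out10 <- pair_presence_filter(tab10, "S1")
  expect_identical(feature_ids(out10),
                   feature_ids(tab10)[colSums(vals10 > 0) == 6])
  expect_false(out10$log_transformed)
  expect_true(all(out10$sample_meta$strain == "S1"))
})

test_that("per-cell conversion reproduces the published median pairs", {
  # the two printed medians: FCdm 0.616 -> FCcell 0.97 and 1.436 -> 2.222,
  # each via the implied mean rcd_dm through the real code path
  set.seed(41)
  spread <- function(center) {
    center + c(-abs(rnorm(250)) - 0.01, 0, abs(rnorm(250)) + 0.01)
  }
  lfc <- spread(log2(0.616))
  res <- fc_per_cell(stats::setNames(lfc, paste0("f", 1:501)),
                     rcd_dm = 0.616 / 0.97)
  expect_equal(res$median_FCdm, 0.616)
  expect_equal(res$median_FCcell, 0.97)
  lfc2 <- spread(log2(1.436))
  res2 <- fc_per_cell(stats::setNames(lfc2, paste0("f", 1:501)),
                      rcd_dm = 1.436 / 2.222)
  expect_equal(res2$median_FCdm, 1.436)
  expect_equal(res2$median_FCcell, 2.222)
})

test_that("the median identity holds to machine precision", {
  for (seed in 1:5) {
    set.seed(seed)
    lfc <- rnorm(101, 0, 1)
    draws <- rlnorm(500, log(0.65), 0.1)
    res <- fc_per_cell(lfc, draws)
    expect_identical(res$median_FCcell,
                     median(2^lfc) / mean(draws))
    expect_true(all(res$features$FCdm >= 0 & res$features$FCcell >= 0))
  }
  expect_error(fc_per_cell(numeric(0), 0.6), "empty")
})

test_that("dosage classes split at 1 and 2 with labelled boundaries", {
  cls <- classify_dosage(c(0.5, 1, 1.5, 2, 3))
  expect_equal(cls$labels,
               c("overcompensation", "full_compensation",
                 "partial_compensation", "one_to_one_dosage",
                 "positive_dosage_effect"))
  expect_equal(unname(cls$proportions), c(1 / 5, 3 / 5, 1 / 5))
})

test_that("rcd_dm draws are positive and shift with rf_dry direction", {
  rcd <- rlnorm(100, log(0.6), 0.05)
  shrunk <- combine_rcd_dm(rcd, rep(0.8, 100), n_draws = 100, paired = TRUE)
  expect_true(all(shrunk > 0))
  expect_gt(mean(shrunk), mean(rcd))  # rf_dry < 1 raises rcd_dm
})
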