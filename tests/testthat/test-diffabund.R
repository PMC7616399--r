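# independent per-feature aov oracle for all three terms
anova_raw_p <- function(tab) {
  meta <- tab$sample_meta
  ps <- t(apply(tab$abundances, 2, function(v) {
    a <- anova(lm(v ~ strain * ploidy, data = meta))
    a$`Pr(>F)`[1:3]
  }))
  list(strain = unname(ps[, 1]), ploidy = unname(ps[, 2]),
       interaction = unname(ps[, 3]))
}

log_table <- function(values, ...) {
  tab <- make_table(2^values, ...)
  tab$abundances[, ] <- values
  tab$log_transformed <- TRUE
  tab
}

test_that("strain-specific lfc is the difference of log2 group means", {
  # identical means -> 0; raw {8,8} vs {2,2} -> log2 lfc of 2
  vals <- log2(cbind(c(2, 2, 8, 8), c(5, 5, 5, 5)))
  tab <- log_table(vals, strains = "S1", n_rep = 2L)
  lfc <- log2_fold_changes(tab, strain = "S1")
  expect_equal(unname(lfc), c(2, 0))
})

test_that("lfc matches a brute-force per-feature loop and is antisymmetric", {
  set.seed(21)
  tab <- random_table(12, strains = c("A", "B"), n_rep = 4L, seed = 21)
  ltab <- log2p1_normalize(tab)
  lfc <- log2_fold_changes(ltab, strain = "A")
  meta <- ltab$sample_meta
  oracle <- vapply(seq_len(12), function(j) {
    v <- ltab$abundances[, j]
    mean(v[meta$strain == "A" & meta$ploidy == "4n"]) -
      mean(v[meta$strain == "A" & meta$ploidy == "2n"])
  }, numeric(1))
  expect_equal(unname(lfc), oracle)
  # swapping ploidy labels negates the lfc exactly
  flipped <- ltab
  flipped$sample_meta$ploidy <- ifelse(flipped$sample_meta$ploidy == "2n",
                                       "4n", "2n")
  expect_equal(log2_fold_changes(flipped, strain = "A"), -lfc)
  # ALL-strain lfc equals the ploidy coefficient of the additive model
  all_lfc <- log2_fold_changes(ltab, strain = "ALL")
  fit <- lm(ltab$abundances[, 3] ~ strain + ploidy, data = meta)
  expect_equal(unname(all_lfc[3]), unname(coef(fit)["ploidy4n"]))
})

test_that("contrast t-tests agree with stats::t.test and limma's lfc", {
  tab <- random_table(15, strains = c("A", "B"), n_rep = 4L, seed = 5)
  ltab <- log2p1_normalize(tab)
  res <- contrast_tests(ltab)
  resA <- res[res$contrast == "A", ]
  meta <- ltab$sample_meta
  for (j in c(1, 7, 15)) {
    v <- ltab$abundances[meta$strain == "A", j]
    pl <- meta$ploidy[meta$strain == "A"]
    ref <- t.test(v[pl == "4n"], v[pl == "2n"], var.equal = TRUE)
    expect_equal(resA$p[j], ref$p.value)
    expect_equal(resA$lfc[j], unname(diff(rev(ref$estimate))))
  }
  design <- model.matrix(~ strain + ploidy, data = meta)
  lfit <- limma::lmFit(t(ltab$abundances), design)
  gen <- res[res$contrast == "general", ]
  expect_equal(gen$lfc, unname(lfit$coefficients[, "ploidy4n"]),
               tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up chain", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.9)
  expect_equal(p.adjust(p, "BH"), bh_brute(p))
  expect_equal(p.adjust(p, "BH")[1], min(1, min(5 * p / rank(p))))
  # monotone in raw p, adjusted >= raw, within [0,1]
  set.seed(1)
  for (i in 1:5) {
    q <- runif(10)
    adj <- p.adjust(q, "BH")
    expect_equal(adj, bh_brute(q))
    expect_true(all(adj >= q & adj <= 1))
    expect_true(all(diff(adj[order(q)]) >= -1e-12))
  }
})

test_that("contrast results satisfy their contracts", {
  tab <- random_table(40, strains = c("A", "B"), n_rep = 4L, seed = 9)
  res <- contrast_tests(log2p1_normalize(tab))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_setequal(unique(res$contrast), c("A", "B", "general"))
  # zero-variance feature: p = 1 with a warning
  tab$abundances[, 2] <- 3
  w <- capture_warnings(res0 <- contrast_tests(log2p1_normalize(tab)))
  expect_true(all(grepl("zero-variance", w)))
  expect_true(all(res0$p[res0$feature_id == feature_ids(tab)[2]] == 1))
})

test_that("two-way ANOVA flags match per-feature aov on a small table", {
  cfg <- sim_config(seed = 31, n_strains = 2, strains = c("A", "B"),
                    n_replicates = 4, n_features = 25, n_qc = 0)
  tab <- log2p1_normalize(simulate_feature_table(cfg, "ESI-"))
  cls <- two_way_anova_classify(tab)
  meta <- tab$sample_meta
  for (j in c(2, 11, 25)) {
    a <- anova(lm(tab$abundances[, j] ~ strain * ploidy, data = meta))
    raw_p <- a$`Pr(>F)`[1:3]
    # recompute this feature's adjusted flags from all raw p-values
    X <- list(~ 1, ~ strain, ~ strain + ploidy, ~ strain * ploidy)
    expect_equal(cls$flags$strain[j],
                 p.adjust(anova_raw_p(tab)$strain, "BH")[j] < 0.05)
  }
  expect_equal(sum(cls$venn), 25)
})

test_that("ANOVA term p-values equal the aov oracle across features", {
  cfg <- sim_config(seed = 8, n_strains = 2, strains = c("A", "B"),
                    n_replicates = 3, n_features = 12, n_qc = 0,
                    frac_ploidy_specific = 0)
  tab <- log2p1_normalize(simulate_feature_table(cfg, "ESI-"))
  oracle <- anova_raw_p(tab)
  cls <- two_way_anova_classify(tab, alpha = 0.05)
  expect_equal(cls$flags$strain,
               p.adjust(oracle$strain, "BH") < 0.05)
  expect_equal(cls$flags$ploidy,
               p.adjust(oracle$ploidy, "BH") < 0.05)
  expect_equal(cls$flags$interaction,
               p.adjust(oracle$interaction, "BH") < 0.05)
})

test_that("strain-only data rarely flags ploidy or interaction", {
  cfg <- sim_config(seed = 17, n_strains = 4, n_replicates = 8,
                    n_features = 400, strain_effect_sd = 1.5,
                    ploidy_effect_sd = 0, interaction_effect_sd = 0,
                    noise_sd = 0.5, frac_ploidy_specific = 0, n_qc = 0)
  tab <- log2p1_normalize(simulate_feature_table(cfg, "ESI-"))
  cls <- two_way_anova_classify(tab)
  expect_gte(mean(!cls$flags$ploidy), 0.95)
  expect_gte(mean(!cls$flags$interaction), 0.95)
})

test_that("interaction-only data concentrates in the interaction region", {
  cfg <- sim_config(seed = 18, n_strains = 4, n_replicates = 8,
                    n_features = 400, strain_effect_sd = 0,
                    ploidy_effect_sd = 0, interaction_effect_sd = 1.5,
                    noise_sd = 0.3, frac_ploidy_specific = 0, n_qc = 0)
  tab <- log2p1_normalize(simulate_feature_table(cfg, "ESI-"))
  cls <- two_way_anova_classify(tab)
  with_int <- cls$flags$interaction
  expect_gt(mean(with_int), 0.5)
  regions <- cls$venn[c("interaction_only", "strain_interaction",
                        "ploidy_interaction", "all_three")]
  expect_gt(sum(regions), sum(cls$venn[c("strain_only", "ploidy_only",
                                         "strain_ploidy")]))
})

test_that("constant features carry no flags and unbalance is refused", {
  vals <- matrix(4, nrow = 16, ncol = 3)
  tab <- log_table(vals, strains = c("A", "B"), n_rep = 4L)
  cls <- two_way_anova_classify(tab)
  expect_false(any(unlist(cls$flags[-1])))
  unb <- tab
  unb$abundances <- unb$abundances[-1, ]
  unb$sample_meta <- unb$sample_meta[-1, ]
  expect_error(two_way_anova_classify(unb), "unbalanced")
})

test_that("ploidy-specific calls require complete absence and presence", {
  vals <- cbind(c(0, 0, 0, 5, 6, 7),   # absent 2n, present 4n
                c(1, 2, 3, 0, 0, 0),   # present 2n, absent 4n
                c(0, 2, 0, 5, 6, 7),   # one positive in "absent" side
                c(1, 2, 3, 4, 5, 6))   # present everywhere
  tab <- make_table(vals, strains = "S1", n_rep = 3L)
  calls <- ploidy_specific_features(tab, "S1")
  expect_equal(calls$call,
               c("absent_in_2n_present_in_4n", "present_in_2n_absent_in_4n",
                 "not_specific", "not_specific"))
})

test_that("designed structural zeros are recovered at the simulated rate", {
  cfg <- sim_config(seed = 23, n_features = 2000, frac_ploidy_specific = 0.05,
                    n_qc = 0)
  tab <- simulate_feature_table(cfg, "ESI-")
  recovered <- unique(unlist(lapply(cfg$strains, function(s) {
    calls <- ploidy_specific_features(tab, s)
    calls$feature_id[calls$call != "not_specific"]
  })))
  expected <- round(0.05 * 2000)
  interval <- qbinom(c(0.025, 0.975), 2000, 0.05)
  expect_gte(length(recovered), interval[1])
  expect_lte(length(recovered), interval[2])
  expect_setequal(recovered, attr(tab, "ploidy_specific_truth")$feature_id)
})

test_that("UpSet cells match brute-force set algebra and sum to the union", {
  set.seed(77)
  universe <- sprintf("F%02d", 1:50)
  strains <- c("W", "X", "Y", "Z")
  calls <- lapply(strains, function(s) {
    daf <- runif(50) < 0.3
    data.frame(feature_id = universe, daf = daf,
               direction = sample(c("up_in_4n", "down_in_4n"), 50,
                                  replace = TRUE),
               stringsAsFactors = FALSE)
  })
  names(calls) <- strains
  res <- daf_intersections(calls)
  for (dir in c("up", "down")) {
    dirlab <- if (dir == "up") "up_in_4n" else "down_in_4n"
    sets <- lapply(calls, function(d)
      d$feature_id[d$daf & d$direction == dirlab])
    brute <- brute_upset(sets, universe)
    cells <- res[[dir]]$cells
    expect_equal(unname(cells[names(brute)]), unname(as.integer(brute)))
    expect_equal(sum(cells), length(unique(unlist(sets))))
    expect_equal(res[[dir]]$totals, vapply(sets, length, integer(1)))
  }
})

test_that("degenerate UpSet cases behave", {
  universe <- c("a", "b", "c")
  mk <- function(daf) data.frame(feature_id = universe, daf = daf,
                                 direction = "up_in_4n",
                                 stringsAsFactors = FALSE)
  shared <- list(A = mk(c(TRUE, FALSE, FALSE)), B = mk(c(TRUE, FALSE, FALSE)),
                 C = mk(c(TRUE, FALSE, FALSE)), D = mk(c(TRUE, FALSE, FALSE)))
  res <- daf_intersections(shared)
  expect_equal(unname(res$up$cells[["A+B+C+D"]]), 1)
  expect_equal(sum(res$up$cells), 1)
  disjoint <- list(A = mk(c(TRUE, FALSE, FALSE)),
                   B = mk(c(FALSE, TRUE, FALSE)))
  res2 <- daf_intersections(disjoint)
  expect_equal(unname(res2$up$cells[["A"]]), 1)
  expect_equal(unname(res2$up$cells[["B"]]), 1)
  expect_equal(unname(res2$up$cells[["A+B"]]), 0)
  mismatched <- list(A = mk(c(TRUE, FALSE, FALSE)),
                     B = mk(c(TRUE, FALSE, FALSE))[1:2, ])
  expect_error(daf_intersections(mismatched), "universe")
})
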