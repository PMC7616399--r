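#' Per-feature tetraploid:diploid log2 fold changes
#'
#' For a single strain the log fold change is the difference of tetraploid
#' and diploid group means of the log2 abundances. For `strain = "ALL"` it is
#' the ploidy main-effect coefficient of an additive strain + ploidy linear
#' model fitted per feature.
#'
#' @param table A log-scale [feature_table()] (values already log2; see
#'   [log2p1_normalize()] or [pair_presence_filter()] + `log2`).
#' @param strain One strain label, or `"ALL"` for the cross-strain main
#'   effect.
#' @return Named numeric vector of per-feature lfc (4n minus 2n).
#' @export
log2_fold_changes <- function(table, strain = "ALL") {
  stopifnot(inherits(table, "feature_table"))
  bio <- drop_qc(table)
  meta <- bio$sample_meta
  x <- bio$abundances
  if (!isTRUE(table$log_transformed)) {
    stop("log2_fold_changes expects log-scale abundances")
  }
  if (identical(strain, "ALL")) {
    check_two_cytotypes(meta)
    X <- stats::model.matrix(additive_formula(meta), data = meta)
    fit <- stats::lm.fit(X, x)
    lfc <- fit$coefficients["ploidy4n", ]
  } else {
    rows <- meta$strain == strain
    if (!any(rows)) stop("unknown strain: ", strain)
    meta <- meta[rows, , drop = FALSE]
    x <- x[rows, , drop = FALSE]
    n2 <- sum(meta$ploidy == "2n")
    n4 <- sum(meta$ploidy == "4n")
    if (n2 < 2L || n4 < 2L) stop("each cytotype needs >= 2 replicates")
    lfc <- colMeans(x[meta$ploidy == "4n", , drop = FALSE]) -
      colMeans(x[meta$ploidy == "2n", , drop = FALSE])
  }
  stats::setNames(as.numeric(lfc), feature_ids(table))
}

additive_formula <- function(meta) {
  if (length(unique(meta$strain)) > 1L) ~ strain + ploidy else ~ ploidy
}

check_two_cytotypes <- function(meta) {
  tab <- table(meta$strain, meta$ploidy)
  if (any(tab < 2L)) {
    stop("every strain needs >= 2 replicates of both cytotypes")
  }
  invisible(tab)
}

# Vectorized equal-variance two-sample t-test per column (4n vs 2n).
# Zero-variance features get p = 1 with a warning, matching the convention
# that an undefined statistic is treated as no evidence.
colwise_t_test <- function(x4, x2) {
  n4 <- nrow(x4); n2 <- nrow(x2)
  m4 <- colMeans(x4); m2 <- colMeans(x2)
  v4 <- colSums(sweep(x4, 2, m4)^2)
  v2 <- colSums(sweep(x2, 2, m2)^2)
  df <- n4 + n2 - 2L
  sp2 <- (v4 + v2) / df
  se <- sqrt(sp2 * (1 / n4 + 1 / n2))
  tstat <- (m4 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- sp2 <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature(s): p set to 1")
    p[degenerate] <- 1
    tstat[degenerate] <- 0
  }
  list(lfc = m4 - m2, t = tstat, p = p, df = df)
}

#' Differential-abundance contrasts
#'
#' Runs, per feature, a two-sided equal-variance t-test of the
#' tetraploid-diploid contrast within each strain, plus a "general" contrast
#' testing the ploidy coefficient of an additive strain + ploidy model across
#' all strains. P-values are Benjamini-Hochberg adjusted within each
#' contrast; a feature is a differentially abundant feature (DAF) when
#' `p_adj < alpha`.
#'
#' @inheritParams log2_fold_changes
#' @param alpha Adjusted-p significance cut-off.
#' @return Data frame with one row per feature x contrast: `feature_id`,
#'   `contrast` (`"general"` or a strain label), `lfc`, `p`, `p_adj`,
#'   `direction` (`up_in_4n`/`down_in_4n`), `daf` (logical).
#' @export
contrast_tests <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (!isTRUE(table$log_transformed)) {
    stop("contrast_tests expects a filtered, log-normalized table")
  }
  bio <- drop_qc(table)
  meta <- bio$sample_meta
  x <- bio$abundances
  check_two_cytotypes(meta)
  ids <- feature_ids(table)
  strains <- sort(unique(meta$strain))

  res <- vector("list", length(strains) + 1L)
  for (i in seq_along(strains)) {
    s <- strains[i]
    rows4 <- meta$strain == s & meta$ploidy == "4n"
    rows2 <- meta$strain == s & meta$ploidy == "2n"
    tt <- colwise_t_test(x[rows4, , drop = FALSE], x[rows2, , drop = FALSE])
    res[[i]] <- data.frame(
      feature_id = ids, contrast = s, lfc = tt$lfc, p = tt$p,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  # General contrast: ploidy main effect in the additive model, per-feature
  # residual variance. With a single strain the strain term drops out.
  X <- stats::model.matrix(additive_formula(meta), data = meta)
  fit <- stats::lm.fit(X, x)
  dfres <- nrow(X) - fit$rank
  rss <- colSums(fit$residuals^2)
  sigma2 <- rss / dfres
  xtxinv <- chol2inv(chol(crossprod(X)))
  j <- which(colnames(X) == "ploidy4n")
  se <- sqrt(sigma2 * xtxinv[j, j])
  beta <- fit$coefficients[j, ]
  tstat <- beta / se
  p_gen <- 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE)
  degenerate <- sigma2 <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature(s): p set to 1")
    p_gen[degenerate] <- 1
  }
  res[[length(strains) + 1L]] <- data.frame(
    feature_id = ids, contrast = "general", lfc = as.numeric(beta), p = p_gen,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- do.call(rbind, res)
  out$p_adj <- stats::ave(out$p, out$contrast,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  out$direction <- ifelse(out$lfc >= 0, "up_in_4n", "down_in_4n")
  out$daf <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Two-way strain-by-ploidy ANOVA classification
#'
#' Per feature, a fixed-effects two-way ANOVA with strain, ploidy and their
#' interaction; each term's p-values are Benjamini-Hochberg adjusted across
#' features and flagged at `p_adj < alpha`. The design must be balanced
#' (equal replicates in every strain-by-ploidy cell) so the sums of squares
#' are unambiguous; unbalanced input is refused.
#'
#' @inheritParams contrast_tests
#' @return List with `flags` (data frame: `feature_id`, logical `strain`,
#'   `ploidy`, `interaction`) and `venn` (named counts of the 7-region
#'   partition plus `none`).
#' @export
two_way_anova_classify <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (!isTRUE(table$log_transformed)) {
    stop("two_way_anova_classify expects log-normalized abundances")
  }
  bio <- drop_qc(table)
  meta <- bio$sample_meta
  x <- bio$abundances
  cells <- table(meta$strain, meta$ploidy)
  if (any(cells == 0L)) stop("missing strain x ploidy cells")
  if (length(unique(as.vector(cells))) != 1L) {
    stop("unbalanced design: two-way ANOVA classification requires equal cell sizes")
  }
  rss_of <- function(formula) {
    X <- stats::model.matrix(formula, data = meta)
    colSums(stats::lm.fit(X, x)$residuals^2)
  }
  rss0 <- rss_of(~ 1)
  rss_s <- rss_of(~ strain)
  rss_sp <- rss_of(~ strain + ploidy)
  rss_full <- rss_of(~ strain * ploidy)
  ns <- length(unique(meta$strain))
  df_s <- ns - 1L
  df_p <- 1L
  df_i <- ns - 1L
  df_e <- nrow(x) - ns * 2L
  f_p <- function(rss_red, rss_fullm, df_num) {
    fstat <- ((rss_red - rss_fullm) / df_num) / (rss_full / df_e)
    stats::pf(fstat, df_num, df_e, lower.tail = FALSE)
  }
  p_s <- f_p(rss0, rss_s, df_s)
  p_p <- f_p(rss_s, rss_sp, df_p)
  p_i <- f_p(rss_sp, rss_full, df_i)
  # constant features: zero SS everywhere -> NaN F; not significant
  const <- rss0 <= .Machine$double.eps * nrow(x)
  p_s[const] <- p_p[const] <- p_i[const] <- 1
  flags <- data.frame(
    feature_id = feature_ids(table),
    strain = stats::p.adjust(p_s, "BH") < alpha,
    ploidy = stats::p.adjust(p_p, "BH") < alpha,
    interaction = stats::p.adjust(p_i, "BH") < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  venn <- c(
    strain_only = sum(flags$strain & !flags$ploidy & !flags$interaction),
    ploidy_only = sum(!flags$strain & flags$ploidy & !flags$interaction),
    interaction_only = sum(!flags$strain & !flags$ploidy & flags$interaction),
    strain_ploidy = sum(flags$strain & flags$ploidy & !flags$interaction),
    strain_interaction = sum(flags$strain & !flags$ploidy & flags$interaction),
    ploidy_interaction = sum(!flags$strain & flags$ploidy & flags$interaction),
    all_three = sum(flags$strain & flags$ploidy & flags$interaction),
    none = sum(!flags$strain & !flags$ploidy & !flags$interaction)
  )
  list(flags = flags, venn = venn)
}

#' Ploidy-specific (presence/absence) feature calls
#'
#' A feature is ploidy-specific within a strain when it is absent (zero or
#' missing, at or below `absence_threshold`) in every replicate of one
#' cytotype and present (above the threshold) in every replicate of the
#' other. Works on the unfiltered raw table, since the quantitative filters
#' would discard exactly these qualitative signals.
#'
#' @param unfiltered_table Raw-scale [feature_table()] before any filtering.
#' @param strain Strain whose diploid-tetraploid pair is examined.
#' @param absence_threshold Intensities at or below this value count as
#'   absent (default exact zero).
#' @return Data frame `feature_id`, `call` with call one of
#'   `absent_in_2n_present_in_4n`, `present_in_2n_absent_in_4n`,
#'   `not_specific`.
#' @export
ploidy_specific_features <- function(unfiltered_table, strain,
                                     absence_threshold = 0) {
  stopifnot(inherits(unfiltered_table, "feature_table"))
  assert_raw(unfiltered_table)
  bio <- drop_qc(unfiltered_table)
  meta <- bio$sample_meta
  rows2 <- meta$strain == strain & meta$ploidy == "2n"
  rows4 <- meta$strain == strain & meta$ploidy == "4n"
  if (!any(rows2) || !any(rows4)) stop("strain lacks one of the cytotypes")
  x2 <- bio$abundances[rows2, , drop = FALSE]
  x4 <- bio$abundances[rows4, , drop = FALSE]
  absent2 <- colSums(is.na(x2) | x2 <= absence_threshold) == nrow(x2)
  absent4 <- colSums(is.na(x4) | x4 <= absence_threshold) == nrow(x4)
  present2 <- colSums(!is.na(x2) & x2 > absence_threshold) == nrow(x2)
  present4 <- colSums(!is.na(x4) & x4 > absence_threshold) == nrow(x4)
  call <- rep("not_specific", ncol(x2))
  call[absent2 & present4] <- "absent_in_2n_present_in_4n"
  call[present2 & absent4] <- "present_in_2n_absent_in_4n"
  data.frame(feature_id = feature_ids(unfiltered_table), call = call,
             stringsAsFactors = FALSE)
}

#' Intersection counts of per-strain DAF sets
#'
#' The cross-strain sharing structure of differentially abundant features,
#' as shown by an UpSet plot: for each direction separately, the number of
#' DAFs falling in each of the `2^k - 1` non-empty strain subsets
#' (exclusive cells), plus per-strain totals.
#'
#' @param calls Result of [contrast_tests()] (strain contrasts only are
#'   used), or a named list of per-strain data frames with columns
#'   `feature_id`, `daf`, `direction` over one shared feature universe.
#' @return List with `up` and `down`, each a list of `cells` (named counts,
#'   names like `"0013+9316"`) and `totals` (per-strain DAF counts).
#' @export
daf_intersections <- function(calls) {
  if (is.data.frame(calls)) {
    calls <- calls[calls$contrast != "general", , drop = FALSE]
    calls <- split(calls, calls$contrast)
  }
  strains <- names(calls)
  universe <- calls[[1L]]$feature_id
  for (s in strains) {
    if (!identical(sort(calls[[s]]$feature_id), sort(universe))) {
      stop("per-strain calls must share one feature universe")
    }
  }
  one_direction <- function(dir) {
    sets <- lapply(calls, function(d) {
      d$feature_id[d$daf & d$direction == dir]
    })
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    membership <- matrix(membership, ncol = length(strains),
                         dimnames = list(universe, strains))
    in_any <- rowSums(membership) > 0
    patt <- apply(membership, 1, function(m) paste(strains[m], collapse = "+"))
    cells <- integer(0)
    subset_names <- unlist(lapply(seq_along(strains), function(k) {
      utils::combn(strains, k, paste, collapse = "+")
    }))
    cells <- stats::setNames(integer(length(subset_names)), subset_names)
    tab <- table(patt[in_any])
    cells[names(tab)] <- as.integer(tab)
    list(cells = cells, totals = vapply(sets, length, integer(1)))
  }
  list(up = one_direction("up_in_4n"), down = one_direction("down_in_4n"))
}
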