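#' @name feature_filters
#' @title Three-step feature quality filter
#'
#' @description Untargeted metabolomics tables carry many uninformative
#' features. The filter chain removes them in three steps, each on the raw
#' intensity scale and always ignoring pooled QC samples:
#' \enumerate{
#'   \item \strong{Presence}: keep a feature only if at least one
#'     strain-by-ploidy group has it detected (abundance > 0, non-missing) in
#'     every replicate.
#'   \item \strong{RSD}: drop the fraction `frac` of features with the
#'     highest within-group relative standard deviation (sd/mean, aggregated
#'     across groups), i.e. the least repeatable features.
#'   \item \strong{IQR}: drop the fraction `frac` of features with the lowest
#'     interquartile range across all samples, i.e. the least variable,
#'     least informative features.
#' }
#' Removal counts are `ceiling(frac * N)` with ties broken by ascending
#' column index, so step counts are exactly reproducible. After filtering the
#' table is normalized with `log2(x + 1)`.
NULL

new_filter_step <- function(step, n_in, n_out, removed_ids) {
  d <- data.frame(step = step, features_in = n_in, features_out = n_out,
                  stringsAsFactors = FALSE)
  attr(d, "removed_ids") <- removed_ids
  d
}

assert_raw <- function(table) {
  if (isTRUE(table$log_transformed)) {
    stop("filters operate on raw intensities, not log-transformed data")
  }
}

#' Presence filter
#'
#' Retains the features detected in every replicate of at least one
#' strain-by-ploidy group; QC samples never count.
#'
#' @param table A raw-scale [feature_table()].
#' @return List with elements `table` (filtered) and `report` (one-row step
#'   report; removed ids in its `removed_ids` attribute).
#' @export
presence_filter <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  assert_raw(table)
  bio <- drop_qc(table)
  key <- group_key(bio$sample_meta)
  present <- !is.na(bio$abundances) & bio$abundances > 0
  keep <- rep(FALSE, ncol(present))
  for (g in unique(key)) {
    rows <- key == g
    keep <- keep | (colSums(present[rows, , drop = FALSE]) == sum(rows))
  }
  report <- new_filter_step("presence", ncol(table$abundances), sum(keep),
                            feature_ids(table)[!keep])
  list(table = subset_features(table, keep), report = report)
}

# Per-feature within-group RSD (sd/mean, n-1 denominator), aggregated across
# strain x ploidy groups. Groups with zero mean are skipped; a feature with
# every group mean zero cannot have survived the presence filter.
rsd_scores <- function(table, aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  bio <- drop_qc(table)
  key <- group_key(bio$sample_meta)
  groups <- unique(key)
  per_group <- vapply(groups, function(g) {
    x <- bio$abundances[key == g, , drop = FALSE]
    mu <- colMeans(x, na.rm = TRUE)
    sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
    ifelse(mu > 0, sdv / mu, NA_real_)
  }, numeric(ncol(bio$abundances)))
  per_group <- matrix(per_group, ncol = length(groups))
  if (any(rowSums(!is.na(per_group)) == 0L)) {
    stop("feature with zero mean in every group; run presence_filter first")
  }
  agg_fun <- switch(aggregate, mean = function(v) mean(v, na.rm = TRUE),
                    median = function(v) stats::median(v, na.rm = TRUE),
                    max = function(v) max(v, na.rm = TRUE))
  apply(per_group, 1, agg_fun)
}

#' Repeatability (RSD) filter
#'
#' Removes the `ceiling(frac * N)` features with the highest within-group
#' relative standard deviation.
#'
#' @inheritParams presence_filter
#' @param frac Fraction of features to remove, in `[0, 1)`.
#' @param aggregate How per-group RSDs combine into one score per feature.
#' @return As [presence_filter()].
#' @export
rsd_filter <- function(table, frac = 0.20,
                       aggregate = c("mean", "median", "max")) {
  stopifnot(inherits(table, "feature_table"))
  assert_raw(table)
  if (!is.numeric(frac) || frac < 0 || frac >= 1) {
    stop("`frac` must lie in [0, 1)")
  }
  bio <- drop_qc(table)
  key <- group_key(bio$sample_meta)
  if (any(table(key) < 2L)) stop("every strain x ploidy group needs >= 2 replicates")
  scores <- rsd_scores(table, aggregate)
  keep <- drop_top_frac(scores, frac, highest = TRUE)
  report <- new_filter_step("rsd", ncol(table$abundances), sum(keep),
                            feature_ids(table)[!keep])
  list(table = subset_features(table, keep), report = report)
}

#' Variability (IQR) filter
#'
#' Removes the `ceiling(frac * N)` features with the lowest interquartile
#' range (75th minus 25th linear-interpolation percentile) across all non-QC
#' samples.
#'
#' @inheritParams rsd_filter
#' @return As [presence_filter()].
#' @export
iqr_filter <- function(table, frac = 0.20) {
  stopifnot(inherits(table, "feature_table"))
  assert_raw(table)
  if (!is.numeric(frac) || frac < 0 || frac >= 1) {
    stop("`frac` must lie in [0, 1)")
  }
  bio <- drop_qc(table)
  if (nrow(bio$abundances) < 2L) stop("need >= 2 non-QC samples")
  iqrs <- apply(bio$abundances, 2, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    q[2] - q[1]
  })
  keep <- drop_top_frac(iqrs, frac, highest = FALSE)
  report <- new_filter_step("iqr", ncol(table$abundances), sum(keep),
                            feature_ids(table)[!keep])
  list(table = subset_features(table, keep), report = report)
}

# Keep all but the ceiling(frac * N) most extreme scores. Stable: ties and
# ordering resolve by ascending feature index.
drop_top_frac <- function(scores, frac, highest = TRUE) {
  n <- length(scores)
  n_drop <- ceiling(frac * n)
  if (n_drop == 0L) return(rep(TRUE, n))
  ord <- order(if (highest) -scores else scores, seq_len(n))
  keep <- rep(TRUE, n)
  keep[ord[seq_len(n_drop)]] <- FALSE
  keep
}

#' log2(x + 1) normalization
#'
#' @param table A raw-scale [feature_table()] (all abundances >= 0).
#' @return The table with every value `x` replaced by `log2(x + 1)` and
#'   `log_transformed = TRUE`.
#' @export
log2p1_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  assert_raw(table)
  if (any(table$abundances < 0, na.rm = TRUE)) stop("negative abundances")
  table$abundances <- log2(table$abundances + 1)
  table$log_transformed <- TRUE
  table
}

#' Full filter pipeline
#'
#' Presence filter, RSD filter, IQR filter, then `log2(x+1)` normalization,
#' with an audit report of per-step feature counts.
#'
#' @inheritParams rsd_filter
#' @param rsd_frac,iqr_frac Removal fractions of the two score-based steps.
#' @return List with `table` (filtered, log-normalized) and `report` (data
#'   frame of steps with `features_in`/`features_out`; per-step removed ids
#'   in the `removed_ids` attribute, a named list).
#' @export
filter_pipeline <- function(table, rsd_frac = 0.20, iqr_frac = 0.20,
                            aggregate = c("mean", "median", "max")) {
  s1 <- presence_filter(table)
  s2 <- rsd_filter(s1$table, frac = rsd_frac, aggregate = aggregate)
  s3 <- iqr_filter(s2$table, frac = iqr_frac)
  report <- rbind(s1$report, s2$report, s3$report)
  attr(report, "removed_ids") <- list(
    presence = attr(s1$report, "removed_ids"),
    rsd = attr(s2$report, "removed_ids"),
    iqr = attr(s3$report, "removed_ids")
  )
  list(table = log2p1_normalize(s3$table), report = report)
}
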