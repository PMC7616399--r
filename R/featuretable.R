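#' Construct a feature table
#'
#' A `feature_table` bundles a samples-by-features intensity matrix with the
#' per-sample design metadata of a mixed-ploidy metabolomics experiment. It is
#' the common currency of the filtering, differential-abundance, and dosage
#' stages.
#'
#' @param abundances Numeric matrix, samples in rows and features in columns.
#'   Values are raw (or log-transformed) intensities; they must be
#'   non-negative or `NA`.
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample_id`, `strain`, `ploidy` (`"2n"` or `"4n"`; `NA` allowed for QC
#'   samples), `replicate`, and logical `is_qc`.
#' @param platform Single label, conventionally one of `"ESI+"`, `"ESI-"`,
#'   `"GCMS"`.
#' @param log_transformed Logical flag recording whether the matrix is on the
#'   log2(x+1) scale. Filters insist on raw intensities.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `abundances`, `sample_meta`, `platform`, `log_transformed`.
#' @export
feature_table <- function(abundances, sample_meta, platform = "ESI-",
                          log_transformed = FALSE) {
  abundances <- as.matrix(abundances)
  if (!is.numeric(abundances)) {
    stop("`abundances` must be a numeric matrix")
  }
  if (any(abundances < 0, na.rm = TRUE)) {
    bad <- which(abundances < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample row %d, feature column %d",
                 bad[1L], bad[2L]))
  }
  sample_meta <- as.data.frame(sample_meta)
  required <- c("sample_id", "strain", "ploidy", "replicate", "is_qc")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols) > 0L) {
    stop("sample_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sample_meta) != nrow(abundances)) {
    stop("sample_meta rows must match abundance matrix rows")
  }
  bad_ploidy <- !is.na(sample_meta$ploidy) &
    !sample_meta$ploidy %in% c("2n", "4n")
  if (any(bad_ploidy)) {
    stop("ploidy labels must be '2n' or '4n' (row ",
         which(bad_ploidy)[1L], ")")
  }
  if (any(is.na(sample_meta$ploidy) & !sample_meta$is_qc)) {
    stop("missing ploidy label for a non-QC sample (row ",
         which(is.na(sample_meta$ploidy) & !sample_meta$is_qc)[1L], ")")
  }
  if (is.null(colnames(abundances))) {
    colnames(abundances) <- sprintf("F%04d", seq_len(ncol(abundances)))
  }
  if (anyDuplicated(colnames(abundances))) {
    stop("feature ids must be unique")
  }
  rownames(abundances) <- sample_meta$sample_id
  structure(
    list(abundances = abundances, sample_meta = sample_meta,
         platform = platform, log_transformed = isTRUE(log_transformed)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  m <- x$sample_meta
  cat(sprintf("feature_table: %d samples x %d features [%s%s]\n",
              nrow(x$abundances), ncol(x$abundances), x$platform,
              if (x$log_transformed) ", log2(x+1)" else ", raw"))
  grp <- table(paste(m$strain[!m$is_qc], m$ploidy[!m$is_qc]))
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  if (any(m$is_qc)) cat("  QC samples:", sum(m$is_qc), "\n")
  invisible(x)
}

#' Feature identifiers of a table
#' @param table A `feature_table`.
#' @return Character vector of feature ids in column order.
#' @export
feature_ids <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  colnames(table$abundances)
}

# Drop QC rows; error if nothing remains. Filters and tests operate on the
# biological samples only.
drop_qc <- function(table) {
  keep <- !table$sample_meta$is_qc
  if (!any(keep)) stop("table has no non-QC samples")
  table$abundances <- table$abundances[keep, , drop = FALSE]
  table$sample_meta <- table$sample_meta[keep, , drop = FALSE]
  table
}

# strain x ploidy group key per non-QC sample
group_key <- function(meta) paste(meta$strain, meta$ploidy, sep = ":")

# Subset features by id or logical/integer index, preserving order.
subset_features <- function(table, keep) {
  table$abundances <- table$abundances[, keep, drop = FALSE]
  table
}
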