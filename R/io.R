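#' @name table_io
#' @title Typed readers and writers
#' @description Feature tables travel as TSV (metadata columns `sample_id`,
#' `strain`, `ploidy`, `replicate`, `is_qc`, then one column per feature),
#' flow and mass observations as CSV, configurations as YAML/JSON, and
#' reports/manifests as JSON. Every emitted table carries `#`-prefixed
#' header lines recording the seed and a hash of the generating
#' configuration, so an output file identifies the run that produced it.
NULL

# FNV-1a over the serialized object; stable within a platform, cheap, and
# good enough to fingerprint a config in a file header.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 3L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

header_lines <- function(seed, hash) {
  c(sprintf("# seed=%s", seed), sprintf("# config_hash=%s", hash))
}

#' Write a feature table as TSV
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param seed,hash Provenance recorded in the `#` header (defaults: absent
#'   seed, hash of the table itself).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, seed = NA,
                                hash = config_hash(table)) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$sample_meta, as.data.frame(table$abundances))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header_lines(seed, hash),
               sprintf("# platform=%s log_transformed=%s", table$platform,
                       table$log_transformed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' Schema violations (missing metadata columns, bad ploidy labels, negative
#' intensities) are reported with row/column coordinates.
#'
#' @param path A file written by [write_feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  platform <- "ESI-"
  log_transformed <- FALSE
  plat_line <- grep("^# platform=", hdr, value = TRUE)
  if (length(plat_line) == 1L) {
    platform <- sub("^# platform=(\\S+).*", "\\1", plat_line)
    log_transformed <- grepl("log_transformed=TRUE", plat_line)
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         strain = "character",
                                         ploidy = "character"))
  meta_cols <- c("sample_id", "strain", "ploidy", "replicate", "is_qc")
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table TSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- df[meta_cols]
  meta$is_qc <- as.logical(meta$is_qc)
  meta$ploidy <- ifelse(meta$ploidy %in% "", NA_character_,
                        as.character(meta$ploidy))
  feat <- as.matrix(df[setdiff(names(df), meta_cols)])
  if (any(feat < 0, na.rm = TRUE)) {
    bad <- which(feat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at row %d, feature '%s'",
                 bad[1L], colnames(feat)[bad[2L]]))
  }
  feature_table(feat, meta, platform = platform,
                log_transformed = log_transformed)
}

#' Write/read flow-cytometry observations as CSV
#' @param observations Data frame from [simulate_flow_observations()].
#' @param path File path.
#' @inheritParams write_feature_table
#' @return `path` / the data frame.
#' @export
write_flow_observations <- function(observations, path, seed = NA,
                                    hash = config_hash(observations)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(seed, hash), con)
  utils::write.csv(observations, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_observations
#' @export
read_flow_observations <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(strain = "character"))
  need <- c("strain", "rmass", "count_2C", "count_4C")
  if (!all(need %in% names(df))) {
    stop("flow CSV needs columns ", paste(need, collapse = ", "))
  }
  df
}

#' Write/read fresh/dry mass observations as CSV
#' @param observations Data frame from [simulate_mass_observations()].
#' @inheritParams write_flow_observations
#' @return `path` / the data frame.
#' @export
write_mass_observations <- function(observations, path, seed = NA,
                                    hash = config_hash(observations)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(seed, hash), con)
  utils::write.csv(observations, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mass_observations
#' @export
read_mass_observations <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(strain = "character",
                                       ploidy = "character"))
  need <- c("strain", "ploidy", "m", "dm")
  if (!all(need %in% names(df))) {
    stop("mass CSV needs columns ", paste(need, collapse = ", "))
  }
  df
}

#' Write a simulation config as YAML
#' @param config A [sim_config()].
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$true_rcd <- as.list(x$true_rcd)
  x$true_pG2 <- as.list(x$true_pG2)
  x$true_f_dry <- as.list(x$true_f_dry)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read a simulation config from YAML/JSON
#' @param path File written by [write_sim_config()] (or hand-written; absent
#'   fields fall back to the [sim_config()] defaults).
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("true_rcd", "true_pG2", "true_f_dry")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  args <- x[names(x) %in% names(formals(sim_config))]
  do.call(sim_config, args)
}
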