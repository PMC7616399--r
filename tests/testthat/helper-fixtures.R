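# Small fixtures and independent brute-force oracles used across the suite.

# Feature table from an explicit matrix: n_rep replicates per strain x ploidy
# group, groups in the order given.
make_table <- function(values, strains = "S1", n_rep = NULL,
                       platform = "ESI-", qc_rows = 0L) {
  values <- as.matrix(values)
  n_groups <- 2L * length(strains)
  if (is.null(n_rep)) n_rep <- nrow(values) / n_groups
  stopifnot(nrow(values) == n_groups * n_rep)
  grid <- expand.grid(replicate = seq_len(n_rep), ploidy = c("2n", "4n"),
                      strain = strains, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$strain, grid$ploidy,
                        grid$replicate),
    strain = grid$strain, ploidy = grid$ploidy, replicate = grid$replicate,
    is_qc = FALSE, stringsAsFactors = FALSE
  )
  if (qc_rows > 0L) {
    values <- rbind(values, matrix(colMeans(values), nrow = qc_rows,
                                   ncol = ncol(values), byrow = TRUE))
    meta <- rbind(meta, data.frame(
      sample_id = sprintf("QC_%d", seq_len(qc_rows)), strain = "QC",
      ploidy = NA_character_, replicate = seq_len(qc_rows), is_qc = TRUE,
      stringsAsFactors = FALSE))
  }
  feature_table(values, meta, platform = platform)
}

# random strictly positive table with continuous (ties-free) intensities
random_table <- function(n_features, strains = c("A", "B"), n_rep = 3L,
                         seed = 1L) {
  set.seed(seed)
  n <- 2L * length(strains) * n_rep
  make_table(matrix(exp(rnorm(n * n_features, 5, 1)), nrow = n),
             strains = strains, n_rep = n_rep)
}

# Benjamini-Hochberg step-up, written independently of stats::p.adjust.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# brute-force "drop the k most extreme scores" membership
brute_keep <- function(scores, frac, highest = TRUE) {
  n_drop <- ceiling(frac * length(scores))
  if (n_drop == 0L) return(rep(TRUE, length(scores)))
  ord <- order(if (highest) -scores else scores, seq_along(scores))
  !(seq_along(scores) %in% ord[seq_len(n_drop)])
}

# brute-force per-feature presence rule: any group fully positive
brute_presence <- function(values, key) {
  apply(values, 2, function(v) {
    any(vapply(unique(key), function(g) {
      all(!is.na(v[key == g]) & v[key == g] > 0)
    }, logical(1)))
  })
}

# brute-force exclusive intersection counts over named membership sets
brute_upset <- function(sets, universe) {
  strains <- names(sets)
  patt <- vapply(universe, function(f) {
    paste(strains[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  table(patt[patt != ""])
}
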