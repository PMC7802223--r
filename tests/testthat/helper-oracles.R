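# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: explicit formulas, exhaustive enumeration, sliding
# windows.

# Pearson via the raw product-moment formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Spearman: average ranks built by counting, then the moment formula
oracle_spearman <- function(x, y) {
  rk <- function(v) vapply(v, function(vi)
    sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
  oracle_pearson(rk(x), rk(y))
}

# BH step-up by direct definition: q_i = min over thresholds t >= p_i of
# m * t / #{p <= t}, scanning every observed p as a threshold
oracle_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    ts <- p[p >= p[i]]
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t), 0)))
  }, 0)
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_sf <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)   # k >= 1 impossible; callers keep k <= min(K, n)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# seed sites by sliding a window over every offset and testing the four
# literal site strings independently, then collapsing to the maximal type
# at each 6mer-core locus
oracle_seed_sites <- function(mirna, target) {
  comp <- function(s) chartr("ACGU", "UGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  core6 <- rc(substr(mirna, 2, 7))
  m8c <- comp(substr(mirna, 8, 8))
  pats <- list("6mer" = core6,
               "7mer-A1" = paste0(core6, "A"),
               "7mer-m8" = paste0(m8c, core6),
               "8mer" = paste0(m8c, core6, "A"))
  core_off <- c("6mer" = 0L, "7mer-A1" = 0L, "7mer-m8" = 1L, "8mer" = 1L)
  rank <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)
  L <- nchar(target)
  best <- list()
  for (ty in names(pats)) {
    pl <- nchar(pats[[ty]])
    for (off in 0:(L - pl)) {
      if (substr(target, off + 1, off + pl) == pats[[ty]]) {
        locus <- off + core_off[[ty]]
        key <- as.character(locus)
        if (is.null(best[[key]]) || rank[[ty]] > rank[[best[[key]]$type]])
          best[[key]] <- list(type = ty, start = off + core_off[[ty]] -
                                (if (rank[[ty]] >= 3) 1L else 0L),
                              len = pl)
      }
    }
  }
  if (!length(best))
    return(data.frame(site_type = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(best, function(b)
    data.frame(site_type = b$type, start = b$start, length = b$len,
               stringsAsFactors = FALSE)))
  df <- df[order(df$start), , drop = FALSE]
  row.names(df) <- NULL
  df
}

random_rna_string <- function(len)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")

# small helper: a tiny CountMatrix from explicit values
tiny_counts <- function(values, groups = rep(c("CG", "HS"), each = 3),
                        rna_class = "mRNA") {
  count_matrix(values, groups, rna_class)
}

# a small synthetic dataset reused by several io/network tests; n_de keeps
# the miRNA universe above 20 so singleton sponge overlaps stay significant
small_dataset <- function(seed = 11) {
  simulate_dataset(simulation_config(
    n_circ = 40L, n_mirna = 25L, n_mrna = 60L, n_de_per_class = 25L,
    n_triads = 3L, n_decoy_edges = 5L, seed = seed))
}

run_pipeline_on <- function(dataset, dir, ...) {
  files <- write_fixture(dataset, dir)
  cfg <- pipeline_config(files[["counts_circ"]], files[["counts_mirna"]],
                         files[["counts_mrna"]], files[["samples"]],
                         files[["mirna_fasta"]], files[["target_fasta"]],
                         output_dir = file.path(dir, "out"), ...)
  run_pipeline(cfg)
}

triad_key <- function(df) paste(df$circ_id, df$mirna_id, df$mrna_id)
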