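test_that("simulation_config validates fields and names the offender", {
  expect_s3_class(simulation_config(), "SimulationConfig")
  expect_error(simulation_config(n_per_group = 1), "n_per_group")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_config(n_triads = 300), "n_triads")
  expect_error(simulation_config(triad_coupling = 1.5), "triad_coupling")
  expect_error(simulation_config(baseline_mean_range = c(-1, 10)),
               "baseline_mean_range")
})

test_that("simulate_dataset produces the configured shapes and valid counts", {
  cfg <- simulation_config(n_per_group = 3, n_circ = 10, n_mirna = 5,
                           n_mrna = 20, n_de_per_class = 4, n_triads = 2,
                           n_decoy_edges = 3, seed = 9)
  ds <- simulate_dataset(cfg)
  expect_equal(dim(ds$counts_circ), c(10L, 6L))
  expect_equal(dim(ds$counts_mirna), c(5L, 6L))
  expect_equal(dim(ds$counts_mrna), c(20L, 6L))
  for (cm in list(ds$counts_circ, ds$counts_mirna, ds$counts_mrna)) {
    expect_true(all(cm$values >= 0 & cm$values == round(cm$values)))
    expect_true(all(colSums(cm$values) > 0))
    expect_identical(cm$groups, ds$counts_circ$groups)
  }
  expect_equal(unname(ds$counts_circ$groups),
               rep(c("CG", "HS"), each = 3))
  # truth bookkeeping: triad members are DE, each triad implies two edges
  tr <- ds$truth$triads
  expect_equal(nrow(tr), 2L)
  expect_true(all(unlist(tr) %in% ds$truth$de_features$feature_id))
  ek <- paste(ds$truth$target_edges$mirna_id, ds$truth$target_edges$target_id)
  expect_true(all(paste(tr$mirna_id, tr$circ_id) %in% ek))
  expect_true(all(paste(tr$mirna_id, tr$mrna_id) %in% ek))
  expect_equal(sum(ds$truth$target_edges$is_decoy), 3L)
})

test_that("identical configs give identical datasets and fixtures", {
  cfg <- simulation_config(n_circ = 15, n_mirna = 8, n_mrna = 25,
                           n_de_per_class = 6, n_triads = 2,
                           n_decoy_edges = 2, seed = 31)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts_mrna$values, d2$counts_mrna$values)
  expect_identical(d1$target_seqs, d2$target_seqs)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  f1 <- write_fixture(d1, dir1); f2 <- write_fixture(d2, dir2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("every planted edge is a literal seed site; no chance edges remain", {
  ds <- small_dataset(seed = 13)
  pred <- predict_targets(ds$mirna_seqs, ds$target_seqs, ds$target_class,
                          min_site_type = "6mer")
  got <- paste(pred$edges$mirna_id, pred$edges$target_id)
  want <- paste(ds$truth$target_edges$mirna_id,
                ds$truth$target_edges$target_id)
  expect_setequal(got, want)
})

test_that("planted triads pass the three numeric screens at full coupling", {
  cfg <- simulation_config(n_circ = 30, n_mirna = 15, n_mrna = 40,
                           n_de_per_class = 10, n_triads = 4,
                           triad_coupling = 1, nb_dispersion = 0.01,
                           seed = 17)
  ds <- simulate_dataset(cfg)
  x <- rbind(log2(normalize_cpm(ds$counts_circ) + 1),
             log2(normalize_cpm(ds$counts_mirna) + 1),
             log2(normalize_cpm(ds$counts_mrna) + 1))
  for (i in seq_len(nrow(ds$truth$triads))) {
    tr <- ds$truth$triads[i, ]
    expect_lt(spearman_scc(x[tr$mirna_id, ], x[tr$circ_id, ]), -0.7)
    expect_lt(spearman_scc(x[tr$mirna_id, ], x[tr$mrna_id, ]), -0.7)
    expect_gt(pearson_pcc(x[tr$circ_id, ], x[tr$mrna_id, ]), 0.9)
  }
})

test_that("with nothing planted, extreme correlations match a shuffle null", {
  cfg <- simulation_config(n_circ = 1, n_mirna = 1, n_mrna = 80,
                           n_de_per_class = 0, n_triads = 0,
                           n_decoy_edges = 0, seed = 29)
  ds <- simulate_dataset(cfg)
  x <- log2(normalize_cpm(ds$counts_mrna) + 1)
  pairs <- combn(nrow(x), 2)
  obs <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- x[pairs[1, j], ]; b <- x[pairs[2, j], ]
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    spearman_scc(a, b)
  }, 0)
  obs <- obs[!is.na(obs)]
  # empirical permutation null at the same n: shuffle one member
  set.seed(2901)
  null_scc <- replicate(4000, spearman_scc(sample(6), sample(6)))
  p_obs <- mean(abs(obs) > 0.7)
  p_null <- mean(abs(null_scc) > 0.7)
  se <- sqrt(p_null * (1 - p_null) * (1 / length(obs) + 1 / 4000))
  expect_lt(abs(p_obs - p_null), 4 * se)
})

test_that("n_triads = 0 leaves only decoy edges in the truth", {
  cfg <- simulation_config(n_circ = 10, n_mirna = 6, n_mrna = 12,
                           n_de_per_class = 4, n_triads = 0,
                           n_decoy_edges = 4, seed = 41)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$truth$triads), 0L)
  expect_true(all(ds$truth$target_edges$is_decoy))
})

test_that("write_fixture round-trips through the pipeline readers", {
  ds <- simulate_dataset(simulation_config(
    n_circ = 12, n_mirna = 6, n_mrna = 15, n_de_per_class = 4,
    n_triads = 1, n_decoy_edges = 2, seed = 3))
  dir <- withr::local_tempdir()
  files <- write_fixture(ds, dir)
  expect_length(files, 9L)
  expect_true(all(file.exists(files)))
  meta <- read_sample_metadata(files[["samples"]])
  back <- read_count_table(files[["counts_circ"]], meta, "circRNA")
  expect_identical(back$values, ds$counts_circ$values)
  expect_identical(back$groups, ds$counts_circ$groups)
  mir <- read_fasta(files[["mirna_fasta"]])
  expect_identical(names(mir), names(ds$mirna_seqs))
  expect_identical(unname(nchar(mir)), unname(nchar(ds$mirna_seqs)))
  expect_identical(as.character(mir), as.character(ds$mirna_seqs))
})
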