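test_that("normalize_cpm rescales every column to one million", {
  m <- matrix(c(10, 90, 5, 5), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- normalize_cpm(m)
  expect_equal(cpm[, "s1"], c(a = 1e5, b = 9e5))
  expect_equal(unname(colSums(cpm)), rep(1e6, 2), tolerance = 1e-6)
  expect_error(normalize_cpm(matrix(0, 2, 1,
                                    dimnames = list(c("a", "b"), "s1"))),
               "library size")
})

test_that("log2_fold_change matches its closed form and is antisymmetric", {
  expect_equal(log2_fold_change(10, 30, 1), log2(31 / 11))
  expect_equal(log2_fold_change(7, 7), 0)
  set.seed(1)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  expect_error(log2_fold_change(-1, 2), "non-negative")
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "positive")
})

test_that("de_test handles zero-variance features and refuses tiny permutation designs", {
  m <- matrix(c(rep(50, 6), c(10, 20, 30, 400, 500, 600)), nrow = 2,
              byrow = TRUE,
              dimnames = list(c("flat", "de"),
                              c(paste0("CG-", 1:3), paste0("HS-", 1:3))))
  # equal CPM everywhere for 'flat' requires equal library sizes; build one
  m2 <- rbind(flat = rep(100, 6), other = rep(300, 6))
  colnames(m2) <- colnames(m)
  cm <- tiny_counts(m2)
  p <- de_test(cm)
  expect_equal(p$p_value, c(1, 1))
  expect_error(de_test(tiny_counts(m), method = "permutation"),
               "at least 4")
})

test_that("permutation p equals exhaustive label-enumeration oracle", {
  set.seed(42)
  g <- rep(c("CG", "HS"), each = 4)
  m <- matrix(rpois(5 * 8, 200), nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  cm <- count_matrix(m, g, "mRNA")
  p <- de_test(cm, method = "permutation")$p_value
  # oracle: enumerate all C(8,4) reassignments on the same transformed data
  x <- log2(normalize_cpm(cm) + 1)
  combs <- combn(8, 4)
  p_oracle <- vapply(seq_len(nrow(x)), function(i) {
    obs <- abs(mean(x[i, 5:8]) - mean(x[i, 1:4]))
    d <- apply(combs, 2, function(a)
      abs(mean(x[i, -a]) - mean(x[i, a])))
    mean(d >= obs - 1e-12)
  }, 0)
  expect_equal(p, p_oracle, tolerance = 1e-12)
})

test_that("bh_fdr matches the worked example and is order-equivariant", {
  expect_identical(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_de applies the class-specific gates strictly", {
  rec <- data.frame(feature_id = c("c1", "m1", "x1"),
                    log2fc = c(1.0, 1.5, 0.9),
                    p_value = c(0.049, 0.01, 0.001),
                    q_value = c(0.20, 0.06, 0.01))
  circ <- call_de(rec, de_thresholds(use_fdr = FALSE))
  expect_true(circ$significant[1])      # p gate, |log2fc| >= 1
  expect_identical(circ$direction[1], "up")
  expect_false(circ$significant[3])     # fails FC gate despite tiny p
  mrna <- call_de(rec, de_thresholds(use_fdr = TRUE))
  expect_false(mrna$significant[2])     # q = 0.06 fails the FDR gate
})

test_that("up + down = significant, and raising the FC gate shrinks the set", {
  ds <- small_dataset(seed = 5)
  de <- run_de(ds$counts_mrna, de_thresholds(use_fdr = TRUE))
  expect_equal(sum(de$direction == "up") + sum(de$direction == "down"),
               sum(de$significant))
  loose <- de$feature_id[de$significant]
  strict <- call_de(de, de_thresholds(min_fold_change = 8, use_fdr = TRUE))
  expect_true(all(strict$feature_id[strict$significant] %in% loose))
})

test_that("Welch type-I error on null NB data is near nominal", {
  cfg <- simulation_config(n_per_group = 5, n_circ = 1, n_mirna = 1,
                           n_mrna = 500, n_de_per_class = 0, n_triads = 0,
                           n_decoy_edges = 0, seed = 77)
  ds <- simulate_dataset(cfg)
  p <- de_test(ds$counts_mrna)$p_value
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * se)
})

test_that("ddct_relative_expression matches the comparative-Ct arithmetic", {
  expect_equal(ddct_relative_expression(20, 15, 22, 15), 4)
  expect_equal(ddct_relative_expression(18, 18, 18, 18), 1)
  expect_equal(ddct_relative_expression(21, 16, 23, 16),
               ddct_relative_expression(21 + 3, 16 + 3, 23 + 3, 16 + 3))
  expect_error(ddct_relative_expression(Inf, 1, 1, 1), "finite")
})
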