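test_that("spearman and pearson match brute-force formulas on random vectors", {
  expect_identical(spearman_scc(c(1, 2, 3), c(6, 5, 4)), -1)
  expect_identical(spearman_scc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_identical(pearson_pcc(c(1, 2, 3), 2 * c(1, 2, 3) + 1), 1)
  expect_identical(pearson_pcc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_pcc(x, y), oracle_pearson(x, y), tolerance = 1e-10)
    expect_equal(spearman_scc(x, y), oracle_spearman(x, y),
                 tolerance = 1e-10)
    # rank invariance under a strictly increasing transform
    expect_equal(spearman_scc(exp(x), y), spearman_scc(x, y))
    expect_equal(pearson_pcc(x, y), pearson_pcc(y, x))
  }
  expect_error(pearson_pcc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_pcc(1:4, 1:3), "equal length")
})

test_that("hypergeom_sf matches exhaustive enumeration for N <= 12", {
  expect_identical(hypergeom_sf(0, 5, 3, 10), 1)
  expect_identical(hypergeom_sf(3, 3, 3, 6), 0.05)
  expect_equal(hypergeom_sf(2, 4, 3, 10), 1 / 3, tolerance = 1e-15)
  for (N in c(5, 9, 12)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_sf(k, K, n, N),
                       oracle_hyper_sf(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
  # monotone non-increasing in k; large-argument log-space branch sane
  p <- vapply(0:10, hypergeom_sf, 0, K = 20, n = 10, N = 100)
  expect_true(all(diff(p) <= 1e-15))
  expect_equal(hypergeom_sf(5, 20, 10, 100),
               stats::phyper(4, 20, 80, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(hypergeom_sf(4, 3, 3, 6), "min\\(K, n\\)")
  expect_error(hypergeom_sf(1, 7, 3, 6), "exceed N")
})

test_that("sponge_test reduces to hypergeom_sf on set sizes", {
  uni <- paste0("m", 1:10)
  st <- sponge_test("c1", "r1", c("m1"), c("m2"), uni)
  expect_equal(st$k, 0); expect_equal(st$p_value, 1)
  st <- sponge_test("c1", "r1", "m1", "m1", uni)
  expect_equal(unlist(st[c("k", "K", "n", "N")]),
               c(k = 1, K = 1, n = 1, N = 10))
  expect_equal(st$p_value, 1 / 10)
  expect_error(sponge_test("c", "r", "zz", "m1", uni), "universe")
})

test_that("sponge test is conservative under random target sets", {
  set.seed(55)
  uni <- paste0("m", 1:40)
  n_rep <- 400
  rej <- 0L
  for (i in seq_len(n_rep)) {
    a <- sample(uni, 8); b <- sample(uni, 8)
    if (sponge_test("c", "r", a, b, uni)$p_value < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("negative_pairs enforces targeting, DE membership and strict SCC", {
  samples <- paste0("s", 1:5)
  logexpr <- rbind(m1 = 1:5,              # miRNA
                   c1 = 5:1,              # perfectly anticorrelated circ
                   c2 = c(5, 4, 1, 3, 2), # SCC with m1 exactly -0.7
                   c3 = 5:1,              # anticorrelated but no edge
                   r1 = c(2, 1, 5, 3, 4)) # weakly correlated mRNA
  colnames(logexpr) <- samples
  edges <- data.frame(mirna_id = c("m1", "m1", "m1"),
                      target_id = c("c1", "c2", "r1"),
                      target_class = c("circRNA", "circRNA", "mRNA"),
                      stringsAsFactors = FALSE)
  np <- negative_pairs(logexpr, edges)
  expect_equal(np$target_id, "c1")
  expect_equal(np$scc, -1)
  expect_identical(spearman_scc(logexpr["m1", ], logexpr["c2", ]), -0.7)
  # c3 anticorrelated but absent from target edges -> excluded by design
  expect_false("c3" %in% np$target_id)
  # DE gate drops edges whose endpoints are not DE
  np2 <- negative_pairs(logexpr, edges, de_ids = c("m1", "c2", "r1"))
  expect_equal(nrow(np2), 0L)
})

test_that("coexpressed_pairs requires a shared miRNA and strict PCC", {
  samples <- paste0("s", 1:5)
  logexpr <- rbind(m1 = 1:5,
                   c1 = 5:1,
                   r1 = c(5, 4, 3, 2, 1) + c(0, 0.1, -0.1, 0, 0),
                   r2 = c(2, 1, 3, 5, 4),
                   cb = c(5, 4, 3, 2, 1),
                   rb = c(4, 5, 2, 3, 1))  # pcc with cb exactly 0.9? no
  colnames(logexpr) <- samples
  np <- data.frame(mirna_id = c("m1", "m1", "m1"),
                   target_id = c("c1", "r1", "r2"),
                   target_class = c("circRNA", "mRNA", "mRNA"),
                   scc = -1, n_samples = 5, stringsAsFactors = FALSE)
  cp <- coexpressed_pairs(logexpr, np)
  expect_true(all(cp$pcc > 0.9))
  expect_equal(cp$circ_id, "c1")
  expect_equal(cp$mrna_id, "r1")  # r2 poorly correlated with c1
  expect_equal(cp$shared_mirnas, "m1")
  # boundary: PCC exactly 0.9 is excluded
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 3, 4, 5)
  expect_identical(pearson_pcc(x, y), 0.9)
  le <- rbind(m1 = 5:1, cx = x, rx = y)
  colnames(le) <- samples
  npx <- data.frame(mirna_id = c("m1", "m1"), target_id = c("cx", "rx"),
                    target_class = c("circRNA", "mRNA"), scc = -1,
                    n_samples = 5, stringsAsFactors = FALSE)
  expect_equal(nrow(coexpressed_pairs(le, npx)), 0L)
})

test_that("build_network assembles nodes, edges and triads with gates", {
  np <- data.frame(mirna_id = c("m1", "m1"), target_id = c("c1", "r1"),
                   target_class = c("circRNA", "mRNA"), scc = c(-0.9, -0.95),
                   n_samples = 6, stringsAsFactors = FALSE)
  cp <- data.frame(circ_id = "c1", mrna_id = "r1", pcc = 0.97,
                   shared_mirnas = "m1", n_shared = 1L,
                   stringsAsFactors = FALSE)
  sp <- data.frame(circ_id = "c1", mrna_id = "r1", k = 1L, K = 1L, n = 1L,
                   N = 30L, p_value = 1 / 30, stringsAsFactors = FALSE)
  net <- build_network(np, cp, sp)
  expect_s3_class(net, "CeRNANetwork")
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(nrow(net$triads), 1L)
  expect_true(all(net$triads$scc_circ_mirna < -0.7,
                  net$triads$scc_mirna_mrna < -0.7,
                  net$triads$pcc_circ_mrna > 0.9,
                  net$triads$sponge_p < 0.05))
  # sponge gate: p at exactly the cutoff removes circ-mRNA edge and triad
  sp2 <- sp; sp2$p_value <- 0.05
  net2 <- build_network(np, cp, sp2, sponge_p_cutoff = 0.05)
  expect_equal(nrow(net2$triads), 0L)
  expect_false("circ-mRNA" %in% net2$edges$kind)
  # every edge endpoint is a node
  expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes$id))
})

test_that("triad enumeration equals a brute-force triple loop", {
  ds <- small_dataset(seed = 21)
  dir <- withr::local_tempdir()
  man <- run_pipeline_on(ds, dir)
  out <- file.path(dir, "out")
  np <- read.delim(file.path(out, "negative_pairs.tsv"))
  cp <- read.delim(file.path(out, "coexpressed_pairs.tsv"))
  sp <- read.delim(file.path(out, "sponge_tests.tsv"))
  tr <- read.delim(file.path(out, "triads.tsv"))
  circs <- unique(np$target_id[np$target_class == "circRNA"])
  mirs <- unique(np$mirna_id)
  mrnas <- unique(np$target_id[np$target_class == "mRNA"])
  brute <- character(0)
  for (ci in circs) for (m in mirs) for (r in mrnas) {
    has_cm <- any(np$mirna_id == m & np$target_id == ci)
    has_mr <- any(np$mirna_id == m & np$target_id == r)
    i <- which(cp$circ_id == ci & cp$mrna_id == r)
    has_cr <- length(i) == 1 &&
      sp$p_value[sp$circ_id == ci & sp$mrna_id == r] < 0.05
    if (has_cm && has_mr && has_cr)
      brute <- c(brute, paste(ci, m, r))
  }
  expect_setequal(triad_key(tr), brute)
})

test_that("extract_subnetwork matches an independent BFS neighborhood", {
  ds <- small_dataset(seed = 21)
  dir <- withr::local_tempdir()
  man <- run_pipeline_on(ds, dir)
  net <- man$network
  expect_gt(nrow(net$triads), 0)
  focal <- net$triads$mrna_id[1]
  sub0 <- extract_subnetwork(net, focal, radius = 0)
  expect_equal(sub0$nodes$id, focal)
  expect_equal(nrow(sub0$edges), 0L)
  sub2 <- extract_subnetwork(net, focal, radius = 2)
  # BFS oracle over the adjacency list
  adj <- list()
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  frontier <- focal; seen <- focal
  for (d in 1:2) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, frontier)
  }
  expect_setequal(sub2$nodes$id, seen)
  # focal degree equals its adjacency count
  deg <- sum(sub2$edges$from == focal | sub2$edges$to == focal)
  expect_equal(deg, length(unique(adj[[focal]])))
  expect_error(extract_subnetwork(net, "nope"), "unknown focal id")
})
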