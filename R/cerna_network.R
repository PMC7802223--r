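# Criteria implemented here, applied to log2(CPM + 1) expression pooled
# over all samples of both groups:
#   (1) miRNA-target pairs (target-predicted, DE only) with Spearman
#       correlation strictly below -0.7 are negatively coexpressed pairs;
#   (2) circRNA-mRNA pairs sharing >= 1 such miRNA and with Pearson
#       correlation strictly above 0.9 are coexpressed pairs;
#   (3) an upper-tail hypergeometric test on the shared miRNAs decides
#       whether the sponge overlap is significant (p strictly < 0.05).

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of average ranks; ties receive their mean rank. The
#' arithmetic keeps integer rank sums exact, so rational coefficients such
#' as -0.7 are represented exactly and strict threshold comparisons are
#' reliable.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
spearman_scc <- function(x, y) {
  pearson_pcc(rank(x, ties.method = "average"),
              rank(y, ties.method = "average"))
}

#' Pearson product-moment correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
pearson_pcc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  a <- x - mean(x)
  b <- y - mean(y)
  saa <- sum(a * a); sbb <- sum(b * b)
  if (saa == 0 || sbb == 0)
    stop("correlation undefined for a constant vector")
  r <- sum(a * b) / sqrt(saa * sbb)
  min(1, max(-1, r))
}

#' Negatively coexpressed miRNA-target pairs
#'
#' Screens the target-predicted edges: a pair is retained iff (a) it is a
#' predicted miRNA->target edge, (b) both members are in `de_ids` (when
#' given), and (c) the Spearman correlation of their log-expression across
#' all samples is strictly below `scc_threshold`. Pairs with undefined
#' correlation (a constant vector) are dropped and counted in the
#' `"n_excluded_constant"` attribute.
#'
#' @param logexpr numeric matrix of log2(CPM + 1), all classes stacked;
#'   rownames are feature ids, columns are the shared samples.
#' @param target_edges data.frame with columns `mirna_id`, `target_id`,
#'   `target_class` (from [predict_targets()]).
#' @param de_ids optional character vector of differentially expressed
#'   feature ids; when supplied both edge endpoints must belong to it.
#' @param scc_threshold retention is `SCC < scc_threshold` (default -0.7,
#'   strict).
#' @return data.frame `mirna_id`, `target_id`, `target_class`, `scc`,
#'   `n_samples`, ordered lexicographically.
#' @export
negative_pairs <- function(logexpr, target_edges, de_ids = NULL,
                           scc_threshold = -0.7) {
  stopifnot(is.matrix(logexpr), !is.null(rownames(logexpr)))
  need <- unique(c(target_edges$mirna_id, target_edges$target_id))
  missing <- setdiff(need, rownames(logexpr))
  if (length(missing))
    stop("target edges reference features absent from the expression ",
         "matrix: ", paste(utils::head(missing, 5L), collapse = ", "))
  edges <- target_edges
  if (!is.null(de_ids))
    edges <- edges[edges$mirna_id %in% de_ids &
                     edges$target_id %in% de_ids, , drop = FALSE]
  n_const <- 0L
  keep <- logical(nrow(edges))
  scc <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    xm <- logexpr[edges$mirna_id[i], ]
    xt <- logexpr[edges$target_id[i], ]
    if (stats::var(xm) == 0 || stats::var(xt) == 0) {
      n_const <- n_const + 1L
      next
    }
    scc[i] <- spearman_scc(xm, xt)
    keep[i] <- scc[i] < scc_threshold
  }
  out <- data.frame(mirna_id = edges$mirna_id[keep],
                    target_id = edges$target_id[keep],
                    target_class = edges$target_class[keep],
                    scc = scc[keep],
                    n_samples = rep(ncol(logexpr), sum(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "n_excluded_constant") <- n_const
  out
}

#' Coexpressed circRNA-mRNA pairs sharing a common miRNA
#'
#' Candidate circRNA-mRNA pairs are those sharing at least one miRNA in
#' the negative-pair set; a candidate is retained iff the Pearson
#' correlation of the two log-expression profiles is strictly above
#' `pcc_threshold`.
#'
#' @param logexpr as in [negative_pairs()].
#' @param neg_pairs output of [negative_pairs()].
#' @param pcc_threshold retention is `PCC > pcc_threshold` (default 0.9,
#'   strict).
#' @return data.frame `circ_id`, `mrna_id`, `pcc`, `shared_mirnas`
#'   (comma-separated), `n_shared`, ordered lexicographically.
#' @export
coexpressed_pairs <- function(logexpr, neg_pairs, pcc_threshold = 0.9) {
  circ_edges <- neg_pairs[neg_pairs$target_class == "circRNA", , drop = FALSE]
  mrna_edges <- neg_pairs[neg_pairs$target_class == "mRNA", , drop = FALSE]
  shared_mirnas <- intersect(circ_edges$mirna_id, mrna_edges$mirna_id)
  cand <- list()
  for (m in shared_mirnas) {
    cc <- circ_edges$target_id[circ_edges$mirna_id == m]
    rr <- mrna_edges$target_id[mrna_edges$mirna_id == m]
    cand[[m]] <- expand.grid(circ_id = cc, mrna_id = rr, mirna_id = m,
                             stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(data.frame(circ_id = character(0), mrna_id = character(0),
                      pcc = numeric(0), shared_mirnas = character(0),
                      n_shared = integer(0), stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  key <- paste(cand$circ_id, cand$mrna_id, sep = "\r")
  by_pair <- split(cand$mirna_id, key)
  ks <- sort(names(by_pair))
  parts <- strsplit(ks, "\r", fixed = TRUE)
  out <- data.frame(circ_id = vapply(parts, `[[`, "", 1L),
                    mrna_id = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  out$pcc <- vapply(seq_len(nrow(out)), function(i) {
    pearson_pcc(logexpr[out$circ_id[i], ], logexpr[out$mrna_id[i], ])
  }, 0)
  out$shared_mirnas <- vapply(by_pair[ks], function(v)
    paste(sort(unique(v)), collapse = ","), "")
  out$n_shared <- vapply(by_pair[ks], function(v)
    length(unique(v)), 0L)
  out <- out[out$pcc > pcc_threshold, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' For X ~ Hypergeometric(N, K, n) (a draw of `n` from a universe of `N`
#' containing `K` marked items), returns
#' `sum_{i = k}^{min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`.
#' For small universes (`N <= 30`) the terms are computed with exact
#' binomial-coefficient arithmetic so that rational probabilities such as
#' 1/20 are represented exactly; larger arguments are accumulated in log
#' space for stability.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K number of marked items in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return probability in \[0, 1\]; `k = 0` returns exactly 1.
#' @export
hypergeom_sf <- function(k, K, n, N) {
  vals <- c(k, K, n, N)
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0))
    stop("k, K, n, N must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  if (k == 0) return(1)
  i <- k:min(K, n)
  if (N <= 30) {
    p <- sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
  } else {
    lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    mx <- max(lt)
    p <- exp(mx) * sum(exp(lt - mx))
  }
  min(1, max(0, p))
}

#' Shared-sponge hypergeometric test for one circRNA-mRNA pair
#'
#' Tests whether the overlap between the miRNA sets of a circRNA and an
#' mRNA is larger than expected under random draws from the miRNA
#' universe: `k` shared miRNAs, `K` targeting the circRNA, `n` targeting
#' the mRNA, universe size `N`, p = P(X >= k).
#'
#' @param circ_id,mrna_id pair ids (carried through).
#' @param mirnas_targeting_circ,mirnas_targeting_mrna character id sets.
#' @param universe character id set containing both target sets.
#' @return list of class `"SpongeTestResult"` with fields `circ_id`,
#'   `mrna_id`, `shared_mirnas`, `k`, `K`, `n`, `N`, `p_value`.
#' @export
sponge_test <- function(circ_id, mrna_id, mirnas_targeting_circ,
                        mirnas_targeting_mrna, universe) {
  sc <- unique(mirnas_targeting_circ)
  sm <- unique(mirnas_targeting_mrna)
  uni <- unique(universe)
  esc <- setdiff(c(sc, sm), uni)
  if (length(esc))
    stop("miRNA set escapes the universe: ",
         paste(utils::head(esc, 5L), collapse = ", "))
  shared <- sort(intersect(sc, sm))
  res <- list(circ_id = circ_id, mrna_id = mrna_id,
              shared_mirnas = shared,
              k = length(shared), K = length(sc), n = length(sm),
              N = length(uni),
              p_value = hypergeom_sf(length(shared), length(sc),
                                     length(sm), length(uni)))
  class(res) <- "SpongeTestResult"
  res
}

#' Assemble the tripartite ceRNA network
#'
#' Builds the typed graph from the screened pairs. Edges are the retained
#' circRNA-miRNA and miRNA-mRNA negative pairs, plus circRNA-mRNA pairs
#' that passed the coexpression screen *and* whose sponge test p-value is
#' strictly below `sponge_p_cutoff`. Nodes are exactly the features on at
#' least one retained edge. Triads are all (circRNA, miRNA, mRNA) triples
#' whose three supporting edges are all retained. All outputs are ordered
#' lexicographically by ids.
#'
#' @param neg_pairs output of [negative_pairs()].
#' @param coex_pairs output of [coexpressed_pairs()].
#' @param sponge_results data.frame with columns `circ_id`, `mrna_id`,
#'   `k`, `K`, `n`, `N`, `p_value` (one row per coexpressed pair; see
#'   [sponge_test()]).
#' @param de_records optional combined [run_de()] table used to annotate
#'   nodes with `log2fc` and `direction`.
#' @param sponge_p_cutoff circ-mRNA edges kept iff `p < cutoff`
#'   (default 0.05, strict).
#' @return list of class `"CeRNANetwork"` with data.frames `nodes`
#'   (`id`, `rna_class`, `log2fc`, `direction`), `edges` (`from`, `to`,
#'   `kind`, `statistic`, `stat_name`) and `triads` (`circ_id`,
#'   `mirna_id`, `mrna_id`, `scc_circ_mirna`, `scc_mirna_mrna`,
#'   `pcc_circ_mrna`, `sponge_p`).
#' @export
build_network <- function(neg_pairs, coex_pairs, sponge_results,
                          de_records = NULL, sponge_p_cutoff = 0.05) {
  cm <- neg_pairs[neg_pairs$target_class == "circRNA", , drop = FALSE]
  mm <- neg_pairs[neg_pairs$target_class == "mRNA", , drop = FALSE]

  # sponge gate on the coexpressed circ-mRNA pairs
  if (nrow(coex_pairs)) {
    skey <- paste(sponge_results$circ_id, sponge_results$mrna_id, sep = "\r")
    ckey <- paste(coex_pairs$circ_id, coex_pairs$mrna_id, sep = "\r")
    missing <- setdiff(ckey, skey)
    if (length(missing))
      stop("coexpressed pair(s) without a sponge test result")
    sp <- sponge_results$p_value[match(ckey, skey)]
    keep <- sp < sponge_p_cutoff
    cm_pairs <- coex_pairs[keep, , drop = FALSE]
    cm_pairs$sponge_p <- sp[keep]
  } else {
    cm_pairs <- cbind(coex_pairs, sponge_p = numeric(0))
  }

  edge_frame <- function(from, to, kind, statistic, stat_name)
    data.frame(from = from, to = to,
               kind = rep_len(kind, length(from)),
               statistic = statistic,
               stat_name = rep_len(stat_name, length(from)),
               stringsAsFactors = FALSE)
  edges <- rbind(
    edge_frame(cm$target_id, cm$mirna_id, "circ-miRNA", cm$scc, "scc"),
    edge_frame(mm$mirna_id, mm$target_id, "miRNA-mRNA", mm$scc, "scc"),
    edge_frame(cm_pairs$circ_id, cm_pairs$mrna_id, "circ-mRNA",
               cm_pairs$sponge_p, "sponge_p"))
  edges <- edges[order(edges$kind, edges$from, edges$to), , drop = FALSE]
  row.names(edges) <- NULL
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
    stop("duplicate edges in network inputs")

  cls <- c(stats::setNames(rep("circRNA", nrow(cm)), cm$target_id),
           stats::setNames(rep("miRNA", nrow(cm)), cm$mirna_id),
           stats::setNames(rep("miRNA", nrow(mm)), mm$mirna_id),
           stats::setNames(rep("mRNA", nrow(mm)), mm$target_id),
           stats::setNames(rep("circRNA", nrow(cm_pairs)), cm_pairs$circ_id),
           stats::setNames(rep("mRNA", nrow(cm_pairs)), cm_pairs$mrna_id))
  cls <- cls[!duplicated(names(cls))]
  nodes <- data.frame(id = as.character(names(cls)),
                      rna_class = as.character(unname(cls)),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  if (!is.null(de_records)) {
    idx <- match(nodes$id, de_records$feature_id)
    nodes$log2fc <- de_records$log2fc[idx]
    nodes$direction <- de_records$direction[idx]
  } else {
    nodes$log2fc <- NA_real_
    nodes$direction <- NA_character_
  }
  row.names(nodes) <- NULL

  # triads: every circ-mRNA edge x miRNA adjacent (negatively) to both
  triads <- list()
  if (nrow(cm_pairs)) {
    for (i in seq_len(nrow(cm_pairs))) {
      ci <- cm_pairs$circ_id[i]; ri <- cm_pairs$mrna_id[i]
      m_c <- cm$mirna_id[cm$target_id == ci]
      m_r <- mm$mirna_id[mm$target_id == ri]
      for (m in sort(intersect(m_c, m_r))) {
        triads[[length(triads) + 1L]] <- data.frame(
          circ_id = ci, mirna_id = m, mrna_id = ri,
          scc_circ_mirna = cm$scc[cm$target_id == ci & cm$mirna_id == m],
          scc_mirna_mrna = mm$scc[mm$target_id == ri & mm$mirna_id == m],
          pcc_circ_mrna = cm_pairs$pcc[i],
          sponge_p = cm_pairs$sponge_p[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  triads <- if (length(triads)) do.call(rbind, triads) else
    data.frame(circ_id = character(0), mirna_id = character(0),
               mrna_id = character(0), scc_circ_mirna = numeric(0),
               scc_mirna_mrna = numeric(0), pcc_circ_mrna = numeric(0),
               sponge_p = numeric(0), stringsAsFactors = FALSE)
  triads <- triads[order(triads$circ_id, triads$mirna_id, triads$mrna_id),
                   , drop = FALSE]
  row.names(triads) <- NULL

  structure(list(nodes = nodes, edges = edges, triads = triads),
            class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  tab <- table(factor(x$nodes$rna_class,
                      levels = c("circRNA", "miRNA", "mRNA")))
  cat(sprintf(paste0("CeRNANetwork: %d nodes (%d circRNA, %d miRNA, ",
                     "%d mRNA), %d edges, %d triads\n"),
              nrow(x$nodes), tab[["circRNA"]], tab[["miRNA"]],
              tab[["mRNA"]], nrow(x$edges), nrow(x$triads)))
  invisible(x)
}

#' Convert a CeRNANetwork to an igraph object
#'
#' Vertices carry `rna_class`, `log2fc`, `direction`; edges carry `kind`,
#' `statistic`, `stat_name`. Attribute names are stable so GraphML
#' round-trips are possible.
#'
#' @param network a [build_network()] result.
#' @return an undirected [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "CeRNANetwork"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Extract the neighborhood subnetwork around a focal node
#'
#' Induced subgraph of all nodes within graph distance `radius` of
#' `focal_id`, with all induced edges, and only the triads fully contained
#' in the kept node set.
#'
#' @param network a [build_network()] result.
#' @param focal_id a node id present in the network.
#' @param radius non-negative integer graph distance (default 1).
#' @return a `"CeRNANetwork"` restricted to the neighborhood.
#' @export
extract_subnetwork <- function(network, focal_id, radius = 1L) {
  stopifnot(inherits(network, "CeRNANetwork"))
  if (!focal_id %in% network$nodes$id)
    stop("unknown focal id: ", focal_id)
  if (radius < 0) stop("radius must be >= 0")
  g <- as_igraph(network)
  keep <- names(igraph::ego(g, order = radius, nodes = focal_id)[[1L]])
  nodes <- network$nodes[network$nodes$id %in% keep, , drop = FALSE]
  edges <- network$edges[network$edges$from %in% keep &
                           network$edges$to %in% keep, , drop = FALSE]
  triads <- network$triads[network$triads$circ_id %in% keep &
                             network$triads$mirna_id %in% keep &
                             network$triads$mrna_id %in% keep, , drop = FALSE]
  row.names(nodes) <- row.names(edges) <- row.names(triads) <- NULL
  structure(list(nodes = nodes, edges = edges, triads = triads),
            class = "CeRNANetwork")
}

#' Write a CeRNANetwork to GraphML and flat TSV tables
#'
#' @param network a [build_network()] result.
#' @param graphml_path,edges_path,triads_path output file paths; any may
#'   be `NULL` to skip that file.
#' @return invisibly, the character vector of files written.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL,
                          triads_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edges_path)) {
    .write_tsv(network$edges, edges_path)
    written <- c(written, edges_path)
  }
  if (!is.null(triads_path)) {
    .write_tsv(network$triads, triads_path)
    written <- c(written, triads_path)
  }
  invisible(written)
}
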