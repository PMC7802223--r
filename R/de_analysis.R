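#' Counts-per-million normalization
#'
#' Library-size normalization: each column is scaled so that it sums to one
#' million. No trimming or reference-sample logic is applied.
#'
#' @param counts a [count_matrix()] object or a numeric matrix with
#'   positive column sums.
#' @return a numeric matrix of the same shape; every column sums to 1e6.
#' @export
normalize_cpm <- function(counts) {
  m <- if (inherits(counts, "CountMatrix")) counts$values else as.matrix(counts)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    bad <- colnames(m)[cs <= 0]
    if (is.null(bad)) bad <- which(cs <= 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(m, 2L, cs, "/") * 1e6
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_g2 + pseudocount) / (mean_g1 + pseudocount))`, the fold-change
#' statistic the significance thresholds act on. Group 2 is the treatment
#' (e.g. heat stress), group 1 the reference.
#'
#' @param mean_g1,mean_g2 non-negative normalized expression values
#'   (vectorized).
#' @param pseudocount positive offset avoiding division by zero (default 1).
#' @return numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mean_g1, mean_g2, pseudocount = 1) {
  if (any(mean_g1 < 0, na.rm = TRUE) || any(mean_g2 < 0, na.rm = TRUE))
    stop("means must be non-negative")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  log2((mean_g2 + pseudocount) / (mean_g1 + pseudocount))
}

#' Per-feature two-group differential-expression test
#'
#' Tests every feature for a mean difference in `log2(CPM + 1)` between the
#' two groups. The default is Welch's unequal-variance t test. An exact
#' label-permutation test (absolute mean difference, full enumeration of
#' group reassignments) is available for designs with at least 4 samples
#' per group; with 3 vs 3 only 20 assignments exist and the smallest
#' attainable two-sided p is 0.1, so permutation is refused there.
#'
#' Features with zero variance in both groups are reported with p = 1.
#'
#' @param counts a [count_matrix()].
#' @param method `"welch_t"` (default) or `"permutation"`.
#' @param pseudocount pseudocount used inside the log transform.
#' @return data.frame with columns `feature_id`, `p_value`.
#' @export
de_test <- function(counts, method = c("welch_t", "permutation"),
                    pseudocount = 1) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "CountMatrix"))
  groups <- counts$groups
  glev <- sort(unique(groups))
  i1 <- which(groups == glev[1L])
  i2 <- which(groups == glev[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("at least 2 samples per group are required")
  if (method == "permutation" && (n1 < 4L || n2 < 4L))
    stop("permutation test requires at least 4 samples per group ",
         "(with 3 vs 3 the minimum two-sided p is 0.1)")
  x <- log2(normalize_cpm(counts) + pseudocount)
  p <- switch(method,
              welch_t = .welch_t_rows(x, i1, i2),
              permutation = .perm_test_rows(x, i1, i2))
  data.frame(feature_id = rownames(x), p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

.welch_t_rows <- function(x, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, nrow(x))
  ok <- se2 > 0
  tt <- abs(m2[ok] - m1[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(tt, df = df, lower.tail = FALSE)
  pmin(p, 1)
}

.perm_test_rows <- function(x, i1, i2) {
  n <- length(i1) + length(i2)
  idx <- c(i1, i2)
  combs <- utils::combn(n, length(i1))
  obs <- abs(rowMeans(x[, i2, drop = FALSE]) - rowMeans(x[, i1, drop = FALSE]))
  xs <- x[, idx, drop = FALSE]
  hits <- integer(nrow(x))
  for (j in seq_len(ncol(combs))) {
    a <- combs[, j]
    d <- abs(rowMeans(xs[, -a, drop = FALSE]) - rowMeans(xs[, a, drop = FALSE]))
    hits <- hits + (d >= obs - 1e-12)
  }
  hits / ncol(combs)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up FDR control: on sorted p-values,
#' `q(i) = min_{j >= i} m * p(j) / j`, mapped back to input order and capped
#' at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Class-specific significance thresholds
#'
#' Defaults follow the convention used for this pipeline: fold change >= 2
#' combined with p < 0.05 for circRNA and miRNA, and with FDR (BH q) < 0.05
#' for mRNA (`use_fdr = TRUE`).
#'
#' @param min_fold_change minimum fold change (> 1); the gate is
#'   `|log2fc| >= log2(min_fold_change)`.
#' @param p_cutoff significance cutoff in (0, 1), applied strictly (`<`).
#' @param use_fdr if `TRUE` the cutoff is applied to BH q-values, otherwise
#'   to raw p-values.
#' @return list of class `"DEThresholds"`.
#' @export
de_thresholds <- function(min_fold_change = 2, p_cutoff = 0.05,
                          use_fdr = FALSE) {
  if (!is.numeric(min_fold_change) || min_fold_change <= 1)
    stop("min_fold_change must be > 1")
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff >= 1)
    stop("p_cutoff must lie in (0, 1)")
  structure(list(min_fold_change = min_fold_change,
                 p_cutoff = p_cutoff,
                 use_fdr = isTRUE(use_fdr)),
            class = "DEThresholds")
}

#' Call differential expression from fold changes and test results
#'
#' A feature is significant iff `|log2fc| >= log2(min_fold_change)` and the
#' chosen statistic (q if `use_fdr`, else p) is strictly below the cutoff.
#' Significant features get direction `"up"` or `"down"` by the sign of
#' `log2fc`; others get `"none"`.
#'
#' @param records data.frame with at least columns `feature_id`, `log2fc`,
#'   `p_value`, `q_value`.
#' @param thresholds a [de_thresholds()] object.
#' @return the input data.frame with added columns `direction`,
#'   `significant`.
#' @export
call_de <- function(records, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "DEThresholds"),
            all(c("feature_id", "log2fc", "p_value", "q_value") %in%
                  names(records)))
  stat <- if (thresholds$use_fdr) records$q_value else records$p_value
  sig <- abs(records$log2fc) >= log2(thresholds$min_fold_change) &
    stat < thresholds$p_cutoff
  records$direction <- ifelse(sig, ifelse(records$log2fc > 0, "up", "down"),
                              "none")
  records$significant <- sig
  records
}

#' Full differential-expression table for one RNA class
#'
#' Normalizes to CPM, computes group means and log2 fold change
#' (treatment over reference), runs [de_test()], applies [bh_fdr()] and
#' calls significance with [call_de()].
#'
#' @param counts a [count_matrix()].
#' @param thresholds a [de_thresholds()] object.
#' @param method test passed to [de_test()].
#' @param reference_group,treatment_group group labels; by default the
#'   alphabetically first label is the reference (so `"CG"` vs `"HS"` is
#'   oriented heat stress over control).
#' @param pseudocount pseudocount for fold change and log transform.
#' @return data.frame with columns `feature_id`, `rna_class`,
#'   `mean_expr_g1`, `mean_expr_g2`, `log2fc`, `p_value`, `q_value`,
#'   `direction`, `significant`.
#' @export
run_de <- function(counts, thresholds = de_thresholds(),
                   method = "welch_t",
                   reference_group = NULL, treatment_group = NULL,
                   pseudocount = 1) {
  stopifnot(inherits(counts, "CountMatrix"))
  glev <- sort(unique(counts$groups))
  if (is.null(reference_group)) reference_group <- glev[1L]
  if (is.null(treatment_group))
    treatment_group <- setdiff(glev, reference_group)
  if (!all(c(reference_group, treatment_group) %in% glev) ||
      reference_group == treatment_group)
    stop("reference/treatment groups must be the two labels present: ",
         paste(glev, collapse = ", "))
  cpm <- normalize_cpm(counts)
  m1 <- rowMeans(cpm[, counts$groups == reference_group, drop = FALSE])
  m2 <- rowMeans(cpm[, counts$groups == treatment_group, drop = FALSE])
  tst <- de_test(counts, method = method, pseudocount = pseudocount)
  rec <- data.frame(feature_id = tst$feature_id,
                    rna_class = counts$rna_class,
                    mean_expr_g1 = m1[tst$feature_id],
                    mean_expr_g2 = m2[tst$feature_id],
                    log2fc = log2_fold_change(m1[tst$feature_id],
                                              m2[tst$feature_id],
                                              pseudocount),
                    p_value = tst$p_value,
                    q_value = bh_fdr(tst$p_value),
                    stringsAsFactors = FALSE, row.names = NULL)
  call_de(rec, thresholds)
}

#' Comparative-Ct relative expression (2^-ddCt)
#'
#' Relative quantification of qPCR expression of a target gene against a
#' reference gene and a calibrator (control) condition:
#' `2 ^ -((Ct_target_case - Ct_ref_case) - (Ct_target_ctrl - Ct_ref_ctrl))`.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl finite
#'   cycle-threshold values.
#' @return positive fold change of the case relative to the control.
#' @examples
#' ddct_relative_expression(20, 15, 22, 15)  # 4
#' @export
ddct_relative_expression <- function(ct_target_case, ct_ref_case,
                                     ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
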