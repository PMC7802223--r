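# Canonical seed-match target prediction.
#
# Site types, on the target read 5'->3' (coordinates 0-based half-open):
#   6mer     reverse complement of miRNA nt 2-7
#   7mer-A1  6mer followed by an "A" opposite miRNA position 1
#   7mer-m8  reverse complement of miRNA nt 2-8
#   8mer     7mer-m8 followed by the A1 "A"
# The A opposite position 1 is an adenosine on the target regardless of the
# miRNA's first nucleotide.

.SITE_TYPES <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)

#' Site-type stringency ordering
#'
#' @return named integer vector mapping site type to rank
#'   (6mer < 7mer-A1 < 7mer-m8 < 8mer).
#' @export
site_type_levels <- function() .SITE_TYPES

.norm_rna <- function(x, what = "sequence") {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("illegal characters in ", what, " after normalization (need A/C/G/U/T)")
  if (any(!nzchar(x))) stop("empty ", what)
  x
}

.rna_complement <- function(x) chartr("ACGU", "UGCA", x)

.rev_string <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

.rna_revcomp <- function(x) .rev_string(.rna_complement(x))

# Seed match strings for one miRNA: the 6mer core (RC of nt 2-7) and the
# target base pairing miRNA nt 8 (which precedes the core 5' on the target).
.seed_strings <- function(mirna) {
  list(core6 = .rna_revcomp(substr(mirna, 2L, 7L)),
       m8 = .rna_complement(substr(mirna, 8L, 8L)))
}

#' Find canonical miRNA seed-match sites in a target sequence
#'
#' Scans the target (treated as a linear 5'->3' string, no strand logic)
#' for all canonical seed matches of the miRNA. At every occurrence of the
#' 6mer core the flanking bases are inspected and the single maximal site
#' type at that locus is reported.
#'
#' @param mirna miRNA sequence (character, length >= 8 nt; T is normalized
#'   to U).
#' @param target target sequence (character).
#' @param mirna_id,target_id ids carried into the output.
#' @param circular if `TRUE` the target is scanned as a circle: the first
#'   7 nt are appended so that back-splice-junction-spanning sites are
#'   seen; sites whose 0-based start is beyond the sequence end are
#'   reported modulo the target length.
#' @return data.frame with columns `mirna_id`, `target_id`, `site_type`,
#'   `start` (0-based), `length`.
#' @examples
#' find_seed_sites("UGAGGUAGUAGGUUGUAUAGUU",
#'                 paste0("GGGG", "CUACCUCA", "GGGG"))  # one 8mer at 4
#' @export
find_seed_sites <- function(mirna, target, mirna_id = "miRNA",
                            target_id = "target", circular = FALSE) {
  mirna <- .norm_rna(mirna, "miRNA")
  target <- .norm_rna(target, "target")
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt long")
  .find_sites_core(mirna, target, mirna_id, target_id, circular)
}

# workhorse; assumes already-normalized sequences
.find_sites_core <- function(mirna, target, mirna_id, target_id, circular) {
  seed <- .seed_strings(mirna)
  L <- nchar(target)
  scan_seq <- if (circular) paste0(target, substr(target, 1L, 7L)) else target
  hits <- gregexpr(seed$core6, scan_seq, fixed = TRUE)[[1L]]
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      site_type = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (hits[1L] == -1L) return(empty)
  hits <- as.integer(hits)
  if (circular) hits <- hits[hits <= L]  # one locus per circular position
  if (!length(hits)) return(empty)
  sl <- nchar(scan_seq)
  out <- lapply(hits, function(i) {
    has_m8 <- i > 1L && substr(scan_seq, i - 1L, i - 1L) == seed$m8
    has_a1 <- i + 6L <= sl && substr(scan_seq, i + 6L, i + 6L) == "A"
    if (has_m8 && has_a1) {
      c(type = "8mer", start = i - 2L, len = 8L)
    } else if (has_m8) {
      c(type = "7mer-m8", start = i - 2L, len = 7L)
    } else if (has_a1) {
      c(type = "7mer-A1", start = i - 1L, len = 7L)
    } else {
      c(type = "6mer", start = i - 1L, len = 6L)
    }
  })
  res <- data.frame(mirna_id = mirna_id, target_id = target_id,
                    site_type = vapply(out, `[[`, "", "type"),
                    start = as.integer(vapply(out, `[[`, "", "start")),
                    length = as.integer(vapply(out, `[[`, "", "len")),
                    stringsAsFactors = FALSE)
  if (circular) res$start <- res$start %% L
  res[order(res$start), , drop = FALSE]
}

#' Predict miRNA -> target edges by seed matching
#'
#' One edge is emitted per (miRNA, target) pair that has at least one seed
#' site of stringency `min_site_type` or better. `restrict_mirnas` /
#' `restrict_targets` implement the rule that only differentially expressed
#' features participate in network construction.
#'
#' @param mirnas named character vector of miRNA sequences (names are ids).
#' @param targets named character vector of candidate target sequences.
#' @param target_class named character vector mapping every target id to
#'   `"circRNA"` or `"mRNA"`.
#' @param min_site_type minimum acceptable site type (default `"7mer-A1"`).
#' @param restrict_mirnas,restrict_targets optional id sets; when given,
#'   only these ids are scanned.
#' @param circular_targets logical: scan targets of class `"circRNA"`
#'   circularly (default `FALSE`).
#' @return list with elements `edges` (data.frame `mirna_id`, `target_id`,
#'   `target_class`, `best_site_type`, `n_sites`) and `sites` (per-site
#'   data.frame as from [find_seed_sites()]).
#' @export
predict_targets <- function(mirnas, targets, target_class,
                            min_site_type = "7mer-A1",
                            restrict_mirnas = NULL, restrict_targets = NULL,
                            circular_targets = FALSE) {
  if (!min_site_type %in% names(.SITE_TYPES))
    stop("min_site_type must be one of: ",
         paste(names(.SITE_TYPES), collapse = ", "))
  if (is.null(names(mirnas)) || is.null(names(targets)))
    stop("mirnas and targets must be named character vectors")
  ids <- c(names(mirnas), names(targets))
  if (anyDuplicated(ids))
    stop("duplicate ids across miRNA/target inputs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing_class <- setdiff(names(targets), names(target_class))
  if (length(missing_class))
    stop("no target_class for: ", paste(missing_class, collapse = ", "))
  if (!is.null(restrict_mirnas))
    mirnas <- mirnas[names(mirnas) %in% restrict_mirnas]
  if (!is.null(restrict_targets))
    targets <- targets[names(targets) %in% restrict_targets]
  min_rank <- .SITE_TYPES[[min_site_type]]
  mirnas[] <- .norm_rna(unname(mirnas), "miRNA")
  if (any(nchar(mirnas) < 8L)) stop("miRNA must be at least 8 nt long")
  targets[] <- .norm_rna(unname(targets), "target")

  site_list <- list()
  for (mid in names(mirnas)) {
    for (tid in names(targets)) {
      circ <- isTRUE(circular_targets) &&
        target_class[[tid]] == "circRNA"
      s <- .find_sites_core(mirnas[[mid]], targets[[tid]],
                            mirna_id = mid, target_id = tid, circular = circ)
      if (nrow(s)) site_list[[length(site_list) + 1L]] <- s
    }
  }
  sites <- if (length(site_list)) do.call(rbind, site_list) else
    data.frame(mirna_id = character(0), target_id = character(0),
               site_type = character(0), start = integer(0),
               length = integer(0), stringsAsFactors = FALSE)
  keep <- .SITE_TYPES[sites$site_type] >= min_rank
  qual <- sites[keep, , drop = FALSE]
  if (nrow(qual)) {
    key <- paste(qual$mirna_id, qual$target_id, sep = "\r")
    agg_n <- tapply(key, key, length)
    agg_best <- tapply(.SITE_TYPES[qual$site_type], key, max)
    ks <- sort(names(agg_n))
    parts <- strsplit(ks, "\r", fixed = TRUE)
    edges <- data.frame(
      mirna_id = vapply(parts, `[[`, "", 1L),
      target_id = vapply(parts, `[[`, "", 2L),
      stringsAsFactors = FALSE)
    edges$target_class <- unname(target_class[edges$target_id])
    edges$best_site_type <- names(.SITE_TYPES)[as.integer(agg_best[ks])]
    edges$n_sites <- as.integer(agg_n[ks])
  } else {
    edges <- data.frame(mirna_id = character(0), target_id = character(0),
                        target_class = character(0),
                        best_site_type = character(0), n_sites = integer(0),
                        stringsAsFactors = FALSE)
  }
  row.names(edges) <- NULL
  list(edges = edges, sites = sites)
}
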