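# Plain-text formats and the end-to-end pipeline driver.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV count table into a CountMatrix
#'
#' Expects a header row of sample ids with a leading feature-id column.
#' Non-integer, negative or missing cells and duplicate ids are rejected.
#'
#' @param path TSV file.
#' @param groups named character vector (or data.frame from
#'   [read_sample_metadata()]) of group labels per sample id.
#' @param rna_class RNA class tag for the matrix.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, groups,
                             rna_class = c("circRNA", "miRNA", "mRNA")) {
  rna_class <- match.arg(rna_class)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character"), header = TRUE)
  if (ncol(df) < 2L) stop("count table needs a feature column plus samples: ",
                          path)
  fid <- df[[1L]]
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                  dimnames = list(fid, colnames(m))))
  bad <- which(is.na(vals) | vals < 0 | vals != round(vals),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count in ", path, " at line ",
         bad[1L, 1L] + 1L, " (feature ", fid[bad[1L, 1L]], ")")
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$sample_id)
  count_matrix(vals, groups, rna_class)
}

#' Write a CountMatrix to TSV
#'
#' @param counts a [count_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "CountMatrix"))
  df <- data.frame(feature_id = rownames(counts$values),
                   counts$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a sample-metadata table
#'
#' TSV with columns `sample_id` and `group`.
#'
#' @param path TSV file.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample metadata needs columns 'sample_id' and 'group': ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in ", path)
  df
}

#' Read a FASTA file of RNA sequences
#'
#' Sequences are upper-cased and DNA-style `T` is normalized to `U`. The
#' record id is the header up to the first whitespace; any description is
#' kept in the `"description"` attribute.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  if (file.size(path) == 0L ||
      !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- .norm_rna(as.character(ss), paste0("FASTA record (", path, ")"))
  out <- stats::setNames(seqs, ids)
  attr(out, "description") <- stats::setNames(desc, ids)
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  ss <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every input path and tunable parameter of [run_pipeline()].
#' Defaults are the pipeline's canonical settings: fold change >= 2 with
#' p < 0.05 for circRNA/miRNA and FDR < 0.05 for mRNA, SCC < -0.7,
#' PCC > 0.9, sponge p < 0.05, minimum site type 7mer-A1, and the set of
#' all differentially expressed miRNAs as the hypergeometric universe.
#'
#' @param counts_circ,counts_mirna,counts_mrna paths to the three count
#'   TSVs.
#' @param samples path to the sample-metadata TSV.
#' @param mirna_fasta,target_fasta paths to the FASTA files.
#' @param gmt optional path to a GMT gene-set file (enables enrichment).
#' @param output_dir directory for all stage outputs.
#' @param thresholds named list of [de_thresholds()] per class.
#' @param de_method test for [de_test()].
#' @param pseudocount CPM pseudocount.
#' @param scc_threshold,pcc_threshold,sponge_p_cutoff network screening
#'   thresholds (strict inequalities).
#' @param min_site_type minimum seed-site stringency.
#' @param universe_policy `"all_de"` (all DE miRNAs, default) or
#'   `"targeting_de"` (DE miRNAs with at least one predicted DE target).
#' @param circular_targets scan circRNA targets circularly.
#' @param reference_group,treatment_group optional explicit group
#'   orientation (default: alphabetical, reference first).
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(counts_circ, counts_mirna, counts_mrna,
                            samples, mirna_fasta, target_fasta,
                            gmt = NULL, output_dir = "cerna_out",
                            thresholds = list(
                              circRNA = de_thresholds(use_fdr = FALSE),
                              miRNA = de_thresholds(use_fdr = FALSE),
                              mRNA = de_thresholds(use_fdr = TRUE)),
                            de_method = "welch_t",
                            pseudocount = 1,
                            scc_threshold = -0.7,
                            pcc_threshold = 0.9,
                            sponge_p_cutoff = 0.05,
                            min_site_type = "7mer-A1",
                            universe_policy = c("all_de", "targeting_de"),
                            circular_targets = FALSE,
                            reference_group = NULL,
                            treatment_group = NULL,
                            seed = 1L) {
  universe_policy <- match.arg(universe_policy)
  if (!min_site_type %in% names(.SITE_TYPES))
    stop("min_site_type must be one of: ",
         paste(names(.SITE_TYPES), collapse = ", "))
  if (scc_threshold <= -1 || scc_threshold >= 1 ||
      pcc_threshold <= -1 || pcc_threshold >= 1)
    stop("correlation thresholds must lie in (-1, 1)")
  if (sponge_p_cutoff < 0 || sponge_p_cutoff > 1)
    stop("sponge_p_cutoff must lie in [0, 1]")
  stopifnot(all(c("circRNA", "miRNA", "mRNA") %in% names(thresholds)))
  structure(list(counts_circ = counts_circ, counts_mirna = counts_mirna,
                 counts_mrna = counts_mrna, samples = samples,
                 mirna_fasta = mirna_fasta, target_fasta = target_fasta,
                 gmt = gmt, output_dir = output_dir,
                 thresholds = thresholds, de_method = de_method,
                 pseudocount = pseudocount,
                 scc_threshold = scc_threshold,
                 pcc_threshold = pcc_threshold,
                 sponge_p_cutoff = sponge_p_cutoff,
                 min_site_type = min_site_type,
                 universe_policy = universe_policy,
                 circular_targets = isTRUE(circular_targets),
                 reference_group = reference_group,
                 treatment_group = treatment_group,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the reconstructed `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  x <- unclass(config)
  x$thresholds <- lapply(x$thresholds, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- lapply(x$thresholds, function(t)
    de_thresholds(t$min_fold_change, t$p_cutoff, t$use_fdr))
  do.call(pipeline_config,
          c(x[setdiff(names(x), "thresholds")], list(thresholds = thr)))
}

#' Run the full ceRNA network-inference pipeline
#'
#' Executes differential expression for the three classes, seed-match
#' target prediction restricted to DE features, the Spearman
#' anti-correlation screen, the Pearson co-expression screen, the
#' hypergeometric sponge tests, network assembly, and (when a GMT file is
#' configured) over-representation analysis of the significant mRNAs.
#' All stage outputs plus a machine-readable JSON manifest (input hashes,
#' parameters, per-stage row counts, output hashes) are written to
#' `config$output_dir`. The pipeline is deterministic: identical config
#' and inputs produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  run <- function(stage_name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage_name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  meta <- run("read_inputs", read_sample_metadata(config$samples))
  counts <- run("read_inputs", list(
    circRNA = read_count_table(config$counts_circ, meta, "circRNA"),
    miRNA = read_count_table(config$counts_mirna, meta, "miRNA"),
    mRNA = read_count_table(config$counts_mrna, meta, "mRNA")))
  sids <- lapply(counts, function(cm) colnames(cm$values))
  if (!all(vapply(sids, identical, TRUE, y = sids[[1L]])))
    stop("pipeline stage 'read_inputs' failed: sample ids differ between ",
         "the three count tables")

  de <- run("de_analysis", lapply(names(counts), function(cl)
    run_de(counts[[cl]], thresholds = config$thresholds[[cl]],
           method = config$de_method,
           reference_group = config$reference_group,
           treatment_group = config$treatment_group,
           pseudocount = config$pseudocount)))
  names(de) <- names(counts)
  de_all <- do.call(rbind, de)
  row.names(de_all) <- NULL
  de_ids <- lapply(de, function(d) d$feature_id[d$significant])

  mirna_seqs <- run("read_sequences", read_fasta(config$mirna_fasta))
  target_seqs <- run("read_sequences", read_fasta(config$target_fasta))
  target_class <- character(0)
  known <- c(stats::setNames(rep("circRNA", nrow(counts$circRNA$values)),
                             rownames(counts$circRNA$values)),
             stats::setNames(rep("mRNA", nrow(counts$mRNA$values)),
                             rownames(counts$mRNA$values)))
  unknown <- setdiff(names(target_seqs), names(known))
  if (length(unknown))
    stop("pipeline stage 'read_sequences' failed: target sequence id(s) ",
         "absent from the circRNA/mRNA count tables: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  target_class <- known[names(target_seqs)]

  pred <- run("target_prediction", predict_targets(
    mirna_seqs, target_seqs, target_class,
    min_site_type = config$min_site_type,
    restrict_mirnas = de_ids$miRNA,
    restrict_targets = c(de_ids$circRNA, de_ids$mRNA),
    circular_targets = config$circular_targets))

  logexpr <- do.call(rbind, lapply(counts, function(cm)
    log2(normalize_cpm(cm) + config$pseudocount)))
  rownames(logexpr) <- unlist(lapply(counts, function(cm)
    rownames(cm$values)), use.names = FALSE)

  neg <- run("negative_pairs", negative_pairs(
    logexpr, pred$edges, de_ids = unlist(de_ids, use.names = FALSE),
    scc_threshold = config$scc_threshold))
  coex <- run("coexpressed_pairs", coexpressed_pairs(
    logexpr, neg, pcc_threshold = config$pcc_threshold))

  universe <- switch(config$universe_policy,
                     all_de = de_ids$miRNA,
                     targeting_de = intersect(de_ids$miRNA,
                                              unique(pred$edges$mirna_id)))
  sponge <- run("sponge_test", {
    rows <- lapply(seq_len(nrow(coex)), function(i) {
      st <- sponge_test(
        coex$circ_id[i], coex$mrna_id[i],
        neg$mirna_id[neg$target_id == coex$circ_id[i]],
        neg$mirna_id[neg$target_id == coex$mrna_id[i]],
        universe)
      data.frame(circ_id = st$circ_id, mrna_id = st$mrna_id,
                 k = st$k, K = st$K, n = st$n, N = st$N,
                 p_value = st$p_value, stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(circ_id = character(0), mrna_id = character(0),
                 k = integer(0), K = integer(0), n = integer(0),
                 N = integer(0), p_value = numeric(0),
                 stringsAsFactors = FALSE)
  })

  network <- run("build_network", build_network(
    neg, coex, sponge, de_records = de_all,
    sponge_p_cutoff = config$sponge_p_cutoff))

  enrich <- NULL
  if (!is.null(config$gmt) && !is.na(config$gmt) && nzchar(config$gmt)) {
    enrich <- run("enrichment", {
      coll <- read_gmt(config$gmt)
      over_representation(de_ids$mRNA, rownames(counts$mRNA$values), coll)
    })
  }

  p <- function(f) file.path(out, f)
  outputs <- c(de_circ = p("de_circRNA.tsv"), de_mirna = p("de_miRNA.tsv"),
               de_mrna = p("de_mRNA.tsv"),
               target_edges = p("target_edges.tsv"),
               target_sites = p("target_sites.tsv"),
               negative_pairs = p("negative_pairs.tsv"),
               coexpressed_pairs = p("coexpressed_pairs.tsv"),
               sponge_tests = p("sponge_tests.tsv"),
               network_graphml = p("network.graphml"),
               network_edges = p("network_edges.tsv"),
               triads = p("triads.tsv"))
  .write_tsv(de$circRNA, outputs[["de_circ"]])
  .write_tsv(de$miRNA, outputs[["de_mirna"]])
  .write_tsv(de$mRNA, outputs[["de_mrna"]])
  .write_tsv(pred$edges, outputs[["target_edges"]])
  .write_tsv(pred$sites, outputs[["target_sites"]])
  .write_tsv(neg, outputs[["negative_pairs"]])
  .write_tsv(coex, outputs[["coexpressed_pairs"]])
  .write_tsv(sponge, outputs[["sponge_tests"]])
  write_network(network, graphml_path = outputs[["network_graphml"]],
                edges_path = outputs[["network_edges"]],
                triads_path = outputs[["triads"]])
  if (!is.null(enrich)) {
    outputs[["enrichment"]] <- p("enrichment.tsv")
    .write_tsv(enrich, outputs[["enrichment"]])
  }

  inputs <- c(counts_circ = config$counts_circ,
              counts_mirna = config$counts_mirna,
              counts_mrna = config$counts_mrna,
              samples = config$samples,
              mirna_fasta = config$mirna_fasta,
              target_fasta = config$target_fasta)
  if (!is.null(config$gmt)) inputs[["gmt"]] <- config$gmt
  params <- unclass(config)
  params$thresholds <- lapply(params$thresholds, unclass)
  manifest <- list(
    tool = "ceRNAnet",
    inputs = as.list(tools::md5sum(inputs)),
    parameters = params,
    stage_counts = list(
      features_tested = lapply(counts, function(cm) nrow(cm$values)),
      de_significant = lapply(de_ids, length),
      target_edges = nrow(pred$edges),
      target_sites = nrow(pred$sites),
      negative_pairs = nrow(neg),
      negative_pairs_excluded_constant =
        attr(neg, "n_excluded_constant"),
      coexpressed_pairs = nrow(coex),
      sponge_tests = nrow(sponge),
      sponge_universe_size = length(universe),
      network_nodes = nrow(network$nodes),
      network_edges = nrow(network$edges),
      triads = nrow(network$triads),
      enrichment_terms = if (is.null(enrich)) 0L else nrow(enrich)),
    outputs = NULL)
  manifest_path <- p("manifest.json")
  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  manifest$files <- c(outputs, manifest = manifest_path)
  manifest$network <- network
  invisible(manifest)
}
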