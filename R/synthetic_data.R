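# Synthetic two-group count data with planted sponge triads.
#
# Generative model (log2 scale of the NB mean):
#   non-DE feature     log2 mu = log2 b
#   plain DE feature   log2 mu = log2 b + L * a_s + eps(f, s)
#   triad member       log2 mu = log2 b + L * a_s + dir * A * c * w_s
# where b is a log-uniform baseline, L = de_log2fc, dir = +1/-1 the
# planted direction and a_s the per-sample "activation": the 0/1 group
# indicator g_s for up-regulated features and 1 - g_s for down-regulated
# ones. A DE feature therefore sits at its low state b in one condition
# and at b * 2^L in the other; with balanced up/down assignment this keeps
# the expected library size equal between groups, so plain CPM
# normalization (no TMM-style composition correction, which is out of
# scope) does not manufacture spurious fold changes in the null features.
# eps is independent Gaussian jitter (sd de_noise_sd), c = triad_coupling,
# A = coupling_amplitude and w_s a deterministic within-group "stress
# intensity" offset shared by all triad members (equally spaced in
# [-1/3, 1/3] over the samples of each group). Within a triad the circRNA
# and mRNA share dir while the miRNA gets -dir, which produces the
# negative miRNA correlations and positive circ-mRNA correlation the
# downstream screens look for. Counts are NB(mu, dispersion) with
# variance mu + dispersion * mu^2.
#
# Sequences: random miRNAs (seed-distinct by construction) and random
# targets that are *scrubbed* of all chance seed matches before the true
# and decoy sites are planted, so the ground-truth edge list is exhaustive.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the reference benchmark: a 3 vs 3 design
#' (groups `"CG"`/`"HS"`), 200 circRNAs / 100 miRNAs / 500 mRNAs, 30
#' differentially expressed features per class at a planted effect of
#' `de_log2fc = 4` (16-fold; heat-shock-scale induction), low biological
#' noise (`nb_dispersion = 0.01`), 10 planted triads at full coupling and
#' 20 decoy target edges not tied to correlated expression.
#'
#' @param n_per_group samples per group (>= 2).
#' @param n_circ,n_mirna,n_mrna feature counts per class.
#' @param baseline_mean_range positive pair (low, high); baselines are
#'   log-uniform on this range (expected counts).
#' @param nb_dispersion negative-binomial dispersion
#'   (variance = mu + dispersion * mu^2); values below 1e-8 fall back to
#'   Poisson sampling.
#' @param n_de_per_class planted DE features per class (includes triad
#'   members).
#' @param de_log2fc planted absolute log2 fold change (> 0).
#' @param n_triads planted triads, `<= min(n_circ, n_mirna, n_mrna)` and
#'   `<= n_de_per_class`.
#' @param triad_coupling coupling strength in (0, 1\] scaling the shared
#'   within-group stress signal of triad members.
#' @param coupling_amplitude log2 amplitude of that shared signal at full
#'   coupling (default 1).
#' @param de_noise_sd sd of the independent log2 jitter of non-triad DE
#'   features (default 0.3).
#' @param n_decoy_edges planted seed-match edges between non-triad
#'   features, with no expression coupling (default 20).
#' @param seed integer RNG seed; identical configs give identical datasets.
#' @param group_labels pair of group labels, reference first.
#' @return validated list of class `"SimulationConfig"`.
#' @export
simulation_config <- function(n_per_group = 3L,
                              n_circ = 200L, n_mirna = 100L, n_mrna = 500L,
                              baseline_mean_range = c(500, 5000),
                              nb_dispersion = 0.01,
                              n_de_per_class = 30L,
                              de_log2fc = 4,
                              n_triads = 10L,
                              triad_coupling = 1,
                              coupling_amplitude = 1,
                              de_noise_sd = 0.3,
                              n_decoy_edges = 20L,
                              seed = 1L,
                              group_labels = c("CG", "HS")) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
              n_mrna = as.integer(n_mrna),
              baseline_mean_range = as.numeric(baseline_mean_range),
              nb_dispersion = as.numeric(nb_dispersion),
              n_de_per_class = as.integer(n_de_per_class),
              de_log2fc = as.numeric(de_log2fc),
              n_triads = as.integer(n_triads),
              triad_coupling = as.numeric(triad_coupling),
              coupling_amplitude = as.numeric(coupling_amplitude),
              de_noise_sd = as.numeric(de_noise_sd),
              n_decoy_edges = as.integer(n_decoy_edges),
              seed = as.integer(seed),
              group_labels = as.character(group_labels))
  class(cfg) <- "SimulationConfig"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid SimulationConfig field '", field, "': ", msg)
  chk(cfg$n_per_group >= 2L, "n_per_group", "need >= 2 samples per group")
  for (f in c("n_circ", "n_mirna", "n_mrna"))
    chk(cfg[[f]] >= 1L, f, "must be strictly positive")
  chk(length(cfg$baseline_mean_range) == 2L &&
        all(cfg$baseline_mean_range > 0) &&
        cfg$baseline_mean_range[1L] <= cfg$baseline_mean_range[2L],
      "baseline_mean_range", "need positive (low, high) with low <= high")
  chk(cfg$nb_dispersion > 0, "nb_dispersion", "must be strictly positive")
  chk(cfg$n_de_per_class >= 0L, "n_de_per_class", "must be >= 0")
  chk(cfg$de_log2fc > 0, "de_log2fc", "must be strictly positive")
  chk(cfg$n_triads >= 0L &&
        cfg$n_triads <= min(cfg$n_circ, cfg$n_mirna, cfg$n_mrna),
      "n_triads", "must be between 0 and min(n_circ, n_mirna, n_mrna)")
  chk(cfg$n_triads <= max(cfg$n_de_per_class, 0L) || cfg$n_triads == 0L,
      "n_triads", "triad members must fit inside n_de_per_class")
  chk(cfg$triad_coupling > 0 && cfg$triad_coupling <= 1,
      "triad_coupling", "must lie in (0, 1]")
  chk(cfg$coupling_amplitude > 0, "coupling_amplitude",
      "must be strictly positive")
  chk(cfg$de_noise_sd >= 0, "de_noise_sd", "must be >= 0")
  chk(cfg$n_decoy_edges >= 0L, "n_decoy_edges", "must be >= 0")
  chk(length(cfg$group_labels) == 2L &&
        !anyDuplicated(cfg$group_labels),
      "group_labels", "need two distinct labels")
  invisible(cfg)
}

#' Plant a canonical seed-match site into a target sequence
#'
#' Overwrites the bases of `target_seq` starting at 0-based `position`
#' with the exact seed match required by `site_type` (see
#' [find_seed_sites()] for the definitions); all other positions are
#' unchanged.
#'
#' @param mirna_seq miRNA sequence (>= 8 nt, A/C/G/U; T normalized to U).
#' @param target_seq target sequence to modify.
#' @param site_type one of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @param position 0-based offset of the site in the target.
#' @return the modified target sequence.
#' @examples
#' plant_seed_sites("UGAGGUAGUAGGUUGUAUAGUU",
#'                  strrep("A", 30), "7mer-m8", 0)
#' @export
plant_seed_sites <- function(mirna_seq, target_seq, site_type, position) {
  mirna_seq <- .norm_rna(mirna_seq, "miRNA")
  target_seq <- .norm_rna(target_seq, "target")
  if (nchar(mirna_seq) < 8L) stop("miRNA must be at least 8 nt long")
  if (!site_type %in% names(.SITE_TYPES))
    stop("site_type must be one of: ",
         paste(names(.SITE_TYPES), collapse = ", "))
  site <- .site_string(mirna_seq, site_type)
  if (position < 0 || position + nchar(site) > nchar(target_seq))
    stop("site does not fit the target at position ", position)
  substr(target_seq, position + 1L, position + nchar(site)) <- site
  target_seq
}

# the literal target-side string of a site type
.site_string <- function(mirna, site_type) {
  s <- .seed_strings(mirna)
  switch(site_type,
         "6mer" = s$core6,
         "7mer-A1" = paste0(s$core6, "A"),
         "7mer-m8" = paste0(s$m8, s$core6),
         "8mer" = paste0(s$m8, s$core6, "A"))
}

# --- internal sequence machinery -------------------------------------------

.random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# miRNAs whose 6mer seed cores are mutually distinct and never occur inside
# another miRNA's full 8mer site string; this keeps planted sites from
# silently creating edges for a second miRNA.
.simulate_mirna_seqs <- function(n) {
  seqs <- character(0)
  hex_pool <- character(0)   # all hexamer substrings of accepted 8mer sites
  core_pool <- character(0)
  guard <- 0L
  while (length(seqs) < n) {
    guard <- guard + 1L
    if (guard > 50L * n) stop("failed to sample seed-distinct miRNAs")
    cand <- .random_rna(sample(20:24, 1L))
    core <- .seed_strings(cand)$core6
    site8 <- .site_string(cand, "8mer")
    hex8 <- substring(site8, 1:3, 6:8)
    if (core %in% hex_pool) next
    if (any(core_pool %in% hex8)) next
    seqs <- c(seqs, cand)
    hex_pool <- c(hex_pool, hex8)
    core_pool <- c(core_pool, core)
  }
  seqs
}

# Remove every occurrence of a forbidden hexamer from the sequences by
# point mutation, leaving protected intervals untouched. `protected` is a
# list (per sequence) of logical vectors. Iterates to a fixed point.
.scrub_seed_matches <- function(seqs, forbidden, protected = NULL) {
  if (!length(forbidden)) return(seqs)
  bases <- c("A", "C", "G", "U")
  for (s in seq_along(seqs)) {
    prot <- if (is.null(protected)) rep(FALSE, nchar(seqs[s])) else
      protected[[s]]
    for (iter in 1:200) {
      chars <- strsplit(seqs[s], "")[[1L]]
      L <- length(chars)
      if (L < 6L) break
      starts <- 1:(L - 5L)
      hex <- substring(seqs[s], starts, starts + 5L)
      bad <- starts[hex %in% forbidden]
      if (!length(bad)) break
      changed <- FALSE
      for (i in bad) {
        win <- i:(i + 5L)
        free <- win[!prot[win]]
        if (!length(free)) next  # fully protected; caller must handle
        pos <- free[ceiling(length(free) / 2L)]
        chars[pos] <- sample(setdiff(bases, chars[pos]), 1L)
        changed <- TRUE
      }
      if (!changed) break
      seqs[s] <- paste(chars, collapse = "")
    }
  }
  seqs
}

# --- main generator ---------------------------------------------------------

#' Simulate a complete synthetic dataset with planted sponge triads
#'
#' Generates negative-binomial count matrices for the three RNA classes
#' over a shared two-group sample design, miRNA and target sequences in
#' which exactly the ground-truth seed-match edges occur (chance matches
#' are scrubbed away before planting), and the ground-truth tables
#' describing what was planted. See the package vignette for the
#' generative model.
#'
#' @param config a [simulation_config()].
#' @return list of class `"SyntheticDataset"` with elements `counts_circ`,
#'   `counts_mirna`, `counts_mrna` ([count_matrix()] objects),
#'   `mirna_seqs`, `target_seqs` (named character vectors),
#'   `target_class` (named character vector for the targets), `truth`
#'   (list with data.frames `de_features`, `target_edges`, `triads`) and
#'   `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_per_group
  samples <- paste0(rep(config$group_labels, each = n), "-",
                    rep(seq_len(n), 2L))
  groups <- stats::setNames(rep(config$group_labels, each = n), samples)
  g01 <- as.numeric(groups == config$group_labels[2L])

  ids <- list(circRNA = sprintf("circ_%04d", seq_len(config$n_circ)),
              miRNA = sprintf("miR_%04d", seq_len(config$n_mirna)),
              mRNA = sprintf("mRNA_%04d", seq_len(config$n_mrna)))

  # planted DE assignment; triad members occupy the first slots and
  # up/down counts are kept balanced so library mass stays comparable
  tdir <- if (config$n_triads > 0L)
    sample(rep(c(1, -1), length.out = config$n_triads)) else numeric(0)
  de <- list(); triad_members <- list()
  for (cl in names(ids)) {
    pick <- sample(ids[[cl]], config$n_de_per_class)
    triad_members[[cl]] <- pick[seq_len(config$n_triads)]
    dirs <- numeric(config$n_de_per_class)
    dirs[seq_len(config$n_triads)] <- if (cl == "miRNA") -tdir else tdir
    n_rest <- config$n_de_per_class - config$n_triads
    if (n_rest > 0L)
      dirs[(config$n_triads + 1L):config$n_de_per_class] <-
        sample(rep(c(1, -1), length.out = n_rest))
    de[[cl]] <- stats::setNames(dirs, pick)
  }

  # deterministic within-group stress offsets, equally spaced
  w <- rep(seq(-1 / 3, 1 / 3, length.out = n), 2L)
  amp <- config$coupling_amplitude * config$triad_coupling

  counts <- list()
  for (cl in names(ids)) {
    f <- ids[[cl]]
    b <- exp(stats::runif(length(f), log(config$baseline_mean_range[1L]),
                          log(config$baseline_mean_range[2L])))
    lmu <- matrix(rep(log2(b), length(samples)), nrow = length(f),
                  dimnames = list(f, samples))
    is_triad <- f %in% triad_members[[cl]]
    for (i in which(f %in% names(de[[cl]]))) {
      dir <- de[[cl]][[f[i]]]
      act <- if (dir > 0) g01 else 1 - g01   # low state b, high state b*2^L
      lmu[i, ] <- lmu[i, ] + config$de_log2fc * act
      if (is_triad[i]) {
        lmu[i, ] <- lmu[i, ] + dir * amp * w
      } else {
        lmu[i, ] <- lmu[i, ] + stats::rnorm(length(samples), 0,
                                            config$de_noise_sd)
      }
    }
    mu <- 2^lmu
    vals <- if (config$nb_dispersion < 1e-8) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$nb_dispersion),
             nrow = nrow(mu))
    }
    dimnames(vals) <- dimnames(lmu)
    counts[[cl]] <- count_matrix(vals, groups, cl)
  }

  # sequences: miRNAs, then scrubbed random targets, then planted sites
  mirna_seqs <- stats::setNames(.simulate_mirna_seqs(config$n_mirna),
                                ids$miRNA)
  target_ids <- c(ids$circRNA, ids$mRNA)
  target_class <- stats::setNames(
    c(rep("circRNA", config$n_circ), rep("mRNA", config$n_mrna)),
    target_ids)
  target_seqs <- stats::setNames(
    vapply(sample(200:2000, length(target_ids), replace = TRUE),
           .random_rna, ""),
    target_ids)
  cores <- vapply(mirna_seqs, function(m) .seed_strings(m)$core6, "")
  target_seqs <- .scrub_seed_matches(target_seqs, cores)

  # edge list to realize: two per triad, plus decoys between non-triad
  # features (decoys carry no expression coupling by construction)
  edges <- data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), site_type = character(0),
                      is_decoy = logical(0), stringsAsFactors = FALSE)
  if (config$n_triads > 0L) {
    edges <- rbind(edges, data.frame(
      mirna_id = rep(triad_members$miRNA, 2L),
      target_id = c(triad_members$circRNA, triad_members$mRNA),
      target_class = rep(c("circRNA", "mRNA"), each = config$n_triads),
      site_type = "8mer", is_decoy = FALSE, stringsAsFactors = FALSE))
  }
  if (config$n_decoy_edges > 0L) {
    free_mirnas <- setdiff(ids$miRNA, triad_members$miRNA)
    free_targets <- setdiff(target_ids,
                            c(triad_members$circRNA, triad_members$mRNA))
    if (length(free_mirnas) && length(free_targets)) {
      seen <- character(0)
      while (sum(edges$is_decoy) < config$n_decoy_edges) {
        m <- sample(free_mirnas, 1L)
        t <- sample(free_targets, 1L)
        if (paste(m, t) %in% seen) next
        seen <- c(seen, paste(m, t))
        edges <- rbind(edges, data.frame(
          mirna_id = m, target_id = t,
          target_class = unname(target_class[t]),
          site_type = "7mer-m8", is_decoy = TRUE, stringsAsFactors = FALSE))
      }
    }
  }

  protected <- lapply(target_seqs, function(s) rep(FALSE, nchar(s)))
  slot_count <- stats::setNames(integer(length(target_ids)), target_ids)
  for (i in seq_len(nrow(edges))) {
    tid <- edges$target_id[i]
    pos <- 30L + slot_count[[tid]] * 40L  # 0-based, spaced sites
    site_len <- nchar(.site_string(mirna_seqs[[edges$mirna_id[i]]],
                                   edges$site_type[i]))
    if (pos + site_len > nchar(target_seqs[[tid]]))
      stop("target ", tid, " too short for planted site ", i)
    target_seqs[[tid]] <- plant_seed_sites(mirna_seqs[[edges$mirna_id[i]]],
                                           target_seqs[[tid]],
                                           edges$site_type[i], pos)
    protected[[tid]][(pos + 1L):(pos + site_len)] <- TRUE
    slot_count[[tid]] <- slot_count[[tid]] + 1L
  }
  # planting can create chance matches at site junctions; scrub around the
  # protected intervals until clean
  target_seqs <- .scrub_seed_matches(target_seqs, cores, protected)

  truth <- list(
    de_features = do.call(rbind, lapply(names(de), function(cl) {
      if (!length(de[[cl]]))
        return(data.frame(rna_class = character(0), feature_id = character(0),
                          direction = character(0), stringsAsFactors = FALSE))
      data.frame(rna_class = cl, feature_id = names(de[[cl]]),
                 direction = ifelse(de[[cl]] > 0, "up", "down"),
                 stringsAsFactors = FALSE, row.names = NULL)
    })),
    target_edges = edges,
    triads = if (config$n_triads > 0L) {
      data.frame(circ_id = triad_members$circRNA,
                 mirna_id = triad_members$miRNA,
                 mrna_id = triad_members$mRNA, stringsAsFactors = FALSE)
    } else {
      data.frame(circ_id = character(0), mirna_id = character(0),
                 mrna_id = character(0), stringsAsFactors = FALSE)
    })

  structure(list(counts_circ = counts$circRNA,
                 counts_mirna = counts$miRNA,
                 counts_mrna = counts$mRNA,
                 mirna_seqs = mirna_seqs,
                 target_seqs = target_seqs,
                 target_class = target_class,
                 truth = truth,
                 config = config),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(paste0("SyntheticDataset: %d circRNA / %d miRNA / %d mRNA ",
                     "features, %d samples, %d planted triads, %d planted ",
                     "edges\n"),
              nrow(x$counts_circ$values), nrow(x$counts_mirna$values),
              nrow(x$counts_mrna$values), ncol(x$counts_circ$values),
              nrow(x$truth$triads), nrow(x$truth$target_edges)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text fixture files
#'
#' Writes the three count tables, the two FASTA files, the sample-metadata
#' table and the ground-truth tables into `directory`. Re-reading the
#' files through the pipeline readers reproduces the in-memory dataset.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param directory output directory (created if needed).
#' @return invisibly, a named character vector (the manifest of written
#'   files).
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  p <- function(f) file.path(directory, f)
  files <- c(counts_circ = p("counts_circ.tsv"),
             counts_mirna = p("counts_mirna.tsv"),
             counts_mrna = p("counts_mrna.tsv"),
             samples = p("samples.tsv"),
             mirna_fasta = p("mirna.fasta"),
             target_fasta = p("targets.fasta"),
             truth_de = p("truth_de_features.tsv"),
             truth_edges = p("truth_target_edges.tsv"),
             truth_triads = p("truth_triads.tsv"))
  write_count_table(dataset$counts_circ, files[["counts_circ"]])
  write_count_table(dataset$counts_mirna, files[["counts_mirna"]])
  write_count_table(dataset$counts_mrna, files[["counts_mrna"]])
  .write_tsv(data.frame(sample_id = names(dataset$counts_circ$groups),
                        group = unname(dataset$counts_circ$groups),
                        stringsAsFactors = FALSE),
             files[["samples"]])
  write_fasta(dataset$mirna_seqs, files[["mirna_fasta"]])
  write_fasta(dataset$target_seqs, files[["target_fasta"]])
  .write_tsv(dataset$truth$de_features, files[["truth_de"]])
  .write_tsv(dataset$truth$target_edges, files[["truth_edges"]])
  .write_tsv(dataset$truth$triads, files[["truth_triads"]])
  invisible(files)
}
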