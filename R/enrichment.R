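#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line, fields are term id, term
#' description, then member ids.
#'
#' @param path GMT file path.
#' @param source_tag optional label stored on the collection (defaults to
#'   the file name).
#' @return list of class `"GeneSetCollection"`: named list `sets` (each a
#'   list with `name` and `members`) plus a `source` tag.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": need term, description, >=1 member")
    if (f[1L] %in% names(sets))
      stop("duplicate term id in GMT: ", f[1L])
    sets[[f[1L]]] <- list(name = f[2L], members = unique(f[-(1:2)]))
  }
  structure(list(sets = sets, source = source_tag),
            class = "GeneSetCollection")
}

#' Build a gene-set collection in code
#'
#' @param members named list of character vectors (term id -> member ids).
#' @param names optional named character vector of term descriptions.
#' @param source_tag label for the collection.
#' @return a `"GeneSetCollection"`.
#' @export
gene_set_collection <- function(members, names = NULL,
                                source_tag = "in-memory") {
  if (is.null(base::names(members)) || anyDuplicated(base::names(members)))
    stop("members must be a uniquely named list")
  if (any(!lengths(members)))
    stop("member sets must be non-empty")
  sets <- lapply(base::names(members), function(id) {
    list(name = if (!is.null(names) && id %in% base::names(names))
      names[[id]] else id,
      members = unique(as.character(members[[id]])))
  })
  base::names(sets) <- base::names(members)
  structure(list(sets = sets, source = source_tag),
            class = "GeneSetCollection")
}

#' Hypergeometric over-representation analysis
#'
#' For every term, the member set is intersected with the universe
#' (size `K`), the query hits are counted (`k`), and
#' `p = hypergeom_sf(k, K, n, N)` with `n` the query size and `N` the
#' universe size. BH q-values are computed across all tested terms.
#'
#' @param query character id set, must be contained in `universe`.
#' @param universe character id set (the background; typically all
#'   features tested for differential expression).
#' @param collection a [read_gmt()] / [gene_set_collection()] object.
#' @return data.frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`, sorted by p then term id.
#' @export
over_representation <- function(query, universe, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  esc <- setdiff(query, universe)
  if (length(esc))
    stop("query escapes the universe: ",
         paste(utils::head(esc, 5L), collapse = ", "))
  n <- length(query); N <- length(universe)
  rows <- lapply(names(collection$sets), function(id) {
    mem <- intersect(collection$sets[[id]]$members, universe)
    k <- length(intersect(query, mem))
    data.frame(term_id = id, term_name = collection$sets[[id]]$name,
               k = k, K = length(mem), n = n, N = N,
               p_value = hypergeom_sf(k, length(mem), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}
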