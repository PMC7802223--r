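#' Feature-by-sample count matrix with a two-group design
#'
#' The basic substrate of the pipeline: an integer matrix of read counts
#' (features in rows, samples in columns) together with a group label per
#' sample and an RNA-class tag. Exactly two group labels must be present
#' (e.g. control `"CG"` and heat stress `"HS"`).
#'
#' @param values integer matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); all entries non-negative integers.
#' @param groups character vector of group labels, one per sample. If
#'   named, it is reordered to match `colnames(values)`.
#' @param rna_class one of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#'
#' @return An object of class `"CountMatrix"`: a list with elements
#'   `values`, `groups` (named by sample id) and `rna_class`.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 2,
#'             dimnames = list(c("f1", "f2"),
#'                             c(paste0("CG-", 1:3), paste0("HS-", 1:3))))
#' cm <- count_matrix(m, rep(c("CG", "HS"), each = 3), "mRNA")
#' @export
count_matrix <- function(values, groups,
                         rna_class = c("circRNA", "miRNA", "mRNA")) {
  rna_class <- match.arg(rna_class)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix requires feature ids (rownames) and sample ids (colnames)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("need one group label per sample column")
  if (length(unique(groups)) != 2L)
    stop("exactly two group labels are required, got: ",
         paste(unique(groups), collapse = ", "))
  if (anyNA(values) || any(values < 0) || any(values != round(values)))
    stop("counts must be non-negative integers")
  cs <- colSums(values)
  if (any(cs == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(values)[cs == 0], collapse = ", "))
  storage.mode(values) <- "double"  # keeps >2^31 totals safe; values stay integral
  structure(list(values = values,
                 groups = stats::setNames(groups, colnames(values)),
                 rna_class = rna_class),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix [%s]: %d features x %d samples\n",
              x$rna_class, nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Feature and sample ids of a CountMatrix
#' @param x a `CountMatrix`.
#' @return character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)
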