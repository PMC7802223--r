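#' ceRNAnet: competing endogenous RNA network inference
#'
#' Infers circRNA-miRNA-mRNA ceRNA regulatory networks from two-group
#' count data: class-specific differential expression, canonical
#' seed-match target prediction, Spearman/Pearson correlation screens, a
#' hypergeometric shared-sponge test, tripartite network assembly, and a
#' synthetic-data generator with planted triads for end-to-end
#' verification. See `vignette` sources under `vignettes/` and the README
#' for a worked example.
#'
#' @keywords internal
"_PACKAGE"
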