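#' Differential-expression flags
#'
#' Flags gene i as differentially expressed iff `max_j |lfc_ij| >=
#' threshold` for at least one genotype (inclusive threshold; default 2,
#' i.e. at least a four-fold change up or down).
#'
#' @param l1 Genes x genotypes LFC matrix.
#' @param threshold Positive absolute-LFC threshold (default 2).
#' @return Named logical vector over genes.
#' @export
deg_flags <- function(l1, threshold = 2) {
  stopifnot(threshold > 0)
  flags <- apply(abs(l1), 1, max) >= threshold
  stats::setNames(flags, rownames(l1))
}

#' One-sided Fisher exact test for enrichment
#'
#' Upper-tail (enrichment) hypergeometric test on a 2x2 contingency table
#' with cells a = selected with the property, b = selected without, c =
#' unselected with, d = unselected without: `P(X >= a)` for
#' `X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b)`. Degenerate margins
#' (no selected items, or no item with the property) give p = 1 by
#' convention.
#'
#' @param a,b,c,d Non-negative integer cell counts; alternatively `a` may be
#'   a 2x2 matrix `rbind(c(a, b), c(c, d))`.
#' @return The one-sided p-value in (0, 1].
#' @export
fisher_one_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(tab < 0) || any(tab != round(tab)) || sum(tab) == 0)
    stop("contingency table must hold non-negative integers with a positive total")
  if (sum(tab[1, ]) == 0 || sum(tab[, 1]) == 0) return(1)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Assemble the selected-gene report
#'
#' One row per selected gene with its selected module memberships, trait
#' attribution, DEG flag, and maximum absolute LFC across genotypes, plus a
#' summary block with per-trait counts, the DEG fraction among selected
#' genes, and a one-sided Fisher exact test of DEG enrichment in the
#' selection (selected vs unselected x DEG vs not, over all genes of `l1`).
#' If `known_genes` is given, a second Fisher test checks enrichment of
#' those externally known genes among the selection, over the same
#' universe.
#'
#' @param selection A `module_selection` from [select_modules()].
#' @param f Affiliation matrix.
#' @param deg Named logical DEG flags from [deg_flags()].
#' @param l1 Genes x genotypes LFC matrix (defines the gene universe).
#' @param known_genes Optional character vector of externally known
#'   treatment-related gene ids.
#' @return A list of class `gene_report`: `table` (data frame) and
#'   `summary` (list of counts, fractions and p-values).
#' @export
build_report <- function(selection, f, deg, l1, known_genes = NULL) {
  genes <- selection$genes
  att <- selection$attribution
  tab <- if (length(genes)) {
    data.frame(
      gene_id = genes,
      modules = vapply(genes, function(g)
        paste(sort(unique(att$module[att$gene_id == g])), collapse = ";"),
        character(1)),
      traits = vapply(genes, function(g)
        paste(sort(unique(att$trait[att$gene_id == g])), collapse = ";"),
        character(1)),
      deg = unname(deg[genes]),
      max_abs_lfc = apply(abs(l1[genes, , drop = FALSE]), 1, max),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), modules = character(0),
               traits = character(0), deg = logical(0),
               max_abs_lfc = numeric(0))
  }
  universe <- rownames(l1)
  sel <- universe %in% genes
  a <- sum(sel & deg[universe])
  b <- sum(sel & !deg[universe])
  cc <- sum(!sel & deg[universe])
  dd <- sum(!sel & !deg[universe])
  genes_per_trait <- lapply(names(selection$modules_by_trait),
    function(tr) length(unique(att$gene_id[att$trait == tr])))
  names(genes_per_trait) <- names(selection$modules_by_trait)
  summary <- list(
    n_selected = length(genes),
    genes_per_trait = genes_per_trait,
    deg_count = a,
    deg_fraction = if (length(genes)) a / length(genes) else 0,
    deg_table = c(a = a, b = b, c = cc, d = dd),
    fisher_p_deg = fisher_one_sided(a, b, cc, dd))
  if (!is.null(known_genes)) {
    known <- universe %in% known_genes
    a2 <- sum(sel & known); b2 <- sum(sel & !known)
    c2 <- sum(!sel & known); d2 <- sum(!sel & !known)
    summary$known_table <- c(a = a2, b = b2, c = c2, d = d2)
    summary$fisher_p_known <- fisher_one_sided(a2, b2, c2, d2)
  }
  structure(list(table = tab, summary = summary), class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("gene_report: %d selected genes, %d DEG (%.0f%%), Fisher p (DEG enrichment) = %.3g\n",
              s$n_selected, s$deg_count, 100 * s$deg_fraction, s$fisher_p_deg))
  if (!is.null(s$fisher_p_known))
    cat(sprintf("  known-gene enrichment: Fisher p = %.3g\n", s$fisher_p_known))
  invisible(x)
}
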