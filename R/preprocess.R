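#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample correcting library size
#' and RNA composition bias. For each sample the factor is the median, over
#' reference genes, of the ratio between the sample's count and the gene's
#' geometric mean across all samples; reference genes are those with a
#' strictly positive geometric mean (i.e. no zero count in any sample).
#'
#' @param counts A `count_matrix` object or a genes x samples numeric matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$values else counts
  log_geo <- rowMeans(log(m))
  ref <- is.finite(log_geo)            # genes with all counts > 0
  if (!any(ref))
    stop("no gene has nonzero counts in every sample; ",
         "consider adding a pseudocount or using a less sparse input")
  sf <- apply(m[ref, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo[ref]))
  })
  stats::setNames(sf, colnames(m))
}

#' Normalize counts and average replicates
#'
#' Divides each sample column by its size factor (giving the
#' replicate-level normalized matrix) and averages the biological
#' replicates of every genotype under each condition. Columns of the
#' averaged matrix are ordered all control genotypes first, then all
#' treatment genotypes, preserving the genotype order of the sample sheet.
#'
#' @param counts A `count_matrix` object.
#' @param sf Size factors as returned by [size_factors()]; computed if `NULL`.
#' @return A list of class `normalized_expression`: `d1` (genes x samples,
#'   normalized), `d2` (genes x 2m, replicate-averaged; column names
#'   `genotype.condition`), `genotypes`.
#' @export
normalize_and_average <- function(counts, sf = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(sf)) sf <- size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be strictly positive")
  sf <- sf[colnames(counts$values)]
  d1 <- sweep(counts$values, 2, sf, "/")
  sheet <- counts$samples
  genotypes <- unique(sheet$genotype)
  cols <- expand.grid(genotype = genotypes,
                      condition = c("control", "treatment"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cols <- cols[order(match(cols$condition, c("control", "treatment"))), ]
  d2 <- vapply(seq_len(nrow(cols)), function(i) {
    sel <- sheet$genotype == cols$genotype[i] & sheet$condition == cols$condition[i]
    rowMeans(d1[, sheet$sample[sel], drop = FALSE])
  }, numeric(nrow(d1)))
  if (nrow(d1) == 1) d2 <- matrix(d2, nrow = 1)
  dimnames(d2) <- list(rownames(d1),
                       paste(cols$genotype, cols$condition, sep = "."))
  structure(list(d1 = d1, d2 = d2, genotypes = genotypes),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("normalized_expression: %d genes, %d genotypes (d1: %d samples, d2: %d columns)\n",
              nrow(x$d2), length(x$genotypes), ncol(x$d1), ncol(x$d2)))
  invisible(x)
}

d2_matrix <- function(x) {
  if (inherits(x, "normalized_expression")) x$d2 else x
}

#' Filter genes on the averaged expression matrix
#'
#' Removes low-variance genes, whose ratio of upper (75th) to lower (25th)
#' quantile across columns falls below `quantile_ratio_max`, and
#' low-expression genes, with more than `low_expr_frac` of columns below
#' `low_expr_value`. A gene with lower quantile 0 but positive upper
#' quantile has an infinite ratio and passes the variance rule.
#'
#' @param x A `normalized_expression` object or an averaged expression matrix.
#' @param quantile_ratio_max Variance rule threshold (default 1.5).
#' @param low_expr_value Expression level considered low (default 10).
#' @param low_expr_frac Fraction of columns allowed below `low_expr_value`
#'   before a gene is removed (default 0.8; removal requires strictly more).
#' @return The same type as `x`, restricted to surviving genes.
#' @export
filter_expression <- function(x, quantile_ratio_max = 1.5,
                              low_expr_value = 10, low_expr_frac = 0.8) {
  d2 <- d2_matrix(x)
  stopifnot(nrow(d2) >= 1)
  q <- t(apply(d2, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE))
  ratio <- ifelse(q[, 1] > 0, q[, 2] / q[, 1],
                  ifelse(q[, 2] > 0, Inf, 1))
  low_var <- ratio < quantile_ratio_max
  low_expr <- rowMeans(d2 < low_expr_value) > low_expr_frac
  keep <- !(low_var | low_expr)
  if (!any(keep))
    stop("expression filter removed every gene; ",
         "consider relaxing quantile_ratio_max or low_expr_value")
  subset_expression(x, keep)
}

subset_expression <- function(x, keep) {
  if (inherits(x, "normalized_expression")) {
    x$d1 <- x$d1[keep, , drop = FALSE]
    x$d2 <- x$d2[keep, , drop = FALSE]
    x
  } else {
    x[keep, , drop = FALSE]
  }
}

#' Expression log fold changes per genotype
#'
#' Splits the averaged expression matrix into its control and treatment
#' blocks and computes, per gene i and genotype j, the log2 ratio
#' `log2((t_ij + pseudocount) / (c_ij + pseudocount))`.
#'
#' @param x A `normalized_expression` object (typically after
#'   [filter_expression()]) or an averaged matrix whose first half of
#'   columns is the control block and second half the treatment block,
#'   genotypes in the same order.
#' @param pseudocount Added to both numerator and denominator so zeros stay
#'   finite (default 1, on the normalized scale).
#' @return Genes x genotypes matrix of log2 fold changes.
#' @export
lfc_expression <- function(x, pseudocount = 1) {
  d2 <- d2_matrix(x)
  m <- ncol(d2) / 2
  stopifnot(m == round(m))
  ctrl <- d2[, seq_len(m), drop = FALSE]
  trt <- d2[, m + seq_len(m), drop = FALSE]
  l0 <- log2(trt + pseudocount) - log2(ctrl + pseudocount)
  colnames(l0) <- sub("\\.control$", "", colnames(ctrl))
  l0
}

#' Filter log-fold-change profiles by interquartile range
#'
#' Removes genes whose per-row LFC interquartile range (75th minus 25th
#' percentile across genotypes) marks them as uninformative. With
#' `mode = "remove_low_variance"` (the default) genes with IQR at or below
#' the threshold are removed, keeping the variable profiles the network is
#' built from; `mode = "remove_high_variance"` removes genes with IQR above
#' the threshold instead.
#'
#' @param l0 Genes x genotypes LFC matrix.
#' @param iqr_threshold IQR threshold (default 0.25).
#' @param mode `"remove_low_variance"` or `"remove_high_variance"`.
#' @return The filtered LFC matrix.
#' @export
filter_lfc <- function(l0, iqr_threshold = 0.25,
                       mode = c("remove_low_variance", "remove_high_variance")) {
  mode <- match.arg(mode)
  stopifnot(nrow(l0) >= 1)
  q <- t(apply(l0, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE))
  iqr <- q[, 2] - q[, 1]
  keep <- if (mode == "remove_low_variance") iqr > iqr_threshold
          else iqr <= iqr_threshold
  if (!any(keep))
    stop("LFC filter removed every gene; consider changing iqr_threshold or mode")
  l0[keep, , drop = FALSE]
}

#' Phenotype log fold changes
#'
#' Per genotype and trait, the log2 ratio of the treatment to the control
#' phenotype value (after adding `pseudocount` to both).
#'
#' @param pheno A `phenotype_table`.
#' @param pseudocount Added to both values before the ratio (default 0;
#'   phenotype measurements are usually strictly positive).
#' @return Genotypes x traits matrix of log2 phenotype ratios.
#' @export
lfc_phenotypes <- function(pheno, pseudocount = 0) {
  stopifnot(inherits(pheno, "phenotype_table"))
  ctrl <- pheno$control + pseudocount
  trt <- pheno$treatment + pseudocount
  bad <- which(ctrl <= 0 | trt <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive phenotype value after pseudocount for genotype '",
         rownames(ctrl)[bad[1, 1]], "', trait '", colnames(ctrl)[bad[1, 2]], "'")
  log2(trt) - log2(ctrl)
}
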