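#' Absolute Pearson correlation similarity matrix
#'
#' Pairwise similarity between gene LFC profiles as the absolute value of
#' the Pearson correlation coefficient, so strongly negatively correlated
#' genes are connected with the same strength as positively correlated
#' ones. The diagonal is 1.
#'
#' @param l1 Genes x genotypes LFC matrix; every row must have nonzero
#'   variance (guaranteed by [filter_lfc()] in `remove_low_variance` mode).
#' @return Symmetric genes x genes similarity matrix with entries in [0, 1].
#' @export
similarity_matrix <- function(l1) {
  v <- apply(l1, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance LFC row(s): ",
         paste(utils::head(rownames(l1)[v == 0]), collapse = ", "))
  s <- abs(stats::cor(t(l1)))
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Soft-threshold a similarity matrix
#'
#' Raises each similarity entry to the power `beta`, giving the weighted
#' adjacency whose connectivity distribution is tuned toward scale-free
#' topology.
#'
#' @param s Similarity matrix from [similarity_matrix()].
#' @param beta Positive integer power (>= 1).
#' @return Weighted adjacency matrix `s^beta`.
#' @export
soft_power <- function(s, beta) {
  stopifnot(beta >= 1)
  s^beta
}

#' Scale-free topology fit of a weighted network
#'
#' Computes soft connectivities `k_i = sum_{j != i} a_ij`, bins them into
#' `n_bins` equal-width bins (linear scale, the convention of the weighted
#' co-expression literature; empty bins dropped), and regresses the log10
#' frequency fraction per bin on the log10 mean bin connectivity. The
#' regression R-squared measures how closely the connectivity distribution
#' follows a power law.
#'
#' @param a Weighted adjacency matrix, or a precomputed numeric vector of
#'   connectivities (useful for diagnostics).
#' @param n_bins Number of histogram bins (default 10, the convention of
#'   the weighted co-expression literature's fit index).
#' @return A list of class `scale_free_fit`: `r_squared`, `slope`,
#'   `bin_centers` (mean connectivity per nonempty bin), `bin_frequencies`
#'   (fraction of nodes per bin), `n_nodes`.
#' @export
scale_free_r2 <- function(a, n_bins = 10) {
  k <- if (is.matrix(a)) rowSums(a) - diag(a) else as.numeric(a)
  k <- k[k > 0]
  if (length(unique(k)) < 2)
    stop("degenerate connectivity distribution: all connectivities equal")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  nonempty <- which(counts > 0)
  if (length(nonempty) < 3)
    stop("fewer than 3 nonempty connectivity bins; cannot assess scale-free fit")
  centers <- vapply(nonempty, function(b) mean(k[bin == b]), numeric(1))
  freq <- counts[nonempty] / length(k)
  fit <- stats::lm(log10(freq) ~ log10(centers))
  structure(list(r_squared = summary(fit)$r.squared,
                 slope = unname(stats::coef(fit)[2]),
                 bin_centers = centers,
                 bin_frequencies = freq,
                 n_nodes = length(k)),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("scale_free_fit: R^2 = %.4f, slope = %.3f over %d bins (%d nodes)\n",
              x$r_squared, x$slope, length(x$bin_centers), x$n_nodes))
  invisible(x)
}

#' Select the soft-threshold power
#'
#' Scans candidate powers and returns the smallest `beta > 1` whose
#' scale-free fit reaches `r2_min`. If no candidate qualifies, the power
#' with the largest R-squared is returned and flagged.
#'
#' @param s Similarity matrix.
#' @param r2_min Minimum acceptable scale-free R-squared (default 0.8).
#' @param beta_grid Candidate integer powers (default 1:20).
#' @param n_bins Bins for [scale_free_r2()].
#' @return A list of class `beta_selection`: `beta`, `fit` (the chosen
#'   [scale_free_r2()] result), `scan` (data frame of beta, r_squared,
#'   slope), `reached_r2_min` (logical).
#' @export
select_beta <- function(s, r2_min = 0.8, beta_grid = 1:20, n_bins = 10) {
  stopifnot(length(beta_grid) >= 1)
  fits <- lapply(beta_grid, function(b) {
    tryCatch(scale_free_r2(soft_power(s, b), n_bins = n_bins),
             error = function(e) NULL)
  })
  r2 <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$r_squared,
               numeric(1))
  scan <- data.frame(beta = beta_grid, r_squared = r2,
                     slope = vapply(fits, function(f)
                       if (is.null(f)) NA_real_ else f$slope, numeric(1)))
  ok <- which(beta_grid > 1 & !is.na(r2) & r2 >= r2_min)
  if (length(ok)) {
    pick <- ok[1]
    reached <- TRUE
  } else {
    if (all(is.na(r2))) stop("scale-free fit failed for every candidate beta")
    pick <- which.max(r2)
    reached <- FALSE
    warning("no beta reached R^2 >= ", r2_min,
            "; returning the best-fitting beta = ", beta_grid[pick])
  }
  structure(list(beta = beta_grid[pick], fit = fits[[pick]], scan = scan,
                 reached_r2_min = reached),
            class = "beta_selection")
}

#' @export
print.beta_selection <- function(x, ...) {
  cat(sprintf("beta_selection: beta = %d (R^2 = %.4f%s)\n", x$beta,
              x$fit$r_squared,
              if (x$reached_r2_min) "" else ", below target R^2"))
  invisible(x)
}

#' Scan hard-threshold cutoffs over a weighted adjacency
#'
#' For each candidate cutoff reports the number of edges (strictly above the
#' cutoff), the number of non-isolated nodes, and the density of the
#' network restricted to those nodes.
#'
#' @param a Weighted adjacency matrix.
#' @param grid Sorted cutoff values in (0, 1).
#' @return Data frame of class `cutoff_scan` with columns `threshold`,
#'   `nodes`, `edges`, `density`; the total gene count is kept in
#'   `attr(, "n_genes")`.
#' @export
threshold_scan <- function(a, grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(grid > 0 & grid < 1), !is.unsorted(grid))
  ut <- upper.tri(a)
  res <- t(vapply(grid, function(tau) {
    above <- a > tau
    diag(above) <- FALSE
    edges <- sum(above[ut])
    nodes <- sum(rowSums(above) > 0)
    dens <- if (nodes >= 2) 2 * edges / (nodes * (nodes - 1)) else 0
    c(nodes = nodes, edges = edges, density = dens)
  }, numeric(3)))
  out <- data.frame(threshold = grid, nodes = res[, "nodes"],
                    edges = res[, "edges"], density = res[, "density"])
  attr(out, "n_genes") <- nrow(a)
  class(out) <- c("cutoff_scan", "data.frame")
  out
}

#' Select a hard-threshold cutoff from a scan
#'
#' If `override` is supplied it wins (the shipped default configuration
#' uses 0.2). Otherwise the smallest cutoff attaining the minimum network
#' density among grid points that keep at least `min_node_frac` of all
#' genes non-isolated is returned.
#'
#' @param scan A [threshold_scan()] result.
#' @param override Optional fixed cutoff.
#' @param min_node_frac Minimum fraction of genes that must stay
#'   non-isolated for a grid point to be eligible (default 0.05).
#' @return The selected cutoff (numeric scalar).
#' @export
select_cutoff <- function(scan, override = NULL, min_node_frac = 0.05) {
  if (!is.null(override)) return(override)
  stopifnot(nrow(scan) >= 1)
  n_genes <- attr(scan, "n_genes")
  eligible <- scan$nodes >= min_node_frac * n_genes & scan$nodes > 0
  if (!any(eligible))
    stop("no cutoff in the grid retains any non-isolated nodes")
  cand <- scan[eligible, ]
  cand$threshold[which.min(cand$density)]
}

#' Binarize a weighted adjacency at a cutoff
#'
#' Entries strictly above `tau` become edges; isolated nodes are removed
#' from the gene list.
#'
#' @param a Weighted adjacency matrix.
#' @param tau Cutoff in (0, 1).
#' @return A list of class `binary_network`: `genes` (retained ids),
#'   `adjacency` (logical symmetric matrix, zero diagonal), `tau`.
#' @export
binarize <- function(a, tau) {
  stopifnot(tau > 0, tau < 1)
  if (is.null(rownames(a)))
    dimnames(a) <- list(paste0("g", seq_len(nrow(a))),
                        paste0("g", seq_len(ncol(a))))
  adj <- a > tau
  diag(adj) <- FALSE
  keep <- rowSums(adj) > 0
  if (!any(keep))
    stop("binarized network is empty at cutoff ", tau)
  adj <- adj[keep, keep, drop = FALSE]
  structure(list(genes = rownames(a)[keep], adjacency = adj, tau = tau),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges (cutoff %g)\n",
              length(x$genes), sum(x$adjacency[upper.tri(x$adjacency)]), x$tau))
  invisible(x)
}
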