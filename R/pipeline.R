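default_config <- function() {
  list(
    preprocess = list(pseudocount = 1, quantile_ratio_max = 1.5,
                      low_expr_value = 10, low_expr_frac = 0.8,
                      lfc_iqr_threshold = 0.25,
                      lfc_filter_mode = "remove_low_variance",
                      pheno_pseudocount = 0),
    network = list(r2_min = 0.8, beta_grid = 1:20, n_bins = 10,
                   cutoff_grid = seq(0.05, 0.95, by = 0.05),
                   cutoff_override = 0.2, cutoff_scale = "adjacency",
                   min_node_frac = 0.05),
    hlc = list(min_module_size = 3),
    lasso = list(k_folds = 10, n_lambda = 100, lambda_min_ratio = 1e-4,
                 lambda_rule = "1se"),
    enrichment = list(deg_threshold = 2))
}

#' Pipeline configuration
#'
#' Builds the full nested configuration for [overlapnet()], starting from
#' the shipped defaults and overriding only the supplied entries. Unknown
#' section or key names are rejected.
#'
#' @param ... Named sections (`preprocess`, `network`, `hlc`, `lasso`,
#'   `enrichment`), each a named list of overrides; e.g.
#'   `overlapnet_control(network = list(cutoff_override = 0.3))`.
#' @return A nested list of class `overlapnet_control`.
#' @export
overlapnet_control <- function(...) {
  cfg <- default_config()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown configuration section(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    for (sec in names(over)) {
      entries <- over[[sec]]
      badk <- setdiff(names(entries), names(cfg[[sec]]))
      if (length(badk) || (length(entries) && is.null(names(entries))))
        stop("unknown key(s) in section '", sec, "': ",
             paste(if (length(badk)) badk else "<unnamed>", collapse = ", "))
      cfg[[sec]][names(entries)] <- entries
    }
  }
  structure(cfg, class = c("overlapnet_control", "list"))
}

#' Fit the full co-expression module selection workflow
#'
#' Runs the five-stage analysis end to end: (a) median-of-ratios
#' normalization, replicate averaging, gene filtering and log-fold-change
#' computation for expression and phenotypes; (b) |Pearson| similarity and
#' soft-threshold power selection against the scale-free topology criterion;
#' (c) hard thresholding and Hierarchical Link Clustering into overlapping
#' gene modules; (d) module eigengenes and per-trait cross-validated LASSO
#' selection of phenotype-associated modules; (e) DEG flagging and Fisher
#' enrichment of the selected gene set.
#'
#' @param counts A `count_matrix` from [read_counts()] / [count_matrix()].
#' @param phenotypes A `phenotype_table`.
#' @param config An [overlapnet_control()] configuration.
#' @param seed Integer seed; fans out deterministically to the seeded
#'   stages (LASSO fold assignment).
#' @param known_genes Optional character vector of externally known
#'   treatment-related gene ids for the second enrichment test.
#' @return An object of class `overlapnet`; see [print.overlapnet()],
#'   [summary.overlapnet()], [coef.overlapnet()], [plot.overlapnet()], and
#'   [write_outputs()].
#' @export
overlapnet <- function(counts, phenotypes,
                       config = overlapnet_control(), seed = 1,
                       known_genes = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(phenotypes, "phenotype_table"))
  if (!inherits(config, "overlapnet_control"))
    stop("config must be created with overlapnet_control()")
  pp <- config$preprocess
  nw <- config$network

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  # (a) preprocessing
  sf <- stage("preprocess", size_factors(counts))
  norm <- stage("preprocess", normalize_and_average(counts, sf))
  n0 <- nrow(norm$d2)
  filt <- stage("preprocess", filter_expression(
    norm, quantile_ratio_max = pp$quantile_ratio_max,
    low_expr_value = pp$low_expr_value, low_expr_frac = pp$low_expr_frac))
  n1 <- nrow(filt$d2)
  l0 <- stage("preprocess", lfc_expression(filt, pseudocount = pp$pseudocount))
  l1 <- stage("preprocess", filter_lfc(l0, iqr_threshold = pp$lfc_iqr_threshold,
                                       mode = pp$lfc_filter_mode))
  n2 <- nrow(l1)
  plfc <- stage("preprocess",
                lfc_phenotypes(phenotypes, pseudocount = pp$pheno_pseudocount))
  stopifnot(identical(rownames(plfc), colnames(l1)))

  # (b) network construction
  s <- stage("network", similarity_matrix(l1))
  bsel <- stage("network", select_beta(s, r2_min = nw$r2_min,
                                       beta_grid = nw$beta_grid,
                                       n_bins = nw$n_bins))
  a <- soft_power(s, bsel$beta)

  # (c) binarization + link clustering
  scan <- stage("network", threshold_scan(a, nw$cutoff_grid))
  tau <- stage("network", select_cutoff(scan, override = nw$cutoff_override,
                                        min_node_frac = nw$min_node_frac))
  tau_eff <- if (identical(nw$cutoff_scale, "similarity"))
    tau^bsel$beta else tau
  net <- stage("network", binarize(a, tau_eff))
  g <- stage("modules", link_graph(net))
  dendro <- stage("modules", build_link_dendrogram(g))
  part <- stage("modules", cut_at_max_density(g, dendro))
  f <- stage("modules", affiliation(g, part,
                                    min_module_size = config$hlc$min_module_size))
  n_affiliated <- sum(rowSums(f) > 0)

  # (d) eigengenes + LASSO
  if (ncol(f) == 0) {
    eg <- matrix(numeric(0), nrow = ncol(l1), ncol = 0,
                 dimnames = list(colnames(l1), character(0)))
    fits <- stats::setNames(vector("list", 0), character(0))
    selection <- structure(list(
      modules_by_trait = stats::setNames(
        rep(list(character(0)), ncol(plfc)), colnames(plfc)),
      genes = character(0),
      attribution = data.frame(gene_id = character(0), trait = character(0),
                               module = character(0))),
      class = "module_selection")
  } else {
    eg <- stage("associate", eigengene_matrix(l1, f))
    fits <- stage("associate", associate_traits(
      eg, plfc, k_folds = config$lasso$k_folds,
      n_lambda = config$lasso$n_lambda,
      lambda_min_ratio = config$lasso$lambda_min_ratio,
      lambda_rule = config$lasso$lambda_rule, seed = seed))
    selection <- stage("associate", select_modules(fits, f))
  }

  # (e) enrichment + report
  deg <- stage("enrich", deg_flags(l1, threshold = config$enrichment$deg_threshold))
  report <- stage("enrich", build_report(selection, f, deg, l1,
                                         known_genes = known_genes))

  funnel <- c(n0 = n0, n1 = n1, n2 = n2,
              network_nodes = length(net$genes),
              affiliated = n_affiliated,
              selected = length(selection$genes))
  summary_stats <- list(
    funnel = as.list(funnel),
    beta = bsel$beta,
    scale_free_r2 = bsel$fit$r_squared,
    cutoff = tau,
    n_modules = ncol(f),
    partition_density = part$density,
    overlap = overlap_histogram(f)[c("n_affiliated", "frac_multi")],
    lambda = lapply(fits, `[[`, "lambda"),
    modules_by_trait = lapply(selection$modules_by_trait, as.list),
    deg_fraction = report$summary$deg_fraction,
    fisher_p_deg = report$summary$fisher_p_deg,
    seed = seed)
  if (!is.null(report$summary$fisher_p_known))
    summary_stats$fisher_p_known <- report$summary$fisher_p_known

  structure(list(
    config = config, seed = seed,
    size_factors = sf, d2 = filt$d2, l1 = l1, pheno_lfc = plfc,
    beta = bsel$beta, beta_selection = bsel, adjacency = a,
    cutoff_scan = scan, cutoff = tau, network = net,
    partition = part, affiliation = f,
    eigengenes = eg, fits = fits, selection = selection,
    deg = deg, report = report,
    funnel = funnel, summary_stats = summary_stats),
    class = "overlapnet")
}

#' @describeIn overlapnet Compact funnel view of a fitted workflow.
#' @param x,object A fitted `overlapnet` object.
#' @param ... Unused.
#' @export
print.overlapnet <- function(x, ...) {
  f <- x$funnel
  cat("overlapnet fit\n")
  cat(sprintf("  gene funnel: %d -> %d (expression filter) -> %d (LFC filter) -> %d (network) -> %d (modules) -> %d (selected)\n",
              f["n0"], f["n1"], f["n2"], f["network_nodes"], f["affiliated"],
              f["selected"]))
  cat(sprintf("  beta = %d (scale-free R^2 = %.3f), cutoff = %g, %d modules (D = %.3f)\n",
              x$beta, x$beta_selection$fit$r_squared, x$cutoff,
              ncol(x$affiliation), x$partition$density))
  cat(sprintf("  %d selected genes, DEG fraction %.2f, Fisher p = %.3g\n",
              f["selected"], x$report$summary$deg_fraction,
              x$report$summary$fisher_p_deg))
  invisible(x)
}

#' @describeIn overlapnet Per-trait selection summary.
#' @export
summary.overlapnet <- function(object, ...) {
  print(object)
  for (tr in names(object$selection$modules_by_trait)) {
    mods <- object$selection$modules_by_trait[[tr]]
    genes <- unique(object$selection$attribution$gene_id[
      object$selection$attribution$trait == tr])
    cat(sprintf("  %s: lambda = %.4g, %d module(s) [%s], %d gene(s)\n",
                tr,
                if (length(object$fits)) object$fits[[tr]]$lambda else NA,
                length(mods), paste(mods, collapse = ", "), length(genes)))
  }
  invisible(object$report$table)
}

#' @describeIn overlapnet Matrix of standardized LASSO coefficients
#'   (modules x traits).
#' @export
coef.overlapnet <- function(object, ...) {
  if (!length(object$fits))
    return(matrix(numeric(0), 0, 0))
  vapply(object$fits, `[[`, numeric(ncol(object$eigengenes)), "coefficients")
}

#' @describeIn overlapnet Diagnostic panels: scale-free fit scan, cutoff
#'   density scan, per-trait cross-validation curves.
#' @export
plot.overlapnet <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  scan <- x$beta_selection$scan
  graphics::plot(scan$beta, scan$r_squared, type = "b", xlab = "beta",
                 ylab = expression(R^2), main = "Scale-free topology fit")
  graphics::abline(h = x$config$network$r2_min, lty = 2)
  graphics::plot(x$cutoff_scan$threshold, x$cutoff_scan$density, type = "b",
                 xlab = "cutoff", ylab = "network density",
                 main = "Cutoff scan")
  graphics::abline(v = x$cutoff, lty = 2)
  if (length(x$fits)) {
    first <- TRUE
    cols <- grDevices::hcl.colors(length(x$fits), "Dark 3")
    for (i in seq_along(x$fits)) {
      cv <- x$fits[[i]]$cv
      if (first) {
        graphics::plot(log10(cv$lambda_grid), cv$cv_mean, type = "l",
                       col = cols[i], xlab = "log10(lambda)",
                       ylab = "CV MSE", main = "LASSO cross-validation")
        first <- FALSE
      } else {
        graphics::lines(log10(cv$lambda_grid), cv$cv_mean, col = cols[i])
      }
      graphics::abline(v = log10(cv$lambda), col = cols[i], lty = 2)
    }
    graphics::legend("topleft", legend = names(x$fits), col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
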