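#' Module eigengene
#'
#' Summarizes a module as the first principal component of its member
#' genes' LFC profiles. Each gene row is z-scored across genotypes before
#' the singular value decomposition; the returned vector is the first right
#' singular vector (unit Euclidean norm), sign-fixed so that its inner
#' product with the mean standardized row is non-negative. If the mean row
#' is numerically zero, the sign is fixed against the first gene's
#' standardized row instead.
#'
#' @param l1 Genes x genotypes LFC matrix.
#' @param gene_set Character vector of gene ids (subset of `rownames(l1)`).
#' @return Named numeric vector over genotypes, unit norm.
#' @export
eigengene <- function(l1, gene_set) {
  stopifnot(length(gene_set) >= 1)
  miss <- setdiff(gene_set, rownames(l1))
  if (length(miss))
    stop("gene(s) absent from the LFC matrix: ",
         paste(utils::head(miss), collapse = ", "))
  sub <- l1[gene_set, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance LFC row(s) cannot be z-scored: ",
         paste(utils::head(gene_set[sds == 0]), collapse = ", "))
  z <- (sub - rowMeans(sub)) / sds
  sv <- svd(z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  ref <- colMeans(z)
  if (sqrt(sum(ref^2)) < 1e-8 * sqrt(ncol(z))) ref <- z[1, ]
  if (sum(v * ref) < 0) v <- -v
  stats::setNames(v, colnames(l1))
}

#' Eigengene matrix for all modules
#'
#' One eigengene column per module of the affiliation matrix, module order
#' preserved. Genes belonging to several modules contribute to each of
#' their modules' eigengenes.
#'
#' @param l1 Genes x genotypes LFC matrix.
#' @param f Affiliation matrix from [affiliation()]; every module must have
#'   at least one gene present in `l1`.
#' @return Genotypes x modules numeric matrix.
#' @export
eigengene_matrix <- function(l1, f) {
  stopifnot(ncol(f) >= 1)
  mods <- module_gene_sets(f)
  eg <- vapply(names(mods), function(u) {
    genes <- intersect(mods[[u]], rownames(l1))
    if (!length(genes))
      stop("module ", u, " has no gene present in the LFC matrix")
    eigengene(l1, genes)
  }, numeric(ncol(l1)))
  rownames(eg) <- colnames(l1)
  eg
}

standardize_design <- function(x, y) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(x = xs, y = y - mean(y), x_center = ctr, x_scale = scl,
       y_mean = mean(y))
}

#' Fit the LASSO at a fixed penalty
#'
#' Minimizes `sum_i (y_i - x_i' a)^2 + lambda * sum_j |a_j|` by cyclic
#' coordinate descent. With `standardize = TRUE` (the default) predictor
#' columns are centered and scaled to unit standard deviation and the
#' response is centered internally; coefficients are reported on that
#' standardized scale.
#'
#' @param x Numeric predictor matrix (samples x modules).
#' @param y Numeric response vector.
#' @param lambda Non-negative penalty (the objective's Lagrangian form).
#' @param standardize Standardize predictors / center response internally.
#' @param tol Convergence tolerance on the largest coefficient change per
#'   sweep.
#' @param max_iter Sweep cap.
#' @return A list of class `lasso_fit`: `coefficients` (named), `lambda`,
#'   `y_mean`, `x_center`, `x_scale`, `standardize`.
#' @export
fit_lasso <- function(x, y, lambda, standardize = TRUE, tol = 1e-11,
                      max_iter = 50000) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !is.finite(lambda) ||
        lambda < 0)
    stop("x, y and lambda must be finite (lambda >= 0)")
  if (standardize) {
    std <- standardize_design(x, y)
  } else {
    std <- list(x = x, y = y, x_center = rep(0, ncol(x)),
                x_scale = rep(1, ncol(x)), y_mean = 0)
  }
  cf <- lasso_cd_path(std$x, std$y, lambda, tol = tol, max_iter = max_iter)[, 1]
  names(cf) <- colnames(x)
  structure(list(coefficients = cf, lambda = lambda,
                 y_mean = std$y_mean, x_center = std$x_center,
                 x_scale = std$x_scale, standardize = standardize),
            class = "lasso_fit")
}

#' @export
coef.lasso_fit <- function(object, ...) object$coefficients

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("lasso_fit: lambda = %.4g, %d of %d nonzero coefficients\n",
              x$lambda, nz, length(x$coefficients)))
  invisible(x)
}

#' Karush-Kuhn-Tucker residual of a LASSO fit
#'
#' For the objective `RSS + lambda * L1`, stationarity requires
#' `|x_j'(y - x a)| <= lambda/2` for inactive coordinates and equality (with
#' matching sign) for active ones. Returns the largest violation across
#' coordinates, evaluated on the internally standardized design the fit
#' used.
#'
#' @param fit A `lasso_fit`.
#' @param x,y The data the fit was computed from.
#' @return Maximum KKT violation (numeric scalar; ~0 for an exact solution).
#' @export
lasso_kkt_residual <- function(fit, x, y) {
  x <- as.matrix(x)
  if (fit$standardize) {
    xs <- sweep(sweep(x, 2, fit$x_center), 2, fit$x_scale, "/")
    yc <- y - fit$y_mean
  } else {
    xs <- x
    yc <- y
  }
  a <- fit$coefficients
  grad <- drop(crossprod(xs, yc - xs %*% a))
  half <- fit$lambda / 2
  viol <- ifelse(a == 0, pmax(abs(grad) - half, 0),
                 abs(grad - sign(a) * half))
  max(viol)
}

#' Cross-validated penalty selection
#'
#' Builds a 100-point (by default) log-spaced penalty grid from
#' `lambda_max` (the smallest penalty with an all-zero solution,
#' `2 * max_j |x_j'y|` on the standardized design) down to
#' `lambda_min_ratio * lambda_max`, estimates the mean-squared prediction
#' error by k-fold cross-validation with a seeded fold assignment, and
#' selects the penalty: either the minimizer of the mean CV MSE
#' (`lambda_rule = "min"`) or the largest penalty whose mean CV MSE is
#' within one standard error of that minimum (`"1se"`, the default, which
#' guards against the spurious near-zero selections the flat region of the
#' CV curve otherwise admits).
#'
#' @param x Predictor matrix (samples x modules).
#' @param y Response vector.
#' @param k_folds Number of folds (default 10; must not exceed the sample
#'   count).
#' @param n_lambda Grid size (default 100).
#' @param lambda_min_ratio Smallest grid value relative to `lambda_max`.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `lasso_cv`: `lambda` (chosen), `lambda_min`,
#'   `lambda_1se`, `lambda_rule`, `lambda_grid`, `cv_mean`, `cv_se`,
#'   `folds`, `seed`.
#' @export
cv_select_lambda <- function(x, y, k_folds = 10, n_lambda = 100,
                             lambda_min_ratio = 1e-4,
                             lambda_rule = c("1se", "min"), seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < k_folds)
    stop("need at least as many samples (", m, ") as folds (", k_folds, ")")
  std <- standardize_design(x, y)
  lambda_max <- 2 * max(abs(crossprod(std$x, std$y)))
  if (lambda_max == 0) lambda_max <- 1e-8   # y constant: any penalty works
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = n_lambda))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  folds <- sample(rep_len(seq_len(k_folds), m))
  err <- matrix(NA_real_, k_folds, n_lambda)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    std_tr <- standardize_design(x[tr, , drop = FALSE], y[tr])
    # warm-started path fits; convergence is relative to the response scale
    path <- lasso_cd_path(std_tr$x, std_tr$y, grid,
                          tol = 1e-7 * max(abs(std_tr$y), 1), max_iter = 5000)
    xval <- sweep(sweep(x[!tr, , drop = FALSE], 2, std_tr$x_center),
                  2, std_tr$x_scale, "/")
    pred <- xval %*% path + std_tr$y_mean
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_mean <- colMeans(err)
  cv_se <- apply(err, 2, stats::sd) / sqrt(k_folds)
  i_min <- which.min(cv_mean)
  lambda_min <- grid[i_min]
  # grid is decreasing, so the first index within one SE is the largest lambda
  lambda_1se <- grid[min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))]
  structure(list(lambda = if (lambda_rule == "min") lambda_min else lambda_1se,
                 lambda_min = lambda_min, lambda_1se = lambda_1se,
                 lambda_rule = lambda_rule, lambda_grid = grid,
                 cv_mean = cv_mean, cv_se = cv_se, folds = folds,
                 seed = seed),
            class = "lasso_cv")
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf("lasso_cv: lambda = %.4g chosen from %d grid points (min CV MSE %.4g)\n",
              x$lambda, length(x$lambda_grid), min(x$cv_mean)))
  invisible(x)
}

#' Per-trait LASSO association of module eigengenes
#'
#' For each phenotype trait, selects the penalty by cross-validation and
#' refits the LASSO on the full data at that penalty, with module
#' eigengenes as predictors and the trait's log fold change as response.
#'
#' @param eigengenes Genotypes x modules matrix from [eigengene_matrix()].
#' @param pheno_lfc Genotypes x traits matrix from [lfc_phenotypes()].
#' @param k_folds,n_lambda,lambda_min_ratio,lambda_rule Passed to
#'   [cv_select_lambda()].
#' @param seed Base seed; trait z uses `seed + z` for its fold assignment.
#' @return Named list (one per trait) of lists with `trait`, `lambda`, `cv`
#'   (the `lasso_cv`), `fit` (the `lasso_fit`), `coefficients`.
#' @export
associate_traits <- function(eigengenes, pheno_lfc, k_folds = 10,
                             n_lambda = 100, lambda_min_ratio = 1e-4,
                             lambda_rule = "1se", seed = 1) {
  stopifnot(nrow(eigengenes) == nrow(pheno_lfc))
  traits <- colnames(pheno_lfc)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(pheno_lfc)))
  out <- lapply(seq_along(traits), function(z) {
    y <- pheno_lfc[, z]
    cv <- cv_select_lambda(eigengenes, y, k_folds = k_folds,
                           n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio,
                           lambda_rule = lambda_rule, seed = seed + z)
    fit <- fit_lasso(eigengenes, y, cv$lambda)
    list(trait = traits[z], lambda = cv$lambda, cv = cv, fit = fit,
         coefficients = fit$coefficients)
  })
  stats::setNames(out, traits)
}

#' Select trait-associated modules and their gene union
#'
#' Modules with a nonzero LASSO coefficient form the selected set of each
#' trait; the target genes are the union of the member genes of all
#' selected modules, with per-gene trait attribution.
#'
#' @param fits Per-trait fits from [associate_traits()].
#' @param f Affiliation matrix the eigengenes were computed from.
#' @return A list of class `module_selection`: `modules_by_trait` (named
#'   list of module-id vectors), `genes` (the union, `I`), `attribution`
#'   (data frame gene_id / trait / module).
#' @export
select_modules <- function(fits, f) {
  mods <- module_gene_sets(f)
  by_trait <- lapply(fits, function(ft)
    names(ft$coefficients)[ft$coefficients != 0])
  rows <- list()
  for (trait in names(by_trait)) {
    for (u in by_trait[[trait]]) {
      if (!u %in% names(mods))
        stop("selected module ", u, " absent from the affiliation matrix")
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = mods[[u]], trait = trait, module = u,
        stringsAsFactors = FALSE)
    }
  }
  attribution <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), trait = character(0),
               module = character(0))
  structure(list(modules_by_trait = by_trait,
                 genes = unique(attribution$gene_id),
                 attribution = attribution),
            class = "module_selection")
}

#' @export
print.module_selection <- function(x, ...) {
  cat(sprintf("module_selection: %d genes in %d selected modules across %d traits\n",
              length(x$genes),
              length(unique(unlist(x$modules_by_trait))),
              sum(lengths(x$modules_by_trait) > 0)))
  invisible(x)
}
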