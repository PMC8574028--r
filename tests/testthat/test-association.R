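test_that("eigengene handles rank-1 and antisymmetric modules", {
  m <- 6
  profile <- c(2, -1, 0.5, 1.5, -2, 0)
  l1 <- rbind(g1 = profile, g2 = profile, g3 = profile)
  colnames(l1) <- paste0("geno", 1:m)
  eg <- eigengene(l1, c("g1", "g2", "g3"))
  expect_equal(sum(eg^2), 1)
  z <- (profile - mean(profile)) / sd(profile)
  expect_equal(unname(eg), z / sqrt(sum(z^2)), tolerance = 1e-10)

  # x and -x: mean standardized row is zero; sign falls back to first gene
  l2 <- rbind(a = profile, b = -profile)
  colnames(l2) <- paste0("geno", 1:m)
  eg2 <- eigengene(l2, c("a", "b"))
  za <- (profile - mean(profile)) / sd(profile)
  expect_gte(sum(eg2 * za), 0)
  expect_equal(abs(unname(eg2)), abs(za / sqrt(sum(za^2))), tolerance = 1e-10)

  # order invariance
  expect_equal(eigengene(l1, c("g3", "g1", "g2")), eg)

  expect_error(eigengene(rbind(g1 = rep(1, m)), "g1"), "zero-variance")
})

test_that("eigengene matrix has one unit-norm column per module", {
  set.seed(3)
  l1 <- matrix(rnorm(12 * 8), 12,
               dimnames = list(paste0("g", 1:12), paste0("geno", 1:8)))
  f <- matrix(0L, 12, 3, dimnames = list(rownames(l1), c("M1", "M2", "M3")))
  f[1:4, 1] <- 1L
  f[3:8, 2] <- 1L    # genes 3,4 in two modules
  f[9:12, 3] <- 1L
  eg <- eigengene_matrix(l1, f)
  expect_equal(dim(eg), c(8, 3))
  expect_equal(unname(colSums(eg^2)), rep(1, 3))
  expect_equal(eg[, "M1"], eigengene(l1, paste0("g", 1:4)))

  f_bad <- matrix(1L, 2, 1, dimnames = list(c("zz1", "zz2"), "M1"))
  expect_error(eigengene_matrix(l1, f_bad), "absent|no gene")
})

test_that("LASSO matches closed forms on orthonormal designs", {
  set.seed(11)
  m <- 24; c <- 6
  q <- qr.Q(qr(matrix(rnorm(m * c), m)))   # orthonormal columns
  beta_true <- c(3, -2, 0, 1.5, 0, 0.5)
  y <- drop(q %*% beta_true)
  bhat <- drop(crossprod(q, y))

  # lambda = 0 -> OLS
  f0 <- fit_lasso(q, y, 0, standardize = FALSE)
  expect_equal(unname(coef(f0)), bhat, tolerance = 1e-8)

  # lambda > 0 -> soft thresholding at lambda/2
  for (lam in c(0.5, 1, 2.5)) {
    fl <- fit_lasso(q, y, lam, standardize = FALSE)
    expected <- sign(bhat) * pmax(abs(bhat) - lam / 2, 0)
    expect_equal(unname(coef(fl)), expected, tolerance = 1e-8)
  }

  # all coefficients vanish once lambda reaches 2 * max |x_j'y|
  lam_max <- 2 * max(abs(bhat))
  expect_true(all(coef(fit_lasso(q, y, lam_max, standardize = FALSE)) == 0))
  expect_true(any(coef(fit_lasso(q, y, 0.9 * lam_max,
                                 standardize = FALSE)) != 0))
})

test_that("KKT conditions hold on random problems", {
  set.seed(21)
  for (i in 1:40) {
    m <- sample(15:40, 1)
    c <- sample(3:12, 1)
    x <- matrix(rnorm(m * c), m)
    y <- rnorm(m)
    lam <- runif(1, 0.01, 2) * max(abs(crossprod(scale(x), y - mean(y))))
    fit <- fit_lasso(x, y, lam)
    expect_lt(lasso_kkt_residual(fit, x, y), 1e-6)
  }
})

test_that("LASSO solutions agree with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  m <- 30; c <- 8
  x <- matrix(rnorm(m * c), m)
  y <- drop(x[, 1] - 2 * x[, 4] + rnorm(m, sd = 0.3))
  xs <- scale(x)
  yc <- y - mean(y)
  for (lam in c(2, 8, 20)) {
    ours <- fit_lasso(x, y, lam)
    # glmnet minimizes 1/(2m) RSS + lambda_g L1  ->  lambda_g = lam / (2m)
    ref <- glmnet::glmnet(xs, yc, lambda = lam / (2 * m), standardize = FALSE,
                          intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(coef(ours)), as.numeric(ref$beta), tolerance = 1e-5)
  }
})

test_that("active sets shrink monotonically along the penalty path", {
  set.seed(14)
  x <- matrix(rnorm(30 * 10), 30)
  y <- rnorm(30)
  std <- overlapnet:::standardize_design(x, y)
  lam_max <- 2 * max(abs(crossprod(std$x, std$y)))
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = 40))
  path <- overlapnet:::lasso_cd_path(std$x, std$y, grid)
  active <- colSums(path != 0)
  expect_equal(active[1], 0)              # all zero at lambda_max
  expect_true(all(diff(active) >= 0))     # grows as lambda decreases
})

test_that("cross-validation selects sensible penalties and is deterministic", {
  set.seed(2)
  m <- 40
  x <- matrix(rnorm(m * 12), m, dimnames = list(NULL, paste0("M", 1:12)))

  # pure noise response: majority of repeats pick a large penalty
  big_lambda <- replicate(10, {
    y <- rnorm(m)
    cv <- cv_select_lambda(x, y, seed = sample.int(1e6, 1))
    fit <- fit_lasso(x, y, cv$lambda)
    sum(coef(fit) != 0)
  })
  expect_gte(mean(big_lambda <= 2), 0.6)

  # noiseless 2-column signal: both true columns active at lambda_min
  y2 <- drop(2 * x[, 3] - 1.5 * x[, 7])
  cv2 <- cv_select_lambda(x, y2, seed = 4)
  fit2 <- fit_lasso(x, y2, cv2$lambda)
  expect_true(all(c("M3", "M7") %in% names(which(coef(fit2) != 0))))

  # determinism for identical seed
  cv_a <- cv_select_lambda(x, y2, seed = 123)
  cv_b <- cv_select_lambda(x, y2, seed = 123)
  expect_identical(cv_a$lambda, cv_b$lambda)
  expect_identical(cv_a$cv_mean, cv_b$cv_mean)

  expect_error(cv_select_lambda(x[1:5, ], y2[1:5], k_folds = 10), "folds")
})

test_that("module selection collects nonzero modules and their gene union", {
  f <- matrix(0L, 6, 3, dimnames = list(paste0("g", 1:6),
                                        paste0("M", 1:3)))
  f[1:3, 1] <- 1L; f[3:5, 2] <- 1L; f[5:6, 3] <- 1L
  fits <- list(
    t1 = list(coefficients = c(M1 = 0.5, M2 = 0, M3 = 0)),
    t2 = list(coefficients = c(M1 = 0.2, M2 = 0, M3 = -0.1)))
  sel <- select_modules(fits, f)
  expect_setequal(sel$modules_by_trait$t1, "M1")
  expect_setequal(sel$modules_by_trait$t2, c("M1", "M3"))
  expect_setequal(sel$genes, c("g1", "g2", "g3", "g5", "g6"))
  both <- sel$attribution[sel$attribution$module == "M1", ]
  expect_setequal(both$trait, c("t1", "t2"))

  none <- list(t1 = list(coefficients = c(M1 = 0, M2 = 0, M3 = 0)))
  expect_length(select_modules(none, f)$genes, 0)
})

test_that("LASSO recovers planted causal modules from true affiliations", {
  # association-stage parameter recovery: eigengenes computed from the
  # *true* module memberships, so only the selection step is under test.
  # Modules are planted disjoint: with overlapping memberships, non-causal
  # eigengenes genuinely carry causal signal through shared genes and the
  # selection problem is not identifiable.
  hits <- vapply(1:25, function(seed) {
    sim <- simulate_study(synthetic_config(n_genes = 400, m_genotypes = 40,
                                           module_size_range = c(8, 12),
                                           overlap_prob = 0,
                                           seed = 1000 + seed))
    truth <- sim$truth
    lfc <- truth$lfc
    f_true <- truth$membership[rowSums(truth$membership) > 0, , drop = FALSE]
    eg <- eigengene_matrix(lfc, f_true)
    plfc <- lfc_phenotypes(sim$phenotypes)
    fits <- associate_traits(eg, plfc, seed = seed)
    sel <- select_modules(fits, f_true)
    mean(vapply(names(truth$causal_modules), function(tr) {
      causal <- colnames(truth$membership)[truth$causal_modules[[tr]]]
      got <- sel$modules_by_trait[[tr]]
      length(intersect(got, causal)) / length(union(got, causal))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(hits >= 0.5), 0.8)
})
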