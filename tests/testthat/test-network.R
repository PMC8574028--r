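test_that("similarity is |Pearson correlation| with unit diagonal", {
  l1 <- rbind(a = c(1, 2, 3, 4),
              b = -2 * c(1, 2, 3, 4) + 3,          # perfect negative
              c = c(1, -1, 1, -1),
              d = c(1, 1, -1, -1))
  s <- similarity_matrix(l1)
  expect_equal(unname(diag(s)), rep(1, 4))
  expect_equal(s["a", "b"], 1)
  expect_equal(s["c", "d"], 0)
  expect_true(all(s >= 0 & s <= 1))

  flat <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  expect_error(similarity_matrix(flat), "zero-variance")
})

test_that("similarity and adjacency stay symmetric in [0,1] on random LFC", {
  for (seed in 1:25) {
    set.seed(seed)
    l1 <- matrix(rnorm(20 * 8), 20,
                 dimnames = list(paste0("g", 1:20), paste0("m", 1:8)))
    s <- similarity_matrix(l1)
    expect_identical(s, t(s))
    expect_true(all(s >= 0 & s <= 1))
    a <- soft_power(s, 3)
    expect_identical(a, t(a))
    expect_true(all(a >= 0 & a <= 1))
    # monotone non-increasing in beta
    expect_true(all(soft_power(s, 5) <= a + 1e-15))
  }
})

test_that("soft thresholding is an elementwise power", {
  s <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(soft_power(s, 1), s)
  expect_equal(soft_power(s, 3)[1, 2], 0.125)
  expect_equal(soft_power(s, 7)[1, 1], 1)
  expect_error(soft_power(s, 0))
})

test_that("scale-free fit is near 1 on a power law and low on uniform noise", {
  k <- 10^seq(0.1, 2, length.out = 15)
  connectivities <- rep(k, round(2e4 * k^-1.8))
  fit <- scale_free_r2(connectivities, n_bins = 15)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(fit$slope, 0)

  set.seed(8)
  n <- 150
  s <- matrix(runif(n * n, 0.4, 0.6), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  fit2 <- scale_free_r2(soft_power(s, 1))
  expect_lt(fit2$r_squared, 0.8)

  expect_error(scale_free_r2(rep(4, 50)), "degenerate")
})

test_that("beta selection returns the smallest qualifying power", {
  # synthetic scan: stub scale_free_r2 via constructed similarity is hard,
  # so test the rule on a similarity whose fit improves with beta
  k <- 10^seq(0.1, 1.6, length.out = 12)
  base <- rep(k, round(5e3 * k^-1.5))
  # direct rule checks through select_beta on a planted-module study
  sim <- simulate_study(synthetic_config(n_genes = 400, m_genotypes = 20,
                                         seed = 2))
  l1 <- filter_lfc(lfc_expression(filter_expression(
    normalize_and_average(sim$counts))))
  s <- similarity_matrix(l1)
  sel <- suppressWarnings(select_beta(s, beta_grid = 1:12))
  expect_true(sel$beta %in% 1:12)
  scan <- sel$scan
  qualifying <- scan$beta[scan$beta > 1 & !is.na(scan$r_squared) &
                            scan$r_squared >= 0.8]
  if (length(qualifying)) {
    expect_true(sel$reached_r2_min)
    expect_equal(sel$beta, min(qualifying))
  } else {
    expect_false(sel$reached_r2_min)
    expect_equal(sel$beta, scan$beta[which.max(scan$r_squared)])
  }
  # fallback rule: impossible threshold forces argmax with a warning
  expect_warning(sel2 <- select_beta(s, r2_min = 1.1, beta_grid = 2:6),
                 "best-fitting")
  expect_false(sel2$reached_r2_min)
  expect_equal(sel2$beta,
               sel2$scan$beta[which.max(sel2$scan$r_squared)])
})

test_that("threshold scan counts match direct enumeration", {
  a <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  a[1, 2] <- a[2, 1] <- 0.9
  a[3, 4] <- a[4, 3] <- 0.9
  a[1, 3] <- a[3, 1] <- 0.1
  diag(a) <- 1
  scan <- threshold_scan(a, grid = c(0.05, 0.5, 0.95))
  expect_equal(scan$edges, c(3, 2, 0))
  expect_equal(scan$nodes, c(4, 4, 0))
  expect_equal(scan$density, c(3 / 6, 2 / 6, 0))

  # tau = 0-ish on a complete weighted matrix -> density 1
  full <- matrix(0.8, 3, 3); diag(full) <- 1
  sc <- threshold_scan(full, grid = 0.5)
  expect_equal(sc$density, 1)
})

test_that("cutoff selection honors override, minimum rule and ties", {
  a <- matrix(0.5, 6, 6); diag(a) <- 1
  scan <- threshold_scan(a, grid = seq(0.1, 0.9, by = 0.1))
  expect_equal(select_cutoff(scan, override = 0.2), 0.2)

  # constructed scan with interior density minimum at 0.3
  fake <- data.frame(threshold = c(0.1, 0.2, 0.3, 0.4),
                     nodes = c(100, 80, 60, 40),
                     edges = c(2000, 900, 200, 150),
                     density = c(0.40, 0.28, 0.11, 0.19))
  attr(fake, "n_genes") <- 100
  class(fake) <- c("cutoff_scan", "data.frame")
  expect_equal(select_cutoff(fake), 0.3)
  fake$density[4] <- fake$density[3]      # tie -> smallest tau
  expect_equal(select_cutoff(fake), 0.3)
  fake$nodes <- c(100, 3, 2, 1)           # retention floor excludes the rest
  expect_equal(select_cutoff(fake), 0.1)
})

test_that("binarization is strict and drops isolated nodes", {
  a <- matrix(c(1, 0.5, 0.1,
                0.5, 1, 0.05,
                0.1, 0.05, 1), 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  # entry exactly 0.5 is excluded (strict >), so no edge survives
  expect_error(binarize(a, 0.5), "empty")
  net <- binarize(a, 0.45)
  expect_setequal(net$genes, c("g1", "g2"))
})

test_that("binarize keeps strictly-above edges and matches the scan", {
  set.seed(77)
  n <- 30
  s <- abs(cor(matrix(rnorm(8 * n), 8)))
  dimnames(s) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a <- soft_power(s, 2)
  for (tau in c(0.2, 0.4, 0.6)) {
    scan <- threshold_scan(a, grid = tau)
    net <- tryCatch(binarize(a, tau), error = function(e) NULL)
    if (is.null(net)) {
      expect_equal(scan$nodes, 0)
    } else {
      expect_equal(length(net$genes), scan$nodes)
      expect_equal(sum(net$adjacency[upper.tri(net$adjacency)]), scan$edges)
      expect_false(any(diag(net$adjacency)))
      expect_true(all(rowSums(net$adjacency) > 0))
    }
  }
  # boundary: entries exactly at tau are not edges
  b <- matrix(c(1, 0.3, 0.3, 1), 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(binarize(b, 0.3), "empty")
  nb <- binarize(b, 0.29)
  expect_equal(length(nb$genes), 2)
})

test_that("gene permutation commutes with the network pipeline", {
  set.seed(12)
  l1 <- matrix(rnorm(25 * 10), 25,
               dimnames = list(paste0("g", 1:25), paste0("m", 1:10)))
  s <- similarity_matrix(l1)
  a <- soft_power(s, 3)
  perm <- sample(25)
  s2 <- similarity_matrix(l1[perm, ])
  expect_equal(s2, s[perm, perm])
  expect_equal(soft_power(s2, 3), a[perm, perm])
  expect_equal(scale_free_r2(soft_power(s2, 3))$r_squared,
               scale_free_r2(a)$r_squared)
})
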