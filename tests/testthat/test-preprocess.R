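make_cm <- function(values, m = 1, r = 2) {
  sheet <- toy_sheet(m = m, r = r)
  colnames(values) <- sheet$sample
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  count_matrix(values, sheet)
}

test_that("median-of-ratios size factors match hand evaluations", {
  # column 2 = 2 x column 1 -> factors (1/sqrt(2), sqrt(2))
  v <- cbind(c(10, 20, 30), c(20, 40, 60))
  sheet <- data.frame(sample = c("s1", "s2"), genotype = "g1",
                      condition = c("control", "treatment"), replicate = 1)
  rownames(v) <- paste0("gene", 1:3)
  colnames(v) <- sheet$sample
  cm <- count_matrix(v, sheet)
  expect_equal(unname(size_factors(cm)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # identical columns -> all factors 1
  v2 <- matrix(rep(c(5, 8, 13, 21), 4), ncol = 4)
  expect_equal(unname(size_factors(make_cm(v2))), rep(1, 4))

  # single-sample matrix -> factor 1 (via the bare-matrix interface)
  single <- matrix(c(3, 7, 11), ncol = 1,
                   dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(size_factors(single)), 1)

  # no gene expressed everywhere -> error
  v3 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), NULL))
  expect_error(size_factors(v3), "pseudocount")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  counts <- matrix(rnbinom(200 * 8, mu = 120, size = 8), 200,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  ours <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("normalization is equivariant to per-sample scaling", {
  set.seed(5)
  base <- matrix(rpois(300 * 8, 80), 300)
  cm <- make_cm(base, m = 2, r = 2)
  sf1 <- size_factors(cm)
  norm1 <- normalize_and_average(cm, sf1)

  gamma <- 3
  scaled <- base
  scaled[, 2] <- base[, 2] * gamma
  cm2 <- make_cm(scaled, m = 2, r = 2)
  sf2 <- size_factors(cm2)
  # scaling one library by gamma rescales the pseudo-reference by
  # gamma^(1/S), so equivariance holds for factor *ratios* and for the
  # normalized matrix up to one global constant
  expect_equal(unname((sf2[2] / sf2[1]) / (sf1[2] / sf1[1])), gamma,
               tolerance = 1e-12)
  norm2 <- normalize_and_average(cm2, sf2)
  scale_drift <- norm2$d1 / norm1$d1
  expect_equal(max(scale_drift) / min(scale_drift), 1, tolerance = 1e-12)
  expect_equal(unname(scale_drift[1, 1]), gamma^(1 / 8), tolerance = 1e-12)
})

test_that("estimated size factors recover planted truth within 5%", {
  sim <- simulate_study(synthetic_config(n_genes = 500, m_genotypes = 10,
                                         seed = 23))
  est <- size_factors(sim$counts)
  truth <- sim$truth$size_factors[names(est)]
  expect_lte(median(abs(est - truth) / truth), 0.05)
})

test_that("replicate averaging and column ordering follow the design", {
  v <- rbind(c(2, 4, 1, 3, 10, 20, 5, 7))
  rownames(v) <- "geneA"
  cm <- make_cm(v, m = 2, r = 2)
  norm <- normalize_and_average(cm, stats::setNames(rep(1, 8), cm$samples$sample))
  # control g1, control g2, treatment g1, treatment g2
  expect_identical(colnames(norm$d2),
                   c("g1.control", "g2.control", "g1.treatment", "g2.treatment"))
  expect_equal(unname(norm$d2[1, ]), c(3, 2, 15, 6))

  # r = 1: averaging is the identity
  v1 <- matrix(c(2, 6, 4, 8), 1)   # samples: g1.c, g2.c, g1.t, g2.t
  cm1 <- make_cm(v1, m = 2, r = 1)
  norm1 <- normalize_and_average(cm1, stats::setNames(rep(1, 4), cm1$samples$sample))
  expect_equal(unname(norm1$d2[1, ]), c(2, 6, 4, 8))
})

test_that("expression filter applies both removal rules", {
  # gene1: 9 of 10 columns below 10 -> removed (low expression)
  # gene2: constant -> Q75/Q25 = 1 -> removed (low variance)
  # gene3: Q25 = 10, Q75 = 20, all >= 10 -> kept
  d2 <- rbind(gene1 = c(rep(5, 9), 50),
              gene2 = rep(100, 10),
              gene3 = c(10, 10, 10, 12, 14, 16, 18, 20, 20, 20))
  kept <- filter_expression(d2)
  expect_identical(rownames(kept), "gene3")

  # Q25 = 0 with Q75 > 0 counts as infinite ratio (kept by variance rule)
  d3 <- rbind(geneZ = c(0, 0, 0, 40, 40, 40, 40, 40, 40, 40),
              gene3 = c(10, 10, 10, 12, 14, 16, 18, 20, 20, 20))
  expect_identical(rownames(filter_expression(d3)), c("geneZ", "gene3"))

  expect_error(filter_expression(rbind(g = rep(1, 10))), "every gene")
})

test_that("filters are idempotent and the funnel is monotone", {
  sim <- simulate_study(synthetic_config(n_genes = 300, m_genotypes = 10,
                                         seed = 4))
  norm <- normalize_and_average(sim$counts)
  f1 <- filter_expression(norm)
  f2 <- filter_expression(f1)
  expect_identical(f1$d2, f2$d2)
  expect_lte(nrow(f1$d2), nrow(norm$d2))

  l0 <- lfc_expression(f1)
  l1 <- filter_lfc(l0)
  expect_identical(filter_lfc(l1), l1)
  expect_lte(nrow(l1), nrow(l0))
})

test_that("expression log fold changes follow log2((t+p)/(c+p))", {
  d2 <- matrix(c(2, 8,    # c = 2, t = 8, pc = 0 -> 2
                 5, 5,    # t = c -> 0
                 0, 3),   # c = 0, t = 3, pc = 1 -> 2
               nrow = 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3),
                               c("g1.control", "g1.treatment")))
  expect_equal(unname(lfc_expression(d2[1:2, , drop = FALSE], pseudocount = 0)[, 1]),
               c(2, 0))
  expect_equal(unname(lfc_expression(d2[3, , drop = FALSE], pseudocount = 1)[, 1]),
               2)
})

test_that("LFC filter direction is controlled by mode", {
  l0 <- rbind(flat = rep(0.5, 8),
              spread = c(-0.4, -0.3, -0.2, -0.05, 0.05, 0.2, 0.3, 0.4))
  # spread row has IQR 0.5
  kept_low <- filter_lfc(l0, iqr_threshold = 0.25, mode = "remove_low_variance")
  expect_identical(rownames(kept_low), "spread")
  kept_high <- filter_lfc(l0, iqr_threshold = 0.25, mode = "remove_high_variance")
  expect_identical(rownames(kept_high), "flat")
  expect_error(filter_lfc(l0["flat", , drop = FALSE], 0.25,
                          "remove_low_variance"),
               "every gene")
})

test_that("phenotype log ratios validate positivity", {
  ctrl <- matrix(c(10, 4), 2, dimnames = list(c("g1", "g2"), "trait1"))
  trt <- matrix(c(5, 4), 2, dimnames = list(c("g1", "g2"), "trait1"))
  pt <- phenotype_table(ctrl, trt)
  pl <- lfc_phenotypes(pt)
  expect_equal(unname(pl[, 1]), c(-1, 0))

  bad <- phenotype_table(matrix(c(0, 4), 2, dimnames = list(c("g1", "g2"), "t")),
                         matrix(c(5, 4), 2, dimnames = list(c("g1", "g2"), "t")))
  expect_error(lfc_phenotypes(bad), "g1")
})
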