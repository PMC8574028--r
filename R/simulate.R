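#' Synthetic study configuration
#'
#' Parameters of the synthetic paired control/treatment RNA-seq study the
#' generator emulates: planted overlapping co-expression modules acting on
#' the log-fold-change scale, negative-binomial counts with per-sample scale
#' factors, and phenotype traits driven by a few causal modules. Defaults
#' describe a reduced-scale study (1,000 genes, 40 genotypes, 2 replicates,
#' 3 traits, 8 modules of 8-15 genes) with a module signal-to-noise ratio of
#' about 3.
#'
#' @param n_genes Total genes.
#' @param m_genotypes Genotypes (each with control and treatment samples).
#' @param r_replicates Biological replicates per genotype x condition.
#' @param n_traits Phenotype traits.
#' @param n_modules Planted modules.
#' @param module_size_range Min/max genes per module.
#' @param overlap_prob Probability that a module gene also joins one other
#'   module.
#' @param module_effect_sd Typical magnitude of a gene's loading on its
#'   module activity; per-gene loadings vary uniformly over
#'   `loading_range` times this value, as genes follow their module's
#'   program with varying strength.
#' @param loading_range Relative spread of per-gene module loadings
#'   (default `c(0.5, 1.5)`).
#' @param gene_noise_sd Per-gene LFC noise standard deviation.
#' @param background_group_size Range of sizes of the background
#'   co-response groups: non-module genes are organized into many small
#'   groups sharing a weak-to-moderate response program, emulating the
#'   fine-grained modular structure of real co-expression networks (the
#'   continuum of connectivities that makes soft-threshold selection
#'   meaningful).
#' @param background_coherence Median loading of background genes on their
#'   group's program, relative to the unit activity scale; per-group
#'   loadings are log-normal around it.
#' @param background_coherence_sdlog Log-scale spread of the per-group
#'   loading.
#' @param baseline_genotype_sd Per-genotype variation of a gene's baseline
#'   expression, in log2 units. Genotypes differ genetically in baseline
#'   expression; this variation spreads the expression filter's quantiles
#'   but cancels exactly in the treatment/control log ratio.
#' @param nb_dispersion Negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); 0 means deterministic counts (the rounded
#'   expected count).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of
#'   per-gene baseline (control) expression means.
#' @param scale_factor_range Range of per-sample scale factors, drawn
#'   log-uniformly and normalized to geometric mean 1.
#' @param causal_modules_per_trait Number of modules driving each trait.
#' @param trait_effect_range Magnitude range of a causal module's effect on
#'   its trait (random sign); the lower bound keeps the trait
#'   signal-to-noise ratio above 3 at the default `trait_noise_sd`.
#' @param trait_noise_sd Noise on the trait's log2 treatment/control ratio.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000, m_genotypes = 40,
                             r_replicates = 2, n_traits = 3, n_modules = 8,
                             module_size_range = c(8, 15),
                             overlap_prob = 0.3, module_effect_sd = 1,
                             loading_range = c(0.8, 1.2),
                             gene_noise_sd = 0.1,
                             background_group_size = c(2, 10),
                             background_coherence = 0.3,
                             background_coherence_sdlog = 0.45,
                             nb_dispersion = 0.005,
                             baseline_log_mean = 5.5, baseline_log_sd = 1,
                             baseline_genotype_sd = 0.35,
                             scale_factor_range = c(0.5, 2),
                             causal_modules_per_trait = 2,
                             trait_effect_range = c(1, 1.5),
                             trait_noise_sd = 0.3, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, m_genotypes >= 2, r_replicates >= 1,
            n_traits >= 1, n_modules >= 1,
            overlap_prob >= 0, overlap_prob <= 1,
            module_effect_sd > 0, gene_noise_sd >= 0,
            all(loading_range > 0), all(background_group_size >= 1),
            background_coherence >= 0, background_coherence_sdlog >= 0,
            baseline_genotype_sd >= 0, nb_dispersion >= 0,
            all(scale_factor_range > 0),
            causal_modules_per_trait >= 1,
            causal_modules_per_trait <= n_modules,
            all(trait_effect_range > 0), trait_noise_sd >= 0)
  if (n_modules * max(module_size_range) > n_genes)
    stop("planted module sizes exceed the number of genes")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic paired control/treatment study
#'
#' Draws per-module activity profiles over genotypes from a standard
#' normal; assigns genes to modules (each module gene joining a second
#' module with probability `overlap_prob`); builds each module gene's true
#' LFC row as the sum of its module loadings times the module activities
#' plus gene-level noise (background genes are pure noise); converts LFC to
#' treatment means over log-normal baselines; draws negative-binomial read
#' counts per replicate under per-sample scale factors; and emits traits as
#' control/treatment phenotype pairs whose log2 ratio is a noisy sum of the
#' activities of a few causal modules.
#'
#' @param config A [synthetic_config()].
#' @return A list: `counts` (a `count_matrix`), `phenotypes`
#'   (a `phenotype_table`), `truth` (a `ground_truth` list with `membership`
#'   gene x module 0/1 matrix, `causal_modules` per trait, `size_factors`
#'   normalized to geometric mean 1, `lfc` the true genes x genotypes
#'   matrix, `activities`).
#' @export
simulate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(cf$seed)
  genes <- sprintf("gene%04d", seq_len(cf$n_genes))
  genotypes <- sprintf("geno%02d", seq_len(cf$m_genotypes))

  # module activities over genotypes
  act <- matrix(stats::rnorm(cf$n_modules * cf$m_genotypes), cf$n_modules,
                dimnames = list(paste0("mod", seq_len(cf$n_modules)), genotypes))

  # disjoint primary membership blocks, then optional second memberships
  sizes <- sample(seq(cf$module_size_range[1], cf$module_size_range[2]),
                  cf$n_modules, replace = TRUE)
  membership <- matrix(0L, cf$n_genes, cf$n_modules,
                       dimnames = list(genes, rownames(act)))
  nxt <- 1
  for (u in seq_len(cf$n_modules)) {
    membership[nxt:(nxt + sizes[u] - 1), u] <- 1L
    nxt <- nxt + sizes[u]
  }
  if (cf$n_modules > 1 && cf$overlap_prob > 0) {
    module_genes <- which(rowSums(membership) > 0)
    joins <- stats::runif(length(module_genes)) < cf$overlap_prob
    for (i in module_genes[joins]) {
      home <- which(membership[i, ] == 1)[1]
      other <- sample(setdiff(seq_len(cf$n_modules), home), 1)
      membership[i, other] <- 1L
    }
  }

  # loadings and true LFC
  loading <- membership * cf$module_effect_sd *
    matrix(sample(c(-1, 1), length(membership), replace = TRUE) *
             stats::runif(length(membership), cf$loading_range[1],
                          cf$loading_range[2]),
           nrow(membership))
  lfc <- loading %*% act +
    matrix(stats::rnorm(cf$n_genes * cf$m_genotypes, sd = cf$gene_noise_sd),
           cf$n_genes, dimnames = list(genes, genotypes))
  bg <- which(rowSums(membership) == 0)
  if (cf$background_coherence > 0 && length(bg)) {
    i <- 1
    while (i <= length(bg)) {
      gs <- min(sample(seq(cf$background_group_size[1],
                           cf$background_group_size[2]), 1),
                length(bg) - i + 1)
      idx <- bg[i:(i + gs - 1)]
      w <- stats::rlnorm(1, log(cf$background_coherence),
                         cf$background_coherence_sdlog)
      lfc[idx, ] <- lfc[idx, ] +
        (w * sample(c(-1, 1), gs, replace = TRUE) *
           stats::runif(gs, 0.7, 1.3)) %o% stats::rnorm(cf$m_genotypes)
      i <- i + gs
    }
  }

  # baselines (gene level, with per-genotype genetic variation), sheet, scale factors
  baseline <- stats::rlnorm(cf$n_genes, cf$baseline_log_mean, cf$baseline_log_sd) *
    2^matrix(stats::rnorm(cf$n_genes * cf$m_genotypes, 0, cf$baseline_genotype_sd),
             cf$n_genes, dimnames = list(genes, genotypes))
  sheet <- expand.grid(replicate = seq_len(cf$r_replicates),
                       genotype = genotypes,
                       condition = c("control", "treatment"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$sample <- sprintf("s%03d", seq_len(nrow(sheet)))
  sheet <- sheet[, c("sample", "genotype", "condition", "replicate")]
  sf <- exp(stats::runif(nrow(sheet), log(cf$scale_factor_range[1]),
                         log(cf$scale_factor_range[2])))
  sf <- sf / exp(mean(log(sf)))          # geometric mean 1
  names(sf) <- sheet$sample

  mu <- vapply(seq_len(nrow(sheet)), function(s) {
    g <- sheet$genotype[s]
    base <- if (sheet$condition[s] == "treatment")
      baseline[, g] * 2^lfc[, g] else baseline[, g]
    base * sf[s]
  }, numeric(cf$n_genes))
  counts <- if (cf$nb_dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cf$nb_dispersion),
           nrow(mu))
  } else {
    round(mu)
  }
  dimnames(counts) <- list(genes, sheet$sample)

  # traits from causal modules
  traits <- sprintf("trait%d", seq_len(cf$n_traits))
  causal <- lapply(traits, function(tr)
    sort(sample(cf$n_modules, cf$causal_modules_per_trait)))
  names(causal) <- traits
  z <- vapply(traits, function(tr) {
    gam <- sample(c(-1, 1), cf$causal_modules_per_trait, replace = TRUE) *
      stats::runif(cf$causal_modules_per_trait, cf$trait_effect_range[1],
                   cf$trait_effect_range[2])
    drop(gam %*% act[causal[[tr]], , drop = FALSE]) +
      stats::rnorm(cf$m_genotypes, sd = cf$trait_noise_sd)
  }, numeric(cf$m_genotypes))
  ctrl <- matrix(stats::rlnorm(cf$m_genotypes * cf$n_traits, 3, 0.3),
                 cf$m_genotypes, dimnames = list(genotypes, traits))
  trt <- ctrl * 2^z

  list(counts = count_matrix(counts, sheet),
       phenotypes = phenotype_table(ctrl, trt),
       truth = structure(list(membership = membership,
                              causal_modules = causal,
                              size_factors = sf,
                              lfc = lfc,
                              activities = act,
                              config = cf),
                         class = "ground_truth"))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Score recovery of planted structure
#'
#' Compares detected modules and the trait selection against the generator's
#' ground truth: best-match Jaccard index between each planted module's gene
#' set and any detected module; per-trait Jaccard between the gene union of
#' the planted causal modules and the gene union of the selected modules;
#' and the fraction of truly multi-module genes detected with at least two
#' memberships.
#'
#' @param truth `ground_truth` from [simulate_study()].
#' @param f Detected affiliation matrix.
#' @param selection A `module_selection`, or `NULL` to skip trait scoring.
#' @return List: `module_jaccard` (per planted module), `mean_module_jaccard`,
#'   `causal_jaccard` (per trait), `overlap_detection_rate`.
#' @export
score_recovery <- function(truth, f, selection = NULL) {
  planted <- lapply(seq_len(ncol(truth$membership)), function(u)
    rownames(truth$membership)[truth$membership[, u] == 1])
  names(planted) <- colnames(truth$membership)
  detected <- module_gene_sets(f)
  module_jaccard <- vapply(planted, function(p) {
    if (!length(detected)) return(0)
    max(vapply(detected, jaccard, numeric(1), a = p))
  }, numeric(1))
  out <- list(module_jaccard = module_jaccard,
              mean_module_jaccard = mean(module_jaccard))
  if (!is.null(selection)) {
    out$causal_jaccard <- vapply(names(truth$causal_modules), function(tr) {
      true_genes <- unique(unlist(planted[truth$causal_modules[[tr]]]))
      sel_mods <- selection$modules_by_trait[[tr]]
      sel_genes <- unique(unlist(detected[sel_mods]))
      jaccard(true_genes, sel_genes)
    }, numeric(1))
  }
  multi <- rownames(truth$membership)[rowSums(truth$membership) >= 2]
  multi <- intersect(multi, rownames(f))
  out$overlap_detection_rate <- if (length(multi))
    mean(rowSums(f[multi, , drop = FALSE]) >= 2) else NA_real_
  out
}
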