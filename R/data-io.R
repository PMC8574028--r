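#' Read a count matrix and its sample sheet
#'
#' Loads raw RNA-seq read counts (genes x samples, tab-separated, first
#' column `gene_id`) together with a sample sheet (CSV with columns
#' `sample`, `genotype`, `condition`, `replicate`) describing the paired
#' control/treatment design. Columns of the returned matrix follow the
#' sample-sheet order, not the file order.
#'
#' The design must be complete: every genotype appears under both the
#' `control` and the `treatment` condition, with the same number of
#' biological replicates everywhere. Counts must be non-negative integers.
#'
#' @param counts_path Path to the TSV count file.
#' @param sheet_path Path to the sample-sheet CSV.
#' @return An object of class `count_matrix`: a list with `values` (integer
#'   matrix, genes x samples) and `samples` (the validated sample sheet).
#' @export
read_counts <- function(counts_path, sheet_path) {
  sheet <- utils::read.csv(sheet_path, stringsAsFactors = FALSE)
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("counts file must have 'gene_id' as its first column, found '",
         names(tab)[1], "'")
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene_id
  count_matrix(values, sheet)
}

#' Construct and validate a count matrix
#'
#' @param values Numeric matrix of non-negative integer counts with gene ids
#'   as row names and sample ids as column names.
#' @param samples Sample sheet data frame with columns `sample`, `genotype`,
#'   `condition` (`control`/`treatment`) and `replicate`.
#' @return A `count_matrix` object; columns are reordered to the sheet order.
#' @export
count_matrix <- function(values, samples) {
  samples <- validate_sample_sheet(samples)
  if (is.null(rownames(values)))
    stop("count matrix must carry gene ids as row names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids in count matrix: ",
         paste(utils::head(unique(rownames(values)[duplicated(rownames(values))])),
               collapse = ", "))
  missing <- setdiff(samples$sample, colnames(values))
  if (length(missing))
    stop("sample sheet lists samples absent from the counts header: ",
         paste(missing, collapse = ", "))
  values <- values[, samples$sample, drop = FALSE]
  bad <- which(!is.finite(values) | values < 0 | values != round(values),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at gene '",
         rownames(values)[bad[1, 1]], "', sample '",
         colnames(values)[bad[1, 2]], "'")
  storage.mode(values) <- "double"
  structure(list(values = values, samples = samples), class = "count_matrix")
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample", "genotype", "condition", "replicate")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet <- as.data.frame(sheet)[, need]
  sheet$sample <- as.character(sheet$sample)
  sheet$genotype <- as.character(sheet$genotype)
  sheet$condition <- as.character(sheet$condition)
  if (anyDuplicated(sheet$sample))
    stop("duplicated sample ids in sample sheet: ",
         paste(unique(sheet$sample[duplicated(sheet$sample)]), collapse = ", "))
  bad_cond <- setdiff(unique(sheet$condition), c("control", "treatment"))
  if (length(bad_cond))
    stop("condition labels must be 'control' or 'treatment'; found: ",
         paste(bad_cond, collapse = ", "))
  if (any(!is.finite(sheet$replicate) | sheet$replicate < 1 |
            sheet$replicate != round(sheet$replicate)))
    stop("replicate indices must be positive integers")
  tab <- table(sheet$genotype, sheet$condition)
  if (ncol(tab) < 2 || any(tab == 0))
    stop("every genotype must appear under both conditions; offending: ",
         paste(rownames(tab)[rowSums(tab == 0) > 0], collapse = ", "))
  if (length(unique(as.vector(tab))) != 1)
    stop("all genotype x condition pairs must have the same replicate count")
  rownames(sheet) <- NULL
  sheet
}

#' @export
print.count_matrix <- function(x, ...) {
  m <- length(unique(x$samples$genotype))
  r <- nrow(x$samples) / (2 * m)
  cat(sprintf("count_matrix: %d genes x %d samples (%d genotypes x 2 conditions x %g replicates)\n",
              nrow(x$values), ncol(x$values), m, r))
  invisible(x)
}

#' Read a phenotype table
#'
#' Reads a long-format table (CSV or TSV, autodetected from the header line)
#' with columns `genotype`, `trait`, `condition`, `value`, holding one
#' control and one treatment measurement per genotype for each trait, and
#' pivots it into paired control/treatment blocks.
#'
#' @param path Path to the long-format phenotype file.
#' @return An object of class `phenotype_table`: list with `control` and
#'   `treatment` (genotype x trait matrices), `genotypes`, `traits`.
#' @export
read_phenotypes <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("genotype", "trait", "condition", "value")
  if (!all(need %in% names(tab)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  val <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(val)) {
    i <- which(is.na(val))[1]
    stop("non-numeric phenotype value '", tab$value[i], "' for genotype '",
         tab$genotype[i], "', trait '", tab$trait[i], "', condition '",
         tab$condition[i], "'")
  }
  tab$value <- val
  phenotype_table_from_long(tab)
}

phenotype_table_from_long <- function(tab) {
  bad_cond <- setdiff(unique(tab$condition), c("control", "treatment"))
  if (length(bad_cond))
    stop("phenotype condition labels must be 'control' or 'treatment'; found: ",
         paste(bad_cond, collapse = ", "))
  genotypes <- unique(tab$genotype)
  traits <- unique(tab$trait)
  key <- paste(tab$genotype, tab$trait, tab$condition, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), ][1, ]
    stop("duplicated phenotype cell: genotype '", d$genotype, "', trait '",
         d$trait, "', condition '", d$condition, "'")
  }
  blocks <- lapply(c("control", "treatment"), function(cond) {
    m <- matrix(NA_real_, length(genotypes), length(traits),
                dimnames = list(genotypes, traits))
    sub <- tab[tab$condition == cond, ]
    m[cbind(match(sub$genotype, genotypes), match(sub$trait, traits))] <- sub$value
    if (anyNA(m)) {
      i <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("missing phenotype cell: genotype '", genotypes[i[1]], "', trait '",
           traits[i[2]], "', condition '", cond, "'")
    }
    m
  })
  phenotype_table(blocks[[1]], blocks[[2]])
}

#' Construct a phenotype table from control and treatment blocks
#'
#' @param control,treatment Genotype x trait numeric matrices with matching
#'   dimnames; all values finite.
#' @return A `phenotype_table` object.
#' @export
phenotype_table <- function(control, treatment) {
  stopifnot(identical(dim(control), dim(treatment)),
            identical(dimnames(control), dimnames(treatment)))
  if (!all(is.finite(control)) || !all(is.finite(treatment)))
    stop("phenotype values must be finite")
  structure(list(control = control, treatment = treatment,
                 genotypes = rownames(control), traits = colnames(control)),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d genotypes x %d traits (%s), control + treatment\n",
              length(x$genotypes), length(x$traits),
              paste(x$traits, collapse = ", ")))
  invisible(x)
}

# ---- matrix TSV round-trip helpers ------------------------------------

fmt_num <- function(x) {
  # repr precision: round-trips to >= 12 significant digits
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%.0f", x),
         sprintf("%.15g", x))
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m),
                   apply(m, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

write_gmt <- function(modules, path, description = "overlapnet module") {
  lines <- vapply(names(modules), function(nm) {
    paste(c(nm, description, modules[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  out
}

#' Write all pipeline artifacts to a directory
#'
#' Persists every stage result of a fitted [overlapnet()] analysis as
#' plain-text, diff-able files: normalized expression (TSV), log fold
#' changes (TSV), the network edge list (TSV, `gene_a  gene_b  weight`),
#' module membership (two-column TSV and GMT), module eigengenes (TSV,
#' genotypes x modules), the per-trait LASSO selection (JSON), the gene
#' report (TSV) and a run summary (JSON).
#'
#' @param fit A fitted `overlapnet` object.
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, a named character vector manifest of the files written.
#' @export
write_outputs <- function(fit, out_dir) {
  stopifnot(inherits(fit, "overlapnet"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  manifest <- c()
  p <- function(f) file.path(out_dir, f)

  write_matrix_tsv(fit$d2, p("normalized_expression.tsv"))
  manifest["normalized_expression"] <- p("normalized_expression.tsv")

  write_matrix_tsv(fit$l1, p("lfc.tsv"))
  manifest["lfc"] <- p("lfc.tsv")

  edges <- network_edge_list(fit$network, fit$adjacency)
  utils::write.table(
    data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
               weight = fmt_num(edges$weight)),
    p("network_edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest["network_edges"] <- p("network_edges.tsv")

  mods <- module_gene_sets(fit$affiliation)
  mem <- data.frame(
    module_id = rep(names(mods), lengths(mods)),
    gene_id = unlist(mods, use.names = FALSE))
  utils::write.table(mem, p("modules.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest["modules_tsv"] <- p("modules.tsv")
  write_gmt(mods, p("modules.gmt"))
  manifest["modules_gmt"] <- p("modules.gmt")

  write_matrix_tsv(fit$eigengenes, p("eigengenes.tsv"), id_col = "genotype")
  manifest["eigengenes"] <- p("eigengenes.tsv")

  sel <- lapply(fit$fits, function(f) {
    nz <- which(f$coefficients != 0)
    list(lambda = f$lambda,
         modules = as.list(names(f$coefficients)[nz]),
         coefficients = as.list(unname(f$coefficients[nz])))
  })
  jsonlite::write_json(sel, p("selection.json"), auto_unbox = TRUE, digits = NA)
  manifest["selection"] <- p("selection.json")

  rep_tab <- fit$report$table
  rep_out <- rep_tab
  if (nrow(rep_out)) rep_out$max_abs_lfc <- fmt_num(rep_out$max_abs_lfc)
  utils::write.table(rep_out, p("gene_report.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest["gene_report"] <- p("gene_report.tsv")

  jsonlite::write_json(fit$summary_stats, p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest["summary"] <- p("summary.json")

  invisible(manifest)
}

network_edge_list <- function(net, adjacency) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency, arr.ind = TRUE)
  w <- adjacency[cbind(match(net$genes[idx[, 1]], rownames(adjacency)),
                       match(net$genes[idx[, 2]], colnames(adjacency)))]
  list(gene_a = net$genes[idx[, 1]], gene_b = net$genes[idx[, 2]], weight = w)
}

module_gene_sets <- function(f) {
  if (is.null(f) || ncol(f) == 0) return(stats::setNames(list(), character(0)))
  out <- lapply(seq_len(ncol(f)), function(u) rownames(f)[f[, u] == 1])
  names(out) <- colnames(f)
  out
}
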