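# shared fixtures and independent oracles

# --- small graphs as adjacency matrices ---------------------------------

adj_from_edges <- function(n, edges, ids = paste0("v", seq_len(n))) {
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

graph_triangle <- function() adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))

graph_two_triangles <- function() {
  adj_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                         c(4, 5), c(4, 6), c(5, 6)))
}

graph_bowtie <- function() {
  # two triangles sharing node 3
  adj_from_edges(5, list(c(1, 2), c(1, 3), c(2, 3),
                         c(3, 4), c(3, 5), c(4, 5)))
}

graph_star <- function(leaves = 3) {
  adj_from_edges(leaves + 1, lapply(seq_len(leaves) + 1, function(l) c(1, l)))
}

graph_path <- function(n = 3) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

graph_clique <- function(n) {
  a <- matrix(1, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  diag(a) <- 0
  a
}

graph_barbell <- function() {
  # two triangles joined by one bridge edge
  adj_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                         c(4, 5), c(4, 6), c(5, 6)))
}

random_gnp <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  a + t(a)
}

# --- naive independent HLC oracle (O(L^3) single linkage) ----------------

naive_link_similarity <- function(adj, e1, e2) {
  shared <- intersect(e1, e2)
  if (length(shared) != 1) return(NA_real_)
  i <- setdiff(e1, shared)
  j <- setdiff(e2, shared)
  eta_i <- union(i, which(adj[i, ] != 0))
  eta_j <- union(j, which(adj[j, ] != 0))
  length(intersect(eta_i, eta_j)) / length(union(eta_i, eta_j))
}

naive_partition_density <- function(edges, clusters) {
  L <- nrow(edges)
  total <- 0
  for (cl in clusters) {
    m_c <- length(cl)
    nodes <- unique(as.vector(edges[cl, , drop = FALSE]))
    n_c <- length(nodes)
    if (n_c > 2)
      total <- total + m_c * (m_c - n_c + 1) / ((n_c - 1) * (n_c - 2))
  }
  2 / L * total
}

# single-linkage over links, merging all pairs at each distinct level at
# once; returns max partition density over every dendrogram level
# (including all-singletons), with ties resolved toward finer partitions.
naive_hlc_best <- function(adj) {
  idx <- which(adj != 0 & upper.tri(adj), arr.ind = TRUE)
  edges <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  L <- nrow(edges)
  sims <- matrix(NA_real_, L, L)
  for (p in seq_len(L)) for (q in seq_len(L)) {
    if (p != q)
      sims[p, q] <- naive_link_similarity(adj, edges[p, ], edges[q, ])
  }
  clusters <- as.list(seq_len(L))
  best_D <- naive_partition_density(edges, clusters)
  best_clusters <- clusters
  levels <- sort(unique(sims[!is.na(sims)]), decreasing = TRUE)
  for (lev in levels) {
    # merge every cluster pair connected at similarity >= lev
    repeat {
      merged <- FALSE
      for (p in seq_along(clusters)) {
        for (q in seq_along(clusters)) {
          if (q <= p) next
          cross <- sims[clusters[[p]], clusters[[q]], drop = FALSE]
          if (any(!is.na(cross) & cross >= lev)) {
            clusters[[p]] <- c(clusters[[p]], clusters[[q]])
            clusters[[q]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    D <- naive_partition_density(edges, clusters)
    if (D > best_D) {
      best_D <- D
      best_clusters <- clusters
    }
  }
  list(density = best_D, clusters = best_clusters, edges = edges)
}

# --- misc ---------------------------------------------------------------

write_counts_fixture <- function(dir, counts, sheet) {
  counts_path <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet_path <- file.path(dir, "samples.csv")
  write.csv(sheet, sheet_path, row.names = FALSE, quote = FALSE)
  list(counts = counts_path, sheet = sheet_path)
}

toy_sheet <- function(m = 2, r = 2) {
  g <- expand.grid(replicate = seq_len(r),
                   genotype = paste0("g", seq_len(m)),
                   condition = c("control", "treatment"),
                   stringsAsFactors = FALSE)
  g$sample <- paste0("s", seq_len(nrow(g)))
  g[, c("sample", "genotype", "condition", "replicate")]
}
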