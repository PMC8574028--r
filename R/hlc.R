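#' Build a link graph from a binary network
#'
#' Represents a simple undirected graph by its node list, an indexed link
#' list, and the adjacency needed for inclusive neighborhoods
#' `eta(v) = {v} + neighbors(v)`.
#'
#' @param x A `binary_network` (from [binarize()]) or a symmetric 0/1 or
#'   logical adjacency matrix (diagonal ignored).
#' @return A list of class `link_graph`: `nodes` (ids), `edges` (L x 2
#'   integer matrix of node indices, first < second), `adjacency` (logical).
#' @export
link_graph <- function(x) {
  adj <- if (inherits(x, "binary_network")) x$adjacency else {
    a <- x != 0
    diag(a) <- FALSE
    a
  }
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric")
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- paste0("v", seq_len(nrow(adj)))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- cbind(idx[, 1], idx[, 2])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges, adjacency = adj),
            class = "link_graph")
}

#' @export
print.link_graph <- function(x, ...) {
  cat(sprintf("link_graph: %d nodes, %d links\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

resolve_nodes <- function(g, e) {
  if (is.character(e)) {
    i <- match(e, g$nodes)
    if (anyNA(i)) stop("unknown node id: ", paste(e[is.na(i)], collapse = ", "))
    i
  } else as.integer(e)
}

#' Jaccard similarity of two incident links
#'
#' For links e_ik and e_jk sharing exactly one node k, the similarity is the
#' Jaccard index of the inclusive neighborhoods of the non-shared endpoints:
#' `|eta(i) n eta(j)| / |eta(i) u eta(j)|`, with `eta(v)` the set containing
#' v and its neighbors.
#'
#' @param g A `link_graph`.
#' @param e1,e2 Links, each as a length-2 vector of node ids (or indices).
#' @return Similarity in [0, 1].
#' @export
link_similarity <- function(g, e1, e2) {
  a <- resolve_nodes(g, e1)
  b <- resolve_nodes(g, e2)
  shared <- intersect(a, b)
  if (length(shared) != 1)
    stop("links must share exactly one node; these share ", length(shared))
  i <- setdiff(a, shared)
  j <- setdiff(b, shared)
  eta_i <- g$adjacency[i, ]
  eta_i[i] <- TRUE
  eta_j <- g$adjacency[j, ]
  eta_j[j] <- TRUE
  sum(eta_i & eta_j) / sum(eta_i | eta_j)
}

# all similarities between pairs of links sharing a node, vectorized
adjacent_pair_similarities <- function(g) {
  L <- nrow(g$edges)
  if (L < 2)
    return(data.frame(link_a = integer(0), link_b = integer(0),
                      sim = numeric(0)))
  n <- length(g$nodes)
  eta <- g$adjacency
  diag(eta) <- TRUE
  common <- crossprod(eta * 1)           # |eta(i) n eta(j)| for all node pairs
  size <- rowSums(eta)
  # incident links per node
  inc <- vector("list", n)
  for (e in seq_len(L)) {
    inc[[g$edges[e, 1]]] <- c(inc[[g$edges[e, 1]]], e)
    inc[[g$edges[e, 2]]] <- c(inc[[g$edges[e, 2]]], e)
  }
  acc <- vector("list", n)
  for (k in seq_len(n)) {
    lk <- inc[[k]]
    d <- length(lk)
    if (d < 2) next
    cmb <- utils::combn(d, 2)
    e1 <- lk[cmb[1, ]]
    e2 <- lk[cmb[2, ]]
    other <- function(e) ifelse(g$edges[e, 1] == k, g$edges[e, 2], g$edges[e, 1])
    acc[[k]] <- cbind(e1, e2, other(e1), other(e2))
  }
  acc <- do.call(rbind, acc)
  if (is.null(acc))
    return(data.frame(link_a = integer(0), link_b = integer(0),
                      sim = numeric(0)))
  pa <- acc[, 1]; pb <- acc[, 2]; ni <- acc[, 3]; nj <- acc[, 4]
  cm <- common[cbind(ni, nj)]
  sim <- cm / (size[ni] + size[nj] - cm)
  data.frame(link_a = pa, link_b = pb, sim = sim)
}

#' Single-linkage link dendrogram
#'
#' Computes the Jaccard similarity for every pair of links sharing a node
#' and agglomerates link clusters by single linkage, processing all pairs at
#' an equal similarity level simultaneously so the result does not depend on
#' link enumeration order. Link pairs with no defined similarity (no shared
#' node) never force a merge, so the dendrogram is a forest over graph
#' components.
#'
#' @param g A `link_graph` with at least one link.
#' @return A list of class `link_dendrogram`: `n_links`, `levels` (distinct
#'   similarity levels, decreasing), `pairs` (data frame of link pairs and
#'   their similarity, ordered by decreasing similarity).
#' @export
build_link_dendrogram <- function(g) {
  stopifnot(inherits(g, "link_graph"), nrow(g$edges) >= 1)
  pairs <- adjacent_pair_similarities(g)
  pairs <- pairs[order(-pairs$sim, pairs$link_a, pairs$link_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(n_links = nrow(g$edges),
                 levels = unique(pairs$sim),
                 pairs = pairs),
            class = "link_dendrogram")
}

#' @export
print.link_dendrogram <- function(x, ...) {
  cat(sprintf("link_dendrogram: %d links, %d distinct merge levels\n",
              x$n_links, length(x$levels)))
  invisible(x)
}

# union-find with path halving
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

density_of_assignment <- function(edges, assign, L) {
  roots <- match(assign, unique(assign))
  m_c <- tabulate(roots)
  n <- max(edges)
  keys <- unique(c(roots * (n + 1) + edges[, 1],
                   roots * (n + 1) + edges[, 2]))
  n_c <- tabulate(keys %/% (n + 1), nbins = length(m_c))
  term <- ifelse(n_c > 2,
                 m_c * (m_c - n_c + 1) / ((n_c - 1) * (n_c - 2)), 0)
  2 / L * sum(term)
}

#' Partition density of a link partition
#'
#' Evaluates `D = (2/|E|) * sum_c |E_c| (|E_c| - |V_c| + 1) /
#' ((|V_c| - 1)(|V_c| - 2))` over the communities of a link partition.
#' Communities whose induced subgraph has at most 2 nodes (single links)
#' contribute 0, since the formula is undefined there. D is 1 when every
#' community is a clique on at least 3 nodes and 0 when each community is a
#' tree; communities sparser than a tree contribute negatively.
#'
#' @param g A `link_graph`.
#' @param partition An integer assignment vector (one community id per
#'   link), a list of link-index vectors, or a `link_partition`.
#' @return The partition density (numeric scalar).
#' @export
partition_density <- function(g, partition) {
  L <- nrow(g$edges)
  if (inherits(partition, "link_partition")) partition <- partition$assignment
  if (is.list(partition)) {
    idx <- unlist(partition, use.names = FALSE)
    if (length(idx) != L || anyDuplicated(idx) || !setequal(idx, seq_len(L)))
      stop("partition must cover every link exactly once")
    assign <- integer(L)
    for (c in seq_along(partition)) assign[partition[[c]]] <- c
  } else {
    assign <- as.integer(partition)
    if (length(assign) != L || anyNA(assign))
      stop("partition must cover every link exactly once")
  }
  density_of_assignment(g$edges, assign, L)
}

#' Cut the link dendrogram at maximum partition density
#'
#' Replays the single-linkage agglomeration, evaluating the partition
#' density after each distinct merge level (and at the all-singletons leaf
#' partition), and returns the partition with maximal density. Ties are
#' broken toward the higher similarity level, i.e. the finer partition.
#'
#' @param g A `link_graph`.
#' @param dendro The matching [build_link_dendrogram()] result; built from
#'   `g` if omitted.
#' @return A list of class `link_partition`: `assignment` (community id per
#'   link, renumbered in first-link order), `density`, `level` (similarity
#'   level of the cut; `Inf` for the leaf partition), `n_communities`,
#'   `profile` (data frame of level and density along the dendrogram).
#' @export
cut_at_max_density <- function(g, dendro = NULL) {
  if (is.null(dendro)) dendro <- build_link_dendrogram(g)
  L <- dendro$n_links
  parent <- seq_len(L)
  best_assign <- seq_len(L)
  best_D <- density_of_assignment(g$edges, best_assign, L)
  best_level <- Inf
  prof_level <- Inf
  prof_D <- best_D
  pairs <- dendro$pairs
  for (lev in dendro$levels) {
    sub <- pairs[pairs$sim == lev, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      ra <- uf_find(parent, sub$link_a[r])
      rb <- uf_find(parent, sub$link_b[r])
      if (ra != rb) parent[min(ra, rb)] <- max(ra, rb)
    }
    # full path compression by pointer doubling, so parent holds roots
    repeat {
      p2 <- parent[parent]
      if (identical(p2, parent)) break
      parent <- p2
    }
    assign <- parent
    D <- density_of_assignment(g$edges, assign, L)
    prof_level <- c(prof_level, lev)
    prof_D <- c(prof_D, D)
    if (D > best_D) {
      best_D <- D
      best_assign <- assign
      best_level <- lev
    }
  }
  structure(list(assignment = match(best_assign, unique(best_assign)),
                 density = best_D,
                 level = best_level,
                 n_communities = length(unique(best_assign)),
                 profile = data.frame(level = prof_level, density = prof_D)),
            class = "link_partition")
}

#' @export
print.link_partition <- function(x, ...) {
  cat(sprintf("link_partition: %d communities, D = %.4f (cut level %s)\n",
              x$n_communities, x$density, format(x$level)))
  invisible(x)
}

#' Gene-module affiliation matrix
#'
#' A gene belongs to a module iff it is an endpoint of one of the module's
#' links, so genes inherit every community of their incident links and can
#' belong to several (or, after size filtering, zero) modules. Modules with
#' fewer than `min_module_size` genes are dropped.
#'
#' @param g A `link_graph`.
#' @param partition A `link_partition` (or assignment vector) over `g`.
#' @param min_module_size Minimum genes per retained module (default 3).
#' @return Binary genes x modules matrix (all nodes of `g` as rows; module
#'   columns `M1`, `M2`, ... in first-link order).
#' @export
affiliation <- function(g, partition, min_module_size = 3) {
  if (inherits(partition, "link_partition")) partition <- partition$assignment
  assign <- as.integer(partition)
  stopifnot(length(assign) == nrow(g$edges))
  comms <- sort(unique(assign))
  sets <- lapply(comms, function(c) {
    e <- g$edges[assign == c, , drop = FALSE]
    sort(unique(as.vector(e)))
  })
  keep <- lengths(sets) >= min_module_size
  sets <- sets[keep]
  f <- matrix(0L, length(g$nodes), length(sets),
              dimnames = list(g$nodes,
                              if (length(sets)) paste0("M", seq_along(sets))
                              else character(0)))
  for (u in seq_along(sets)) f[sets[[u]], u] <- 1L
  f
}

#' Module-membership overlap summary
#'
#' Per-gene module counts and the split of affiliated genes between single
#' and multiple memberships.
#'
#' @param f Affiliation matrix from [affiliation()].
#' @return List: `counts` (named integer per gene), `n_affiliated`,
#'   `frac_single`, `frac_multi` (fractions of affiliated genes in exactly
#'   one / more than one module).
#' @export
overlap_histogram <- function(f) {
  stopifnot(length(f) > 0)
  counts <- rowSums(f)
  aff <- counts >= 1
  n_aff <- sum(aff)
  list(counts = counts,
       n_affiliated = n_aff,
       frac_single = if (n_aff) sum(counts[aff] == 1) / n_aff else NA_real_,
       frac_multi = if (n_aff) sum(counts[aff] >= 2) / n_aff else NA_real_)
}
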