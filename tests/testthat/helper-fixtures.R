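# Shared fixtures and independent brute-force oracles.

# Build a signed graph directly from an edge description, bypassing
# threshold_edges, for hand-constructed metric cases.
make_graph <- function(nodes, from = character(0), to = character(0),
                       weight = numeric(0), threshold = 0.5,
                       condition = "fixture") {
  structure(list(
    nodes = region_set(nodes),
    edges = data.frame(from = from, to = to, weight = weight,
                       sign = ifelse(weight > 0, "positive", "negative"),
                       stringsAsFactors = FALSE),
    threshold = threshold, condition = condition),
    class = "signed_graph")
}

# Independent oracle for the within-module degree score: a single pass over
# the raw edge list, no shared code with mwmdz().
oracle_mwmdz <- function(edges, assignment, sizes, node) {
  s_i <- sizes[[assignment[[node]]]]
  if (s_i == 1) return(0)
  total <- 0
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]; b <- edges$to[i]
      if (a != node && b != node) next
      other <- if (a == node) b else a
      if (assignment[[other]] == assignment[[node]]) {
        total <- total + abs(edges$weight[i])
      }
    }
  }
  total / (s_i - 1)
}

# Independent oracle for the participation coefficient.
oracle_pc <- function(edges, assignment, node) {
  counts <- list()
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]; b <- edges$to[i]
      if (a != node && b != node) next
      other <- if (a == node) b else a
      m <- as.character(assignment[[other]])
      counts[[m]] <- (counts[[m]] %||% 0) + 1
    }
  }
  k <- sum(unlist(counts))
  if (k == 0) return(0)
  1 - sum(vapply(counts, function(x) (x / k)^2, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random signed graph over given nodes: each pair carries an edge with
# probability p_edge, weight uniform on (0.5, 1] with random sign.
random_graph <- function(nodes, p_edge = 0.4) {
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  w <- (0.5 + 0.5 * stats::runif(sum(keep))) *
    sample(c(-1, 1), sum(keep), replace = TRUE)
  make_graph(nodes,
             from = pairs[1, keep], to = pairs[2, keep], weight = w)
}

random_partition <- function(nodes, n_modules) {
  module_partition(stats::setNames(
    sample(seq_len(n_modules), length(nodes), replace = TRUE), nodes))
}

# Independent naive agglomerative clustering (complete linkage) used as an
# oracle for hierarchical_cluster on small inputs: repeatedly merges the
# pair of clusters with the smallest maximum inter-point distance.
naive_complete_linkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- list(members = merged, height = best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Partition from the naive linkage at a strict height cut.
naive_cut <- function(D, h) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  repeat {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (is.null(best) || best_d >= h) break
    clusters <- c(clusters[-best],
                  list(sort(c(clusters[[best[1]]], clusters[[best[2]]]))))
  }
  asg <- stats::setNames(character(length(labels)), labels)
  for (i in seq_along(clusters)) asg[clusters[[i]]] <- as.character(i)
  asg
}

# Canonical small condition specs.
tiny_spec <- function(n = 9, rho_within = 0.8, rho_between = 0,
                      regions = c("A", "B", "C", "D"),
                      partition = NULL, condition = "tiny") {
  means <- stats::setNames(rep(500, length(regions)), regions)
  sds <- stats::setNames(rep(100, length(regions)), regions)
  if (is.null(partition)) {
    partition <- stats::setNames(rep(c(1, 2), length.out = length(regions)),
                                 regions)
    partition <- sort(partition)
    names(partition) <- regions
  }
  condition_spec(condition, n, means, sds, partition, rho_within, rho_between)
}

# Group samples with exact means and sds (no sampling noise).
exact_groups <- function(means, sds, n = 10) {
  base <- as.vector(scale(seq_len(n)))
  groups <- Map(function(m, s) m + s * base, means, sds)
  group_samples("outcome", groups)
}

# Agreement between two labelled partitions, ignoring label names
# (adjusted Rand index via mclust when available).
partition_ari <- function(a, b) {
  stopifnot(requireNamespace("mclust", quietly = TRUE))
  common <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[common], b[common])
}

# Exact equivalence up to label renaming: identical co-membership on every
# pair (well-defined for degenerate partitions where the ARI is NaN).
partitions_equal <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) != length(a) || length(common) != length(b)) return(FALSE)
  co <- function(x) outer(x[common], x[common], "==")
  identical(co(a), co(b))
}
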