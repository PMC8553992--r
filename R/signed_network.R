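#' Threshold a correlation matrix into a signed graph
#'
#' An edge joins two regions iff the absolute Pearson correlation strictly
#' exceeds the threshold: positive edges for R > threshold, negative edges
#' for R < -threshold, the correlation kept as the edge weight. An R of
#' exactly the threshold (0.5 by default) yields no edge. Missing-pair
#' sentinels (`NA`) never produce edges (logged).
#'
#' @param cm A [correlation_matrix()].
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.5.
#' @return Object of class `"signed_graph"`: list with `nodes` (the region
#'   set), `edges` (data frame `from`, `to`, `weight`, `sign`),
#'   `threshold`, `condition`.
#' @examples
#' tab <- generate_condition(
#'   condition_spec("c", 9, c(A = 500, B = 500, C = 500),
#'                  c(A = 100, B = 100, C = 100),
#'                  c(A = 1, B = 1, C = 2), 0.9), seed = 7)
#' threshold_edges(correlation_matrix(tab))
#' @export
threshold_edges <- function(cm, threshold = 0.5) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  R <- cm$R
  ut <- upper.tri(R)
  idx <- which(ut, arr.ind = TRUE)
  w <- R[ut]
  n_missing <- sum(is.na(w))
  if (n_missing > 0) {
    message(sprintf("%d region pair(s) with missing correlation carry no edge",
                    n_missing))
  }
  keep <- !is.na(w) & abs(w) > threshold
  edges <- data.frame(
    from = rownames(R)[idx[keep, 1]],
    to = colnames(R)[idx[keep, 2]],
    weight = w[keep],
    sign = ifelse(w[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  structure(list(nodes = cm$regions, edges = edges,
                 threshold = threshold, condition = cm$condition),
            class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat(sprintf(
    "Signed graph '%s': %d nodes, %d edges (%d positive, %d negative), |R| > %g\n",
    x$condition, length(x$nodes), nrow(x$edges),
    sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative"),
    x$threshold))
  invisible(x)
}

# incident edges of a node
node_edges <- function(g, node) {
  g$edges[g$edges$from == node | g$edges$to == node, , drop = FALSE]
}

edge_other_end <- function(edges, node) {
  ifelse(edges$from == node, edges$to, edges$from)
}

#' Modified within-module degree score
#'
#' The weight-based within-module connectivity score for small signed
#' networks: the sum of absolute edge weights between a node and its
#' module mates, divided by `(s_i - 1)` where `s_i` is the node's module
#' size. Ranges from 0 (no within-module edges) to 1 (edges of absolute
#' weight 1 to every module mate). A node alone in its module scores 0 by
#' definition. Despite the "z" its name inherits from the classical
#' within-module degree z score, no mean/variance standardization is
#' involved.
#'
#' @param g A [threshold_edges()] signed graph.
#' @param p A [module_partition()] over the same regions.
#' @param nodes Nodes to evaluate; default all.
#' @return Named numeric vector in `[0, 1]`.
#' @examples
#' # a node with within-module edge weights 0.6 and -0.8 in a module of 3
#' g <- structure(list(
#'   nodes = region_set(c("A", "B", "C")),
#'   edges = data.frame(from = c("A", "A"), to = c("B", "C"),
#'                      weight = c(0.6, -0.8),
#'                      sign = c("positive", "negative")),
#'   threshold = 0.5, condition = "demo"), class = "signed_graph")
#' mwmdz(g, module_partition(c(A = 1, B = 1, C = 1)))  # A: 0.7
#' @export
mwmdz <- function(g, p, nodes = NULL) {
  stopifnot(inherits(g, "signed_graph"), inherits(p, "module_partition"))
  if (is.null(nodes)) nodes <- as.character(g$nodes)
  check_nodes(g, p, nodes)
  asg <- p$assignment
  out <- vapply(nodes, function(node) {
    s_i <- p$module_sizes[[asg[[node]]]]
    if (s_i == 1L) return(0)
    e <- node_edges(g, node)
    mates <- edge_other_end(e, node)
    within <- asg[mates] == asg[[node]]
    sum(abs(e$weight[within])) / (s_i - 1L)
  }, numeric(1))
  stats::setNames(out, nodes)
}

#' Participation coefficient
#'
#' Measures how a node's edges are distributed over modules:
#' `1 - sum_s (K_is / k_i)^2`, where `K_is` is the number of edges (counted
#' regardless of sign or weight) between node `i` and module `s`, and
#' `k_i` is the node's total degree. 0 when every edge stays in one module
#' (in particular the node's own), approaching 1 as edges spread evenly
#' over many modules. An isolated node (`k_i = 0`) returns 0 with a
#' warning.
#'
#' @inheritParams mwmdz
#' @return Named numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(g, p, nodes = NULL) {
  stopifnot(inherits(g, "signed_graph"), inherits(p, "module_partition"))
  if (is.null(nodes)) nodes <- as.character(g$nodes)
  check_nodes(g, p, nodes)
  asg <- p$assignment
  out <- vapply(nodes, function(node) {
    e <- node_edges(g, node)
    k_i <- nrow(e)
    if (k_i == 0L) {
      warning("node '", node, "' has no edges; participation coefficient 0",
              call. = FALSE)
      return(0)
    }
    k_is <- table(asg[edge_other_end(e, node)])
    1 - sum((as.numeric(k_is) / k_i)^2)
  }, numeric(1))
  stats::setNames(out, nodes)
}

check_nodes <- function(g, p, nodes) {
  bad <- setdiff(nodes, as.character(g$nodes))
  if (length(bad)) {
    stop("node(s) not in graph: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(nodes, names(p$assignment))
  if (length(bad)) {
    stop("node(s) not in partition: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-node network metrics table
#'
#' Computes, for every node, the module id, within-module degree `K_i`,
#' total degree `k_i`, the modified within-module degree score and the
#' participation coefficient. The per-module degree breakdown `K_is` is
#' attached as the `module_degrees` attribute (nodes x modules matrix) for
#' audit.
#'
#' @param g A [threshold_edges()] signed graph.
#' @param p A [module_partition()] over exactly the graph's region set.
#' @return Data frame of class `"node_metrics"` with columns `region`,
#'   `module`, `k_within`, `k_total`, `mwmdz`, `pc`.
#' @export
node_metrics_table <- function(g, p) {
  stopifnot(inherits(g, "signed_graph"), inherits(p, "module_partition"))
  g_only <- setdiff(as.character(g$nodes), names(p$assignment))
  p_only <- setdiff(names(p$assignment), as.character(g$nodes))
  if (length(g_only) || length(p_only)) {
    stop("graph/partition region mismatch; graph only: {",
         paste(g_only, collapse = ", "), "}, partition only: {",
         paste(p_only, collapse = ", "), "}", call. = FALSE)
  }
  nodes <- as.character(g$nodes)
  asg <- p$assignment
  mods <- names(p$module_sizes)
  deg <- matrix(0L, length(nodes), length(mods),
                dimnames = list(nodes, mods))
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$from[i]; b <- g$edges$to[i]
    deg[a, asg[[b]]] <- deg[a, asg[[b]]] + 1L
    deg[b, asg[[a]]] <- deg[b, asg[[a]]] + 1L
  }
  k_total <- rowSums(deg)
  k_within <- deg[cbind(nodes, asg[nodes])]
  pc <- suppressWarnings(participation_coefficient(g, p, nodes))
  out <- data.frame(region = nodes,
                    module = unname(asg[nodes]),
                    k_within = as.integer(k_within),
                    k_total = as.integer(k_total),
                    mwmdz = unname(mwmdz(g, p, nodes)),
                    pc = unname(pc),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("node_metrics", "data.frame"),
            module_degrees = deg)
}

#' Convert a signed graph to igraph
#'
#' @param g A [threshold_edges()] signed graph.
#' @param metrics Optional [node_metrics_table()] to attach as node
#'   attributes (`module`, `mwmdz`, `pc`).
#' @return An undirected [igraph::graph] with `weight` and `sign` edge
#'   attributes.
#' @export
as_igraph <- function(g, metrics = NULL) {
  stopifnot(inherits(g, "signed_graph"))
  vertices <- data.frame(name = as.character(g$nodes),
                         stringsAsFactors = FALSE)
  if (!is.null(metrics)) {
    stopifnot(inherits(metrics, "node_metrics"))
    m <- metrics[match(vertices$name, metrics$region), ]
    vertices$module <- m$module
    vertices$mwmdz <- m$mwmdz
    vertices$pc <- m$pc
  }
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = vertices)
}

#' Export a signed graph to standard network file formats
#'
#' Writes Gephi-readable GraphML or GEXF, or a plain signed edge list.
#' Nodes carry `module`, `mwmdz` and `pc` attributes when `metrics` is
#' given; edges always carry the signed `weight` and a `sign` attribute
#' (`"positive"`/`"negative"`).
#'
#' @param g A [threshold_edges()] signed graph.
#' @param metrics Optional [node_metrics_table()].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, metrics = NULL, path,
                         format = c("graphml", "gexf", "edgelist")) {
  stopifnot(inherits(g, "signed_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- as_igraph(g, metrics)
    igraph::write_graph(ig, path, format = "graphml")
  } else if (format == "gexf") {
    write_gexf(g, metrics, path)
  } else {
    utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

# minimal GEXF 1.2 writer (static undirected graph, node/edge attvalues)
write_gexf <- function(g, metrics, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nodes <- as.character(g$nodes)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="module" title="module" type="string"/>',
    '      <attribute id="mwmdz" title="mwmdz" type="double"/>',
    '      <attribute id="pc" title="pc" type="double"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="sign" title="sign" type="string"/>',
    '      <attribute id="r" title="r" type="double"/>',
    '    </attributes>',
    '    <nodes>')
  for (node in nodes) {
    if (!is.null(metrics)) {
      m <- metrics[metrics$region == node, ]
      lines <- c(lines, sprintf(
        '      <node id="%s" label="%s"><attvalues><attvalue for="module" value="%s"/><attvalue for="mwmdz" value="%.17g"/><attvalue for="pc" value="%.17g"/></attvalues></node>',
        esc(node), esc(node), esc(m$module), m$mwmdz, m$pc))
    } else {
      lines <- c(lines, sprintf('      <node id="%s" label="%s"/>',
                                esc(node), esc(node)))
    }
  }
  lines <- c(lines, '    </nodes>', '    <edges>')
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      lines <- c(lines, sprintf(
        '      <edge id="e%d" source="%s" target="%s" weight="%.17g"><attvalues><attvalue for="sign" value="%s"/><attvalue for="r" value="%.17g"/></attvalues></edge>',
        i, esc(g$edges$from[i]), esc(g$edges$to[i]),
        abs(g$edges$weight[i]), g$edges$sign[i], g$edges$weight[i]))
    }
  }
  lines <- c(lines, '    </edges>', '  </graph>', '</gexf>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
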