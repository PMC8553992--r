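as_cm <- function(R, condition = "fixture") {
  structure(list(condition = condition, regions = region_set(rownames(R)),
                 R = R, n_used = NULL, min_pairs = NA_integer_),
            class = "correlation_matrix")
}

test_that("edge thresholding is strict and sign-preserving", {
  labels <- c("A", "B", "C", "D")
  R <- diag(4); dimnames(R) <- list(labels, labels)
  R["A", "B"] <- R["B", "A"] <- 0.5      # exactly at threshold: no edge
  R["A", "C"] <- R["C", "A"] <- -0.51    # negative edge
  R["B", "C"] <- R["C", "B"] <- 0.51     # positive edge
  R["A", "D"] <- R["D", "A"] <- -0.5     # exactly at -threshold: no edge
  g <- threshold_edges(as_cm(R), threshold = 0.5)
  key <- paste(g$edges$from, g$edges$to)
  expect_setequal(key, c("A C", "B C"))
  expect_equal(g$edges$weight[key == "A C"], -0.51)
  expect_equal(g$edges$sign[key == "A C"], "negative")
  expect_equal(g$edges$sign[key == "B C"], "positive")

  # identity matrix -> empty edge set
  eye <- diag(3)
  dimnames(eye) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  expect_equal(nrow(threshold_edges(as_cm(eye))$edges), 0L)
  expect_error(threshold_edges(as_cm(eye), threshold = 1), "threshold")
})

test_that("missing-pair sentinels never become edges", {
  labels <- c("A", "B", "C")
  R <- diag(3); dimnames(R) <- list(labels, labels)
  R["A", "B"] <- R["B", "A"] <- NA
  R["A", "C"] <- R["C", "A"] <- 0.9
  expect_message(g <- threshold_edges(as_cm(R)), "missing")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 0.9)
})

test_that("raising the threshold never adds an edge", {
  withr::local_seed(5)
  sp <- tiny_spec(n = 9, rho_within = 0.7, regions = paste0("R", 1:8),
                  partition = stats::setNames(rep(1:2, each = 4),
                                              paste0("R", 1:8)))
  cm <- correlation_matrix(generate_condition(sp, seed = 3))
  prev <- NULL
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    edges <- threshold_edges(cm, th)$edges
    key <- paste(edges$from, edges$to)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("within-module degree score matches its analytic cases", {
  # singleton module -> 0 even with cross-module edges
  g <- make_graph(c("A", "B", "C"), from = c("A", "A"), to = c("B", "C"),
                  weight = c(0.9, -0.9))
  p <- module_partition(c(A = 1, B = 2, C = 2))
  expect_equal(unname(mwmdz(g, p, "A")), 0)

  # module of 3 with within edges 0.6 and -0.8 -> 0.7
  g2 <- make_graph(c("A", "B", "C", "D"),
                   from = c("A", "A", "A"), to = c("B", "C", "D"),
                   weight = c(0.6, -0.8, 0.95))
  p2 <- module_partition(c(A = 1, B = 1, C = 1, D = 2))
  expect_equal(unname(mwmdz(g2, p2, "A")), 0.7)

  # |r| = 1 edges to every module mate -> exactly 1
  g3 <- make_graph(c("A", "B", "C", "D"),
                   from = c("A", "A", "A"), to = c("B", "C", "D"),
                   weight = c(1, -1, 1))
  p3 <- module_partition(c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(unname(mwmdz(g3, p3, "A")), 1)
})

test_that("participation coefficient matches its analytic cases", {
  # all edges within own module -> 0
  g <- make_graph(c("A", "B", "C", "D"),
                  from = c("A", "A", "A"), to = c("B", "C", "D"),
                  weight = c(0.6, 0.7, -0.9))
  p <- module_partition(c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(unname(participation_coefficient(g, p, "A")), 0)

  # 4 edges split 2/2 across two modules -> 0.5
  g2 <- make_graph(c("A", "B", "C", "D", "E"),
                   from = rep("A", 4), to = c("B", "C", "D", "E"),
                   weight = c(0.6, 0.7, -0.6, -0.7))
  p2 <- module_partition(c(A = 1, B = 1, C = 1, D = 2, E = 2))
  expect_equal(unname(participation_coefficient(g2, p2, "A")), 0.5)

  # 4 edges spread over 4 modules -> 0.75
  p3 <- module_partition(c(A = 1, B = 1, C = 2, D = 3, E = 4))
  expect_equal(unname(participation_coefficient(g2, p3, "A")), 0.75)

  # isolated node -> 0 with a warning
  expect_warning(
    pc <- participation_coefficient(g2, p2, "E"), NA)  # E has one edge
  g_iso <- make_graph(c("A", "B", "Z"), from = "A", to = "B", weight = 0.8)
  expect_warning(
    pc0 <- participation_coefficient(g_iso,
      module_partition(c(A = 1, B = 1, Z = 2)), "Z"), "no edges")
  expect_equal(unname(pc0), 0)
})

test_that("metrics lie in range and ignore edge signs where they must", {
  withr::local_seed(41)
  for (rep in 1:200) {
    nodes <- paste0("N", seq_len(sample(4:8, 1)))
    g <- random_graph(nodes, p_edge = 0.5)
    p <- random_partition(nodes, sample(2:4, 1))
    mz <- suppressWarnings(mwmdz(g, p))
    pc <- suppressWarnings(participation_coefficient(g, p))
    expect_true(all(mz >= 0 & mz <= 1))
    expect_true(all(pc >= 0 & pc < 1))
    # pc bounded by 1 - 1/(modules touched)
    for (node in nodes) {
      e <- g$edges[g$edges$from == node | g$edges$to == node, ]
      if (nrow(e) == 0) next
      others <- ifelse(e$from == node, e$to, e$from)
      nm <- length(unique(p$assignment[others]))
      expect_lte(pc[[node]], 1 - 1 / nm + 1e-12)
    }
    # flipping one edge sign changes neither metric
    if (nrow(g$edges)) {
      g_flip <- g
      g_flip$edges$weight[1] <- -g_flip$edges$weight[1]
      g_flip$edges$sign[1] <- ifelse(g_flip$edges$weight[1] > 0,
                                     "positive", "negative")
      expect_equal(suppressWarnings(mwmdz(g_flip, p)), mz)
      expect_equal(suppressWarnings(participation_coefficient(g_flip, p)), pc)
    }
  }
})

test_that("node metrics table matches the brute-force oracle and bookkeeping", {
  withr::local_seed(53)
  for (rep in 1:50) {
    nodes <- paste0("N", seq_len(sample(4:6, 1)))
    g <- random_graph(nodes, p_edge = 0.6)
    p <- random_partition(nodes, 3)
    tab <- suppressWarnings(node_metrics_table(g, p))
    deg <- attr(tab, "module_degrees")
    for (i in seq_len(nrow(tab))) {
      node <- tab$region[i]
      expect_equal(tab$mwmdz[i],
                   oracle_mwmdz(g$edges, p$assignment, p$module_sizes, node))
      expect_equal(tab$pc[i], oracle_pc(g$edges, p$assignment, node))
      # sum_s K_is = k_i; K_i <= min(k_i, s_i - 1)
      expect_equal(sum(deg[node, ]), tab$k_total[i])
      s_i <- p$module_sizes[[p$assignment[[node]]]]
      expect_lte(tab$k_within[i], min(tab$k_total[i], s_i - 1))
    }
  }
})

test_that("node order does not change the metrics table", {
  withr::local_seed(61)
  nodes <- paste0("N", 1:6)
  g <- random_graph(nodes, p_edge = 0.6)
  p <- random_partition(nodes, 3)
  g_perm <- g
  g_perm$nodes <- region_set(rev(nodes))
  t1 <- suppressWarnings(node_metrics_table(g, p))
  t2 <- suppressWarnings(node_metrics_table(g_perm, p))
  t2 <- t2[match(t1$region, t2$region), ]
  cols <- c("region", "module", "k_within", "k_total", "mwmdz", "pc")
  expect_equal(`rownames<-`(as.data.frame(t2)[cols], NULL),
               `rownames<-`(as.data.frame(t1)[cols], NULL))
})

test_that("metrics table rejects graph/partition region mismatch", {
  g <- make_graph(c("A", "B"), from = "A", to = "B", weight = 0.8)
  p <- module_partition(c(A = 1, C = 1))
  expect_error(node_metrics_table(g, p), "mismatch.*B.*C")
})

test_that("an empty graph yields all-zero metrics", {
  g <- make_graph(paste0("R", 1:13))
  p <- module_partition(stats::setNames(rep(1:3, length.out = 13),
                                        paste0("R", 1:13)))
  tab <- suppressWarnings(node_metrics_table(g, p))
  expect_equal(tab$mwmdz, rep(0, 13))
  expect_equal(tab$pc, rep(0, 13))
  expect_equal(tab$k_total, rep(0L, 13))
})

test_that("graphml export round-trips nodes, edges, weights and attributes", {
  withr::local_seed(71)
  nodes <- paste0("N", 1:6)
  g <- random_graph(nodes, p_edge = 0.7)
  p <- random_partition(nodes, 2)
  metrics <- suppressWarnings(node_metrics_table(g, p))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, metrics, path, format = "graphml")
  back <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(back)$name, nodes)
  expect_equal(igraph::ecount(back), nrow(g$edges))
  ends <- igraph::as_data_frame(back, "edges")
  ord <- order(ends$from, ends$to)
  gord <- order(g$edges$from, g$edges$to)
  expect_equal(ends$weight[ord], g$edges$weight[gord])
  expect_equal(ends$sign[ord], g$edges$sign[gord])
  expect_equal(igraph::V(back)$pc[match(nodes, igraph::V(back)$name)],
               metrics$pc[match(nodes, metrics$region)])
})

test_that("gexf export is valid XML carrying signs; empty graphs export too", {
  skip_if_not_installed("xml2")
  g <- make_graph(c("A", "B", "C"), from = c("A", "A"), to = c("B", "C"),
                  weight = c(0.8, -0.7))
  p <- module_partition(c(A = 1, B = 1, C = 2))
  metrics <- node_metrics_table(g, p)
  path <- withr::local_tempfile(fileext = ".gexf")
  export_graph(g, metrics, path, format = "gexf")
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_length(edges, 2L)
  signs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//d1:attvalue[@for='sign']", ns), "value")
  expect_setequal(signs, c("positive", "negative"))

  # empty 13-node graph still exports valid files
  g_empty <- make_graph(paste0("R", 1:13))
  path2 <- withr::local_tempfile(fileext = ".gexf")
  export_graph(g_empty, NULL, path2, format = "gexf")
  doc2 <- xml2::read_xml(path2)
  expect_length(xml2::xml_find_all(doc2, ".//d1:node", xml2::xml_ns(doc2)), 13L)
  expect_length(xml2::xml_find_all(doc2, ".//d1:edge", xml2::xml_ns(doc2)), 0L)

  path3 <- withr::local_tempfile(fileext = ".txt")
  export_graph(g, metrics, path3, format = "edgelist")
  el <- utils::read.delim(path3)
  expect_equal(nrow(el), 2L)
  expect_error(export_graph(g, metrics, path3, format = "dot"), "arg")
})
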