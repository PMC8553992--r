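#' Construct a module partition
#'
#' @param assignment Named vector, region -> module id (coerced to
#'   character ids).
#' @return Object of class `"module_partition"`: list with `assignment`,
#'   `n_modules`, `module_sizes`.
#' @examples
#' module_partition(c(A = 1, B = 1, C = 2))
#' @export
module_partition <- function(assignment) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be named by region", call. = FALSE)
  }
  region_set(names(assignment))
  ids <- as.character(assignment)
  sizes <- table(ids)
  structure(list(assignment = stats::setNames(ids, names(assignment)),
                 n_modules = length(sizes),
                 module_sizes = stats::setNames(as.integer(sizes),
                                                names(sizes))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d regions in %d modules (%d isolates)\n",
              length(x$assignment), x$n_modules, count_isolates(x)))
  for (m in names(x$module_sizes)) {
    cat(sprintf("  module %s: %s\n", m,
                paste(names(x$assignment)[x$assignment == m], collapse = ", ")))
  }
  invisible(x)
}

#' Euclidean distances between correlation profiles
#'
#' Each region's coactivity profile is its full row of the correlation
#' matrix (all columns, diagonal included); the distance between two
#' regions is the Euclidean norm of the difference between their rows.
#' Regions with identical profiles are at distance 0.
#'
#' @param cm A [correlation_matrix()] with no missing entries (drop
#'   incomplete regions upstream), and at least 3 regions.
#' @return Object of class `"distance_matrix"`: list with `regions` and the
#'   symmetric matrix `D`.
#' @examples
#' tab <- generate_condition(
#'   condition_spec("c", 9, c(A = 500, B = 500, C = 500),
#'                  c(A = 100, B = 100, C = 100),
#'                  c(A = 1, B = 1, C = 2), 0.8), seed = 7)
#' correlation_distance(correlation_matrix(tab))
#' @export
correlation_distance <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (length(cm$regions) < 3L) {
    stop("need at least 3 regions to cluster", call. = FALSE)
  }
  if (anyNA(cm$R)) {
    stop("correlation matrix has missing pairs; drop incomplete regions first",
         call. = FALSE)
  }
  D <- as.matrix(stats::dist(cm$R, method = "euclidean"))
  structure(list(regions = cm$regions, D = D, condition = cm$condition),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Euclidean distance matrix over %d correlation profiles\n",
              length(x$regions)))
  print(round(x$D, 3))
  invisible(x)
}

#' Agglomerative hierarchical clustering of regions
#'
#' Clusters regions on their correlation-profile distances. The default
#' linkage is complete (monotone merge heights, so the half-height cut is
#' well defined); `single`, `average` and `ward` (Ward's method on squared
#' Euclidean distances, `ward.D2`) are also supported. Regions are ordered
#' lexicographically before clustering so ties break identically however
#' the input was ordered.
#'
#' @param dm A [correlation_distance()] result.
#' @param linkage_method One of `"complete"`, `"single"`, `"average"`,
#'   `"ward"`.
#' @return Object of class `"linkage_tree"`: list with the `hclust` fit,
#'   `max_height`, `method`, `regions`.
#' @export
hierarchical_cluster <- function(dm, linkage_method = "complete") {
  stopifnot(inherits(dm, "distance_matrix"))
  supported <- c(complete = "complete", single = "single",
                 average = "average", ward = "ward.D2")
  if (!linkage_method %in% names(supported)) {
    stop("unsupported linkage '", linkage_method, "'; supported: ",
         paste(names(supported), collapse = ", "), call. = FALSE)
  }
  ord <- order(rownames(dm$D), method = "radix")
  D <- dm$D[ord, ord]
  hc <- stats::hclust(stats::as.dist(D), method = supported[[linkage_method]])
  if (is.unsorted(hc$height)) {
    # single/complete/average/ward.D2 are all monotone; guard regardless
    stop("non-monotone merge heights; choose a monotone linkage", call. = FALSE)
  }
  structure(list(hclust = hc, max_height = max(hc$height),
                 method = linkage_method, regions = dm$regions,
                 condition = dm$condition),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("Linkage tree (%s linkage): %d merges, max height %.4g\n",
              x$method, length(x$hclust$height), x$max_height))
  invisible(x)
}

#' Linkage merges as a table
#'
#' @param tree A [hierarchical_cluster()] result.
#' @return Data frame with `merge`, `child_a`, `child_b` (negative = leaf
#'   index, positive = earlier merge), `height`, `size`.
#' @export
linkage_table <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  hc <- tree$hclust
  n <- length(hc$labels)
  sizes <- integer(n - 1L)
  child_size <- function(ch, i) if (ch < 0) 1L else sizes[ch]
  for (i in seq_len(n - 1L)) {
    sizes[i] <- child_size(hc$merge[i, 1], i) + child_size(hc$merge[i, 2], i)
  }
  data.frame(merge = seq_len(n - 1L),
             child_a = hc$merge[, 1], child_b = hc$merge[, 2],
             height = hc$height, size = sizes)
}

#' Cut a dendrogram at a fraction of its height
#'
#' Modules are the maximal clusters fully merged at heights strictly below
#' `cut_fraction * max_height`; the default `cut_fraction = 0.5` is the
#' half-height cut. A merge sitting exactly at the cut height does not
#' join (strict inequality, so ties at the cut resolve identically every
#' run). Leaves not merged below the cut become singleton modules --
#' isolates. `cut_fraction = 1` means cutting at the root: every merge is
#' applied and a single module results.
#'
#' Module ids are assigned in lexicographic order of each module's first
#' region label.
#'
#' @param tree A [hierarchical_cluster()] result.
#' @param cut_fraction Fraction of the tree's maximum merge height in
#'   (0, 1]; default 0.5.
#' @return A [module_partition()].
#' @export
cut_dendrogram <- function(tree, cut_fraction = 0.5) {
  stopifnot(inherits(tree, "linkage_tree"))
  if (!is.numeric(cut_fraction) || length(cut_fraction) != 1L ||
      cut_fraction <= 0 || cut_fraction > 1) {
    stop("cut_fraction must lie in (0, 1]", call. = FALSE)
  }
  hc <- tree$hclust
  n <- length(hc$labels)
  h <- cut_fraction * tree$max_height
  apply_merge <- if (cut_fraction == 1) rep(TRUE, n - 1L) else hc$height < h

  # union-find over leaves, applying the surviving merges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_of_merge <- integer(n - 1L)  # representative leaf after merge i
  for (i in seq_len(n - 1L)) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    ra <- if (a < 0) find(-a) else find(cluster_of_merge[a])
    rb <- if (b < 0) find(-b) else find(cluster_of_merge[b])
    if (apply_merge[i]) parent[max(ra, rb)] <- min(ra, rb)
    cluster_of_merge[i] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- hc$labels
  # id modules by lexicographic order of their first member label
  reps <- unique(roots)
  first_label <- vapply(reps, function(r) min(labels[roots == r]), character(1))
  ids <- stats::setNames(order(order(first_label, method = "radix")), reps)
  assignment <- stats::setNames(as.character(ids[as.character(roots)]), labels)
  # restore the region-set order
  assignment <- assignment[intersect(tree$regions, labels)]
  module_partition(assignment)
}

#' Count isolate modules
#'
#' An isolate is a module containing a single region (a leaf not merged
#' below the dendrogram cut).
#'
#' @param p A [module_partition()].
#' @return Integer count of size-1 modules.
#' @examples
#' count_isolates(module_partition(c(A = 1, B = 1, C = 2)))
#' @export
count_isolates <- function(p) {
  stopifnot(inherits(p, "module_partition"))
  sum(p$module_sizes == 1L)
}

#' Write a module partition as delimited text
#'
#' @param p A [module_partition()].
#' @param path Output path; columns `region`, `module_id`.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "module_partition"))
  df <- data.frame(region = names(p$assignment),
                   module_id = unname(p$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
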