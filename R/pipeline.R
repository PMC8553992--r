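#' Pipeline configuration
#'
#' Holds every tunable parameter of the end-to-end analysis. The defaults
#' reproduce the canonical analysis settings: edge threshold `|R| > 0.5`,
#' dendrogram cut at half the tree height, complete linkage, `alpha =
#' 0.05`, at least 5 complete pairs per correlation.
#'
#' @param input_path Long-format density table (tab-delimited text with
#'   columns `subject_id`, `condition`, `region`, `density`).
#' @param output_dir Directory for all artifacts (created if absent).
#' @param edge_threshold Absolute-correlation edge cutoff; default 0.5.
#' @param cut_fraction Dendrogram cut as a fraction of tree height;
#'   default 0.5.
#' @param linkage_method Linkage for [hierarchical_cluster()]; default
#'   `"complete"`.
#' @param alpha Significance level for the region screen; default 0.05.
#' @param min_pairs Minimum complete pairs per correlation; default 5.
#' @param seed Integer seed recorded in provenance (the analysis itself is
#'   deterministic; the seed drives synthetic input generation).
#' @param export_formats Graph formats to write; subset of
#'   `c("graphml", "gexf", "edgelist")`.
#' @param raster Also write heat map rasters; default `FALSE`.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_path, output_dir,
                            edge_threshold = 0.5, cut_fraction = 0.5,
                            linkage_method = "complete", alpha = 0.05,
                            min_pairs = 5L, seed = 1L,
                            export_formats = c("graphml", "gexf"),
                            raster = FALSE) {
  stopifnot(is.character(input_path), length(input_path) == 1L,
            is.character(output_dir), length(output_dir) == 1L)
  bad <- setdiff(export_formats, c("graphml", "gexf", "edgelist"))
  if (length(bad)) {
    stop("unknown export format(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(input_path = input_path, output_dir = output_dir,
                 edge_threshold = edge_threshold,
                 cut_fraction = cut_fraction,
                 linkage_method = linkage_method, alpha = alpha,
                 min_pairs = as.integer(min_pairs), seed = as.integer(seed),
                 export_formats = export_formats, raster = isTRUE(raster)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' CLI flags and function arguments in `...` override file values.
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @param ... Overrides.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Validate a long-format density file
#'
#' Checks the canonical input schema: required columns present, densities
#' numeric and non-missing, no duplicated (subject, condition, region)
#' triples. Returns one finding per violation with its location; an empty
#' data frame means the file is valid.
#'
#' @param path Input file path.
#' @return Data frame with columns `row`, `column`, `message` (0 rows if
#'   valid).
#' @export
validate_input <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  finding <- function(row, column, message) {
    data.frame(row = row, column = column, message = message,
               stringsAsFactors = FALSE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  findings <- list()
  required <- c("subject_id", "condition", "region", "density")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    return(finding(0L, paste(missing, collapse = ","),
                   paste("missing required column(s):",
                         paste(missing, collapse = ", "))))
  }
  dens <- suppressWarnings(as.numeric(raw$density))
  bad <- which(is.na(dens))
  for (r in bad) {
    findings[[length(findings) + 1L]] <-
      finding(r, "density",
              sprintf("non-numeric or missing density '%s'", raw$density[r]))
  }
  key <- paste(raw$subject_id, raw$condition, raw$region, sep = "\r")
  dup <- which(duplicated(key))
  for (r in dup) {
    findings[[length(findings) + 1L]] <-
      finding(r, "subject_id,condition,region",
              sprintf("duplicated triple (%s, %s, %s)",
                      raw$subject_id[r], raw$condition[r], raw$region[r]))
  }
  neg <- which(!is.na(dens) & dens < 0)
  for (r in neg) {
    findings[[length(findings) + 1L]] <-
      finding(r, "density", "negative density")
  }
  if (length(findings)) do.call(rbind, findings) else finding(integer(0),
                                                              character(0),
                                                              character(0))
}

#' Run the full c-Fos network pipeline
#'
#' Reads and validates the long-format density table, runs the per-region
#' group screen across conditions, then per condition: Pearson coactivity
#' matrix, correlation-profile distances, hierarchical clustering,
#' half-height dendrogram cut, signed edge thresholding and node metrics.
#' All artifacts are written to `config$output_dir`; the in-memory report
#' is returned. Every output is a pure function of (input bytes, config,
#' seed), so repeated runs are byte-identical.
#'
#' Artifacts per condition `<c>`: `correlation_<c>.tsv` (and `.png` when
#' `raster`), `linkage_<c>.tsv`, `partition_<c>.tsv`, `edges_<c>.tsv`,
#' `node_metrics_<c>.tsv`, `graph_<c>.graphml` / `.gexf`. Study-level:
#' `region_screen.tsv` and `manifest.json` (config, seed, package version,
#' input checksum).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"network_report"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  findings <- validate_input(config$input_path)
  if (nrow(findings)) {
    stop("input failed validation (", nrow(findings), " finding(s)); first: ",
         findings$message[1], " at row ", findings$row[1], call. = FALSE)
  }
  long <- read_density_long(config$input_path)
  study <- study_from_long(long)

  empty <- vapply(study$tables, function(t) nrow(t) == 0L, logical(1))
  if (any(empty)) {
    warning("skipping empty condition(s): ",
            paste(names(study$tables)[empty], collapse = ", "), call. = FALSE)
    study$tables <- study$tables[!empty]
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, sprintf(...))

  screen <- screen_regions(study, alpha = config$alpha)
  utils::write.table(screen, out("region_screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  conditions <- lapply(names(study$tables), function(cond) {
    tab <- study$tables[[cond]]
    cm <- correlation_matrix(tab, min_pairs = config$min_pairs)
    heatmap_export(cm, out("correlation_%s.tsv", cond),
                   raster = config$raster)
    dm <- correlation_distance(cm)
    tree <- hierarchical_cluster(dm, linkage_method = config$linkage_method)
    utils::write.table(linkage_table(tree), out("linkage_%s.tsv", cond),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    part <- cut_dendrogram(tree, cut_fraction = config$cut_fraction)
    write_partition(part, out("partition_%s.tsv", cond))
    graph <- threshold_edges(cm, threshold = config$edge_threshold)
    metrics <- node_metrics_table(graph, part)
    utils::write.table(metrics, out("node_metrics_%s.tsv", cond),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    utils::write.table(graph$edges, out("edges_%s.tsv", cond), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    for (fmt in config$export_formats) {
      ext <- if (fmt == "edgelist") "edges.txt" else fmt
      export_graph(graph, metrics, out("graph_%s.%s", cond, ext),
                   format = fmt)
    }
    list(condition = cond, correlation = cm, tree = tree, partition = part,
         graph = graph, metrics = metrics, n_isolates = count_isolates(part))
  })
  names(conditions) <- names(study$tables)

  manifest <- list(
    package = "fosnet",
    version = as.character(utils::packageVersion("fosnet")),
    config = config[c("edge_threshold", "cut_fraction", "linkage_method",
                      "alpha", "min_pairs", "export_formats", "raster")],
    seed = config$seed,
    input = basename(config$input_path),
    input_md5 = unname(tools::md5sum(config$input_path)),
    conditions = names(conditions),
    n_regions = length(study$regions))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(screen = screen, conditions = conditions,
                 config = config, manifest = manifest),
            class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("c-Fos network pipeline report\n")
  cat(sprintf("  %d condition(s), %d region(s) screened (%d significant at alpha = %g)\n",
              length(x$conditions), nrow(x$screen), sum(x$screen$significant),
              x$config$alpha))
  for (cond in names(x$conditions)) {
    cc <- x$conditions[[cond]]
    cat(sprintf("  %s: %d modules (%d isolates), %d edges\n", cond,
                cc$partition$n_modules, cc$n_isolates, nrow(cc$graph$edges)))
  }
  invisible(x)
}
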