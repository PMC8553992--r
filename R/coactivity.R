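#' Interregional Pearson correlation matrix
#'
#' Computes, for one condition, the Pearson correlation of c-Fos densities
#' between every pair of regions across subjects, pairwise-complete: each
#' pair uses the subjects observed for both regions. Pairs with fewer than
#' `min_pairs` complete observations are set to `NA` (the missing-pair
#' sentinel, excluded from downstream edges). Regions with zero variance
#' across subjects have undefined correlations and are dropped with a
#' warning.
#'
#' @param table A `"density_table"` (subjects x regions).
#' @param min_pairs Minimum complete subject pairs required per region
#'   pair; default 5.
#' @return Object of class `"correlation_matrix"`: list with `condition`,
#'   `regions`, `R` (symmetric, unit diagonal, `NA` for missing pairs) and
#'   `n_used` (pairwise subject counts).
#' @examples
#' tab <- generate_condition(
#'   condition_spec("c", 9, c(A = 500, B = 500, C = 500),
#'                  c(A = 100, B = 100, C = 100),
#'                  c(A = 1, B = 1, C = 2), 0.8), seed = 7)
#' correlation_matrix(tab)
#' @export
correlation_matrix <- function(table, min_pairs = 5L) {
  stopifnot(inherits(table, "density_table") || is.matrix(table))
  x <- unclass(table)
  condition <- attr(table, "condition")
  if (is.null(condition)) condition <- "unknown"

  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  degenerate <- !is.na(sds) & sds == 0
  if (any(degenerate)) {
    warning("dropping zero-variance region(s): ",
            paste(colnames(x)[degenerate], collapse = ", "), call. = FALSE)
    x <- x[, !degenerate, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 usable regions", call. = FALSE)

  R <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = "pearson"))
  n_used <- crossprod(!is.na(x))
  storage.mode(n_used) <- "integer"
  low <- n_used < min_pairs
  diag(low) <- FALSE
  if (any(low)) {
    message(sprintf("%d region pair(s) below min_pairs = %d set to missing",
                    sum(low) / 2, min_pairs))
    R[low] <- NA_real_
  }
  diag(R) <- 1
  structure(list(condition = condition,
                 regions = region_set(colnames(x)),
                 R = R, n_used = n_used, min_pairs = as.integer(min_pairs)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Interregional Pearson correlation matrix, condition '%s' (%d regions)\n",
              x$condition, length(x$regions)))
  print(round(x$R, 2))
  invisible(x)
}

#' Export a correlation matrix as text and heat map
#'
#' Writes the matrix as tab-delimited text (region labels as header row and
#' first column, full precision) and, optionally, as a raster heat map with
#' a color scale symmetric about 0 (so R = 0 maps to the neutral midpoint
#' regardless of the observed range).
#'
#' @param cm A [correlation_matrix()].
#' @param path Output path for the text matrix; the raster file takes the
#'   same path with its extension replaced by `.png`.
#' @param raster Also write the heat map raster; default `TRUE`.
#' @return Invisibly, the path(s) written.
#' @export
heatmap_export <- function(cm, path, raster = TRUE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  df <- data.frame(region = rownames(cm$R), cm$R, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  paths <- path
  if (raster) {
    png_path <- sub("\\.[^.]*$", "", path)
    png_path <- paste0(png_path, ".png")
    breaks <- seq(-1, 1, length.out = 101)
    colors <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
    pheatmap::pheatmap(cm$R, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = breaks, color = colors, na_col = "#BBBBBB",
                       main = cm$condition, filename = png_path,
                       width = 6, height = 5.5)
    paths <- c(paths, png_path)
  }
  invisible(paths)
}

#' Read back a correlation matrix written by [heatmap_export()]
#'
#' @param path Text matrix path.
#' @param condition Condition name to attach (default from file name).
#' @return A `"correlation_matrix"` (without pairwise counts).
#' @export
read_correlation_matrix <- function(path, condition = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  R <- as.matrix(df[, -1, drop = FALSE])
  rownames(R) <- df$region
  if (is.null(condition)) {
    condition <- sub("\\.[^.]*$", "", basename(path))
  }
  structure(list(condition = condition, regions = region_set(rownames(R)),
                 R = R, n_used = NULL, min_pairs = NA_integer_),
            class = "correlation_matrix")
}
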