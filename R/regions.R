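#' Create a region set
#'
#' A region set is an ordered vector of unique region labels. The order is
#' fixed at construction and defines the row/column order of every matrix
#' built downstream (density tables, correlation matrices, distance
#' matrices).
#'
#' @param names Character vector of region labels.
#' @return A character vector of class `"region_set"`.
#' @examples
#' region_set(c("mPOA", "LS", "VTA"))
#' @export
region_set <- function(names) {
  names <- as.character(names)
  if (length(names) == 0L) {
    stop("a region set needs at least one region", call. = FALSE)
  }
  if (anyNA(names) || any(!nzchar(names))) {
    stop("region labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    dup <- unique(names[duplicated(names)])
    stop("duplicated region labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(names, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set with", length(x), "regions:\n")
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' The thirteen regions of the social decision-making network
#'
#' Returns the canonical region set used throughout rodent social
#' decision-making network (SDMN) studies: the seven social behavioral
#' network regions plus the mesolimbic reward system regions, thirteen in
#' total. Labels are the standard anatomical abbreviations.
#'
#' @return A [region_set] of 13 region abbreviations.
#' @examples
#' sdmn_regions()
#' @export
sdmn_regions <- function() {
  region_set(c("AH", "BLA", "BNST", "HIP", "LS", "MeA", "mPOA",
               "NAcc", "PAG", "CP", "VMH", "VP", "VTA"))
}
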