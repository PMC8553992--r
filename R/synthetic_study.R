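#' Specify one synthetic study condition
#'
#' A condition specification describes the multivariate normal distribution
#' from which per-subject regional densities are drawn: per-region means and
#' standard deviations (cells/mm^3) plus a planted block-correlation
#' structure defined by a module partition, a shared within-module
#' correlation, and between-module correlations.
#'
#' The implied correlation matrix is validated for positive
#' semi-definiteness at construction. A minimum eigenvalue in
#' `[-1e-10, 0)` is treated as numerical noise and repaired by adding
#' `1e-10` to the diagonal; anything more negative is rejected, reporting
#' the offending eigenvalue.
#'
#' @param condition Condition name (string).
#' @param n_subjects Number of subjects (positive integer).
#' @param region_means Named numeric vector, region -> mean density (> 0).
#' @param region_sds Named numeric vector, region -> density sd (> 0).
#' @param partition Named vector, region -> planted module id.
#' @param rho_within Correlation applied to region pairs sharing a module.
#' @param rho_between Correlation for pairs in different modules: a single
#'   number applied to all between-module pairs (default 0), or a symmetric
#'   numeric matrix with the module ids as dimnames.
#' @return An object of class `"condition_spec"`.
#' @seealso [generate_condition()], [generate_study()]
#' @examples
#' means <- c(A = 500, B = 500, C = 500)
#' sds <- c(A = 100, B = 100, C = 100)
#' part <- c(A = 1, B = 1, C = 2)
#' condition_spec("control", 8, means, sds, part, rho_within = 0.8)
#' @export
condition_spec <- function(condition, n_subjects, region_means, region_sds,
                           partition, rho_within, rho_between = 0) {
  stopifnot(is.character(condition), length(condition) == 1L, nzchar(condition))
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    stop("n_subjects must be a positive integer", call. = FALSE)
  }
  regions <- region_set(names(region_means))
  if (!all(region_means > 0)) {
    stop("all region means must be > 0 (densities)", call. = FALSE)
  }
  missing_sd <- setdiff(regions, names(region_sds))
  if (length(missing_sd)) {
    stop("regions missing from region_sds: ",
         paste(missing_sd, collapse = ", "), call. = FALSE)
  }
  if (!all(region_sds[regions] > 0)) {
    stop("all region sds must be > 0", call. = FALSE)
  }
  missing_mod <- setdiff(regions, names(partition))
  if (length(missing_mod)) {
    stop("regions missing from partition: ",
         paste(missing_mod, collapse = ", "), call. = FALSE)
  }
  if (abs(rho_within) > 1) stop("rho_within must lie in [-1, 1]", call. = FALSE)

  spec <- structure(
    list(condition = condition,
         n_subjects = n_subjects,
         region_means = region_means[regions],
         region_sds = region_sds[regions],
         partition = partition[regions],
         rho_within = rho_within,
         rho_between = rho_between),
    class = "condition_spec")
  # validates PSD as a construction invariant
  spec$R <- planted_correlation(spec)
  spec
}

#' Planted correlation matrix of a condition specification
#'
#' Expands the block description (partition, `rho_within`, `rho_between`)
#' into the full region-by-region correlation matrix and validates positive
#' semi-definiteness.
#'
#' @param spec A [condition_spec()].
#' @return Symmetric correlation matrix with region dimnames.
#' @export
planted_correlation <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  regions <- names(spec$region_means)
  p <- length(regions)
  part <- spec$partition
  mods <- unique(part)
  rb <- spec$rho_between

  R <- matrix(NA_real_, p, p, dimnames = list(regions, regions))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) {
        R[i, j] <- 1
      } else if (part[i] == part[j]) {
        R[i, j] <- spec$rho_within
      } else if (is.matrix(rb)) {
        R[i, j] <- rb[as.character(part[i]), as.character(part[j])]
      } else {
        R[i, j] <- rb
      }
    }
  }
  if (any(abs(R) > 1)) stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (!isSymmetric(unname(R))) {
    stop("rho_between matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(ev)
  if (min_ev < -1e-10) {
    stop(sprintf(
      "planted correlation matrix is not positive semi-definite (minimum eigenvalue %.6g)",
      min_ev), call. = FALSE)
  }
  if (min_ev < 0) diag(R) <- diag(R) + 1e-10
  R
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("Condition spec '%s': %d subjects, %d regions, %d planted modules\n",
              x$condition, x$n_subjects, length(x$region_means),
              length(unique(x$partition))))
  cat(sprintf("  rho_within = %g, rho_between = %s\n", x$rho_within,
              if (is.matrix(x$rho_between)) "<matrix>" else format(x$rho_between)))
  invisible(x)
}

# Deterministic per-condition substream: a polynomial rolling hash of the
# condition name offsets the master seed, so adding or renaming one
# condition never perturbs the draws of another.
condition_seed <- function(master_seed, condition) {
  h <- 0
  for (code in utf8ToInt(condition)) h <- (h * 31 + code) %% 2147480009
  as.integer((as.numeric(master_seed) + h) %% 2147483647)
}

#' Draw one condition's density table
#'
#' Samples an `n_subjects` x `regions` table of c-Fos densities from a
#' multivariate normal with the spec's planted correlation structure,
#' scaled to `region_sds` and shifted to `region_means`. Negative draws are
#' clipped to 0 (recorded in the `n_clipped` attribute, with a warning);
#' clipping is negligible by construction when means sit >= 4 sd above
#' zero. Bit-identical for identical `(spec, seed)`.
#'
#' @param spec A [condition_spec()].
#' @param seed Integer seed for this condition's draw.
#' @return A `"density_table"`: numeric matrix (subjects x regions) with
#'   attributes `condition` and `n_clipped`.
#' @examples
#' means <- c(A = 500, B = 500); sds <- c(A = 100, B = 100)
#' sp <- condition_spec("ctrl", 5, means, sds, c(A = 1, B = 1), 0.7)
#' generate_condition(sp, seed = 1)
#' @export
generate_condition <- function(spec, seed) {
  stopifnot(inherits(spec, "condition_spec"))
  regions <- names(spec$region_means)
  n <- spec$n_subjects
  p <- length(regions)
  L <- chol(spec$R)
  Z <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(n * p), nrow = n, ncol = p))
  X <- Z %*% L
  X <- sweep(X, 2L, spec$region_sds, "*")
  X <- sweep(X, 2L, spec$region_means, "+")
  n_clipped <- sum(X < 0)
  if (n_clipped > 0) {
    warning(sprintf("clipped %d negative density value(s) to 0 in condition '%s'",
                    n_clipped, spec$condition), call. = FALSE)
    X[X < 0] <- 0
  }
  dimnames(X) <- list(sprintf("%s_s%02d", spec$condition, seq_len(n)), regions)
  density_table(X, condition = spec$condition, n_clipped = n_clipped)
}

#' Construct a density table
#'
#' @param x Numeric matrix, subjects in rows, regions in columns (named).
#' @param condition Condition name.
#' @param n_clipped Count of zero-clipped cells (bookkeeping).
#' @return Object of class `"density_table"`.
#' @export
density_table <- function(x, condition, n_clipped = 0L) {
  stopifnot(is.matrix(x), is.numeric(x), !is.null(colnames(x)))
  region_set(colnames(x))
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("%s_s%02d", condition, seq_len(nrow(x)))
  }
  structure(x, condition = condition, n_clipped = as.integer(n_clipped),
            class = c("density_table", "matrix", "array"))
}

#' @export
print.density_table <- function(x, ...) {
  cat(sprintf("Density table, condition '%s': %d subjects x %d regions (cells/mm^3)\n",
              attr(x, "condition"), nrow(x), ncol(x)))
  print(round(unclass(x), 1), ...)
  invisible(x)
}

#' Generate a multi-condition synthetic study
#'
#' Draws one density table per condition specification. Each condition uses
#' an independent RNG substream derived deterministically from the master
#' seed and the condition name. Planted module partitions are kept as
#' ground truth.
#'
#' @param specs List of [condition_spec()] objects sharing one region set.
#' @param seed Master integer seed.
#' @return A `"study_dataset"`: list with elements `tables` (named list of
#'   density tables), `regions`, `truth` (named list of planted
#'   [module_partition] objects), `seed`.
#' @examples
#' means <- c(A = 500, B = 500); sds <- c(A = 100, B = 100)
#' s1 <- condition_spec("ctrl", 5, means, sds, c(A = 1, B = 1), 0.7)
#' s2 <- condition_spec("treat", 6, means, sds, c(A = 1, B = 2), 0.7)
#' generate_study(list(s1, s2), seed = 42)
#' @export
generate_study <- function(specs, seed) {
  if (length(specs) == 0L) stop("empty condition spec list", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, logical(1), "condition_spec")))
  cond_names <- vapply(specs, `[[`, character(1), "condition")
  if (anyDuplicated(cond_names)) {
    stop("duplicate condition names: ",
         paste(unique(cond_names[duplicated(cond_names)]), collapse = ", "),
         call. = FALSE)
  }
  region_sets <- lapply(specs, function(s) names(s$region_means))
  if (!all(vapply(region_sets, identical, logical(1), region_sets[[1]]))) {
    stop("all condition specs must share one region set", call. = FALSE)
  }
  tables <- lapply(specs, function(s) {
    generate_condition(s, condition_seed(seed, s$condition))
  })
  names(tables) <- cond_names
  truth <- lapply(specs, function(s) module_partition(s$partition))
  names(truth) <- cond_names
  structure(list(tables = tables,
                 regions = region_set(region_sets[[1]]),
                 truth = truth,
                 seed = as.integer(seed)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  ns <- vapply(x$tables, nrow, integer(1))
  cat(sprintf("Study dataset: %d conditions, %d regions, seed %d\n",
              length(x$tables), length(x$regions), x$seed))
  cat("  subjects per condition:",
      paste(sprintf("%s=%d", names(ns), ns), collapse = ", "), "\n")
  invisible(x)
}

#' Default synthetic SDMN study
#'
#' A canned four-condition study over the 13-region social decision-making
#' network, emulating the structure of a vole resident-exposure experiment:
#' a non-stimulated control, a partner re-exposure, an opposite-sex
#' stranger and a same-sex stranger, with 7/9/9/9 subjects.
#'
#' Eight of the thirteen regions (VP, LS, BNST, mPOA, AH, MeA, VMH, VTA)
#' carry socially evoked mean elevations, distributed stimulus-specifically:
#' the partner condition elevates VP/LS/BNST/mPOA/VMH, the opposite-sex
#' stranger elevates mPOA/VMH, and the same-sex stranger elevates all
#' eight. Baseline density is 500 +/- 100 cells/mm^3; elevated regions sit
#' at 900 +/- 150 (means >= 4 sd above zero, so zero-clipping is
#' negligible). Planted coactivity is condition-specific: broadly positive
#' coupling with 3 modules in control, a strongly coupled
#' social-behavioral-network block among 5 modules under partner exposure,
#' fragmentation into 8 modules (4 singletons) with negative cross-block
#' correlation under opposite-sex exposure, and 5 modules with the
#' strongest negative cross-block coupling under same-sex exposure.
#'
#' @param seed Master integer seed.
#' @return A `"study_dataset"`; see [generate_study()].
#' @examples
#' study <- simulate_sdmn_study(seed = 1)
#' study
#' @export
simulate_sdmn_study <- function(seed) {
  regions <- sdmn_regions()
  baseline <- stats::setNames(rep(500, length(regions)), regions)
  sds_base <- stats::setNames(rep(100, length(regions)), regions)

  elevate <- function(regions_up) {
    means <- baseline; sds <- sds_base
    means[regions_up] <- 900
    sds[regions_up] <- 150
    list(means = means, sds = sds)
  }
  part_of <- function(blocks) {
    out <- integer(0)
    for (i in seq_along(blocks)) {
      out <- c(out, stats::setNames(rep(i, length(blocks[[i]])), blocks[[i]]))
    }
    out[regions]
  }

  ctrl <- elevate(character(0))
  ctrl_part <- part_of(list(c("AH", "BNST", "LS", "mPOA", "VMH"),
                            c("BLA", "HIP", "MeA", "PAG"),
                            c("CP", "NAcc", "VP", "VTA")))
  partner <- elevate(c("VP", "LS", "BNST", "mPOA", "VMH"))
  partner_part <- part_of(list(c("AH", "LS", "mPOA", "VP"),
                               c("BLA", "NAcc", "VTA", "CP"),
                               c("MeA", "PAG"),
                               c("VMH", "BNST"),
                               "HIP"))
  opp <- elevate(c("mPOA", "VMH"))
  opp_part <- part_of(list(c("mPOA", "VMH", "AH"),
                           c("LS", "BNST"),
                           c("NAcc", "VP"),
                           c("MeA", "PAG"),
                           "BLA", "HIP", "CP", "VTA"))
  same <- elevate(c("VP", "LS", "BNST", "mPOA", "AH", "MeA", "VMH", "VTA"))
  same_part <- part_of(list(c("BNST", "MeA", "VMH", "AH"),
                            c("mPOA", "VP", "LS", "VTA"),
                            c("NAcc", "CP"),
                            c("BLA", "PAG"),
                            "HIP"))

  specs <- list(
    condition_spec("control", 7, ctrl$means, ctrl$sds, ctrl_part,
                   rho_within = 0.6, rho_between = 0.25),
    condition_spec("partner", 9, partner$means, partner$sds, partner_part,
                   rho_within = 0.75, rho_between = 0.2),
    condition_spec("opposite_sex_stranger", 9, opp$means, opp$sds, opp_part,
                   rho_within = 0.7, rho_between = -0.1),
    condition_spec("same_sex_stranger", 9, same$means, same$sds, same_part,
                   rho_within = 0.7, rho_between = -0.2))
  generate_study(specs, seed)
}

#' Write / read the canonical long-format density table
#'
#' The pipeline's canonical input is long-format tab-delimited text with a
#' header row and columns `subject_id`, `condition`, `region`, `density`
#' (cells/mm^3), UTF-8 encoded.
#'
#' @param study A `"study_dataset"` (or named list of density tables).
#' @param path Output file path.
#' @return `write_density_long()` returns `path` invisibly;
#'   `read_density_long()` returns the long-format data frame.
#' @export
write_density_long <- function(study, path) {
  tables <- if (inherits(study, "study_dataset")) study$tables else study
  rows <- lapply(names(tables), function(cond) {
    tab <- tables[[cond]]
    data.frame(subject_id = rep(rownames(tab), times = ncol(tab)),
               condition = cond,
               region = rep(colnames(tab), each = nrow(tab)),
               density = as.vector(unclass(tab)),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_density_long
#' @export
read_density_long <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  required <- c("subject_id", "condition", "region", "density")
  missing <- setdiff(required, names(long))
  if (length(missing)) {
    stop("input is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  long
}

#' Assemble per-condition density tables from long-format data
#'
#' @param long Long-format data frame with columns `subject_id`,
#'   `condition`, `region`, `density`.
#' @return A `"study_dataset"` without ground-truth partitions.
#' @export
study_from_long <- function(long) {
  required <- c("subject_id", "condition", "region", "density")
  missing <- setdiff(required, names(long))
  if (length(missing)) {
    stop("long data missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  regions <- region_set(unique(long$region))
  conds <- unique(long$condition)
  tables <- lapply(conds, function(cond) {
    sub <- long[long$condition == cond, , drop = FALSE]
    subjects <- unique(sub$subject_id)
    m <- matrix(NA_real_, length(subjects), length(regions),
                dimnames = list(subjects, regions))
    idx <- cbind(match(sub$subject_id, subjects), match(sub$region, regions))
    m[idx] <- sub$density
    density_table(m, condition = cond)
  })
  names(tables) <- conds
  structure(list(tables = tables, regions = regions, truth = NULL,
                 seed = NA_integer_),
            class = "study_dataset")
}

#' Write planted ground-truth partitions
#'
#' Tab-delimited text with columns `region`, `module_id`, `condition`.
#'
#' @param study A `"study_dataset"` carrying `truth` partitions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_partitions <- function(study, path) {
  stopifnot(inherits(study, "study_dataset"))
  if (is.null(study$truth)) stop("study has no ground-truth partitions", call. = FALSE)
  rows <- lapply(names(study$truth), function(cond) {
    asg <- study$truth[[cond]]$assignment
    data.frame(region = names(asg), module_id = unname(asg), condition = cond,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
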