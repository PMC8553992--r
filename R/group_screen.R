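#' Bundle grouped observations of one outcome
#'
#' @param outcome_name Name of the measured outcome (e.g. a region's c-Fos
#'   density in cells/mm^3, or a behavioral duration in seconds).
#' @param groups Named list, group label -> numeric vector of observations.
#'   At least two groups, each with at least two values.
#' @return Object of class `"group_samples"`.
#' @examples
#' group_samples("mPOA", list(control = c(1, 2, 3), partner = c(4, 5, 6)))
#' @export
group_samples <- function(outcome_name, groups) {
  stopifnot(is.character(outcome_name), length(outcome_name) == 1L)
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list of numeric vectors", call. = FALSE)
  }
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values; too small: ",
         paste(names(groups)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  if (any(!vapply(groups, is.numeric, logical(1)))) {
    stop("all groups must be numeric", call. = FALSE)
  }
  structure(list(outcome_name = outcome_name, groups = groups),
            class = "group_samples")
}

#' One-way between-subjects ANOVA
#'
#' Classical fixed-effects one-way ANOVA: F = MS_between / MS_within with
#' `df = (k - 1, N - k)`, p from the F distribution. When all observations
#' are identical across groups the test is degenerate and reports `F = 0,
#' p = 1`. The fit keeps `ms_within` and the group sizes because the SNK
#' post hoc test reuses them.
#'
#' @param samples A [group_samples()] object (or a bare named list).
#' @return Object of class `"anova_fit"`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `group_n`, `ms_within`.
#' @examples
#' one_way_anova(group_samples("y", list(A = c(1, 2), B = c(3, 4))))
#' @export
one_way_anova <- function(samples) {
  if (!inherits(samples, "group_samples")) {
    samples <- group_samples("outcome", samples)
  }
  g <- samples$groups
  if (anyNA(unlist(g))) stop("NA values in group samples", call. = FALSE)
  k <- length(g)
  ns <- vapply(g, length, integer(1))
  N <- sum(ns)
  means <- vapply(g, mean, numeric(1))
  grand <- sum(unlist(g)) / N

  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df_between <- k - 1L
  df_within <- N - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within

  if (ms_within == 0 && ms_between == 0) {       # all values identical
    f_stat <- 0; p <- 1
  } else if (ms_within == 0) {                   # separated groups, no noise
    f_stat <- Inf; p <- 0
  } else {
    f_stat <- ms_between / ms_within
    p <- stats::pf(f_stat, df_between, df_within, lower.tail = FALSE)
  }
  structure(list(F = f_stat, df_between = df_between, df_within = df_within,
                 p = p, group_means = means, group_n = ns,
                 ms_within = ms_within, outcome_name = samples$outcome_name),
            class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("One-way ANOVA on '%s': F(%d, %d) = %.4g, p = %.4g\n",
              x$outcome_name, x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Student-Newman-Keuls step-down post hoc test
#'
#' Orders the group means and tests each pair with the Studentized range
#' statistic `q = |mean_a - mean_b| / sqrt(MS_within / n_h)`, where `n_h`
#' is the harmonic mean of the two group sizes, against the critical value
#' at the span `r` (the number of ordered means the pair encloses) and the
#' within-group degrees of freedom. The step-down blocking rule is applied:
#' once a span is declared non-significant, every pair nested inside it is
#' forced non-significant regardless of its own statistic.
#'
#' If `MS_within = 0` the range statistic is undefined; by convention every
#' pair with unequal means is reported significant and the result is
#' flagged (`zero_variance` attribute).
#'
#' @param samples A [group_samples()] object.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A data frame of class `"snk_posthoc"`, one row per unordered
#'   pair: `group_a`, `group_b`, `mean_diff`, `q_statistic`, `span_r`,
#'   `p`, `significant`, `blocked`. Group means are kept in the
#'   `group_means` attribute (used by [compact_letter_display()]).
#' @examples
#' set.seed(1)
#' g <- group_samples("y", list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 4)))
#' snk_posthoc(g)
#' @export
snk_posthoc <- function(samples, alpha = 0.05) {
  if (!inherits(samples, "group_samples")) {
    samples <- group_samples("outcome", samples)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  fit <- one_way_anova(samples)
  means <- sort(fit$group_means)     # ascending; ties keep name order
  labels <- names(means)
  ns <- fit$group_n[labels]
  k <- length(means)
  dfw <- fit$df_within
  msw <- fit$ms_within
  zero_var <- msw == 0

  # step-down sweep over decreasing spans: a pair may reject only if every
  # containing span rejected; otherwise it is blocked (forced NS)
  sig <- matrix(NA, k, k)
  q_mat <- matrix(NA_real_, k, k)
  p_mat <- matrix(NA_real_, k, k)
  blocked <- matrix(FALSE, k, k)

  for (r in seq(k, 2L)) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      n_h <- 2 / (1 / ns[i] + 1 / ns[j])
      diff <- abs(means[j] - means[i])
      if (zero_var) {
        q <- if (diff > 0) Inf else 0
        p <- if (diff > 0) 0 else 1
      } else {
        q <- diff / sqrt(msw / n_h)
        p <- stats::ptukey(q, nmeans = r, df = dfw, lower.tail = FALSE)
      }
      q_mat[i, j] <- q
      p_mat[i, j] <- p
      # immediate containing spans suffice (blocking propagates downward)
      contained_ok <- r == k ||
        all(c(if (i > 1L) sig[i - 1L, j], if (j < k) sig[i, j + 1L]))
      blocked[i, j] <- !contained_ok
      sig[i, j] <- contained_ok && p < alpha
    }
  }
  pairs <- which(upper.tri(sig), arr.ind = TRUE)
  out <- data.frame(
    group_a = labels[pairs[, 1]],
    group_b = labels[pairs[, 2]],
    mean_diff = means[pairs[, 2]] - means[pairs[, 1]],
    q_statistic = q_mat[pairs],
    span_r = pairs[, 2] - pairs[, 1] + 1L,
    p = p_mat[pairs],
    significant = sig[pairs],
    blocked = blocked[pairs],
    stringsAsFactors = FALSE)
  out <- out[order(out$span_r, out$group_a, decreasing = c(TRUE, FALSE),
                   method = "radix"), ]
  rownames(out) <- NULL
  structure(out, class = c("snk_posthoc", "data.frame"),
            group_means = fit$group_means, alpha = alpha,
            zero_variance = zero_var)
}

#' Compact letter display for a set of pairwise comparisons
#'
#' Encodes a pairwise significance relation as letters: two groups share at
#' least one letter if and only if they do not differ significantly. Uses
#' the insert-and-absorb algorithm: start from one class holding every
#' group; for each significant pair split every class containing both, then
#' absorb classes that became subsets of others. Letters are assigned in
#' ascending order of group means, starting at "a".
#'
#' @param comparisons A [snk_posthoc()] result, or any data frame with
#'   columns `group_a`, `group_b`, `significant` covering all pairs.
#' @param group_means Named vector of group means used to order letters;
#'   taken from the `snk_posthoc` attribute when present.
#' @return Named character vector of class `"letter_display"`, group ->
#'   letter string.
#' @examples
#' cmp <- data.frame(group_a = c("A", "A", "B"), group_b = c("B", "C", "C"),
#'                   significant = c(TRUE, FALSE, FALSE))
#' compact_letter_display(cmp, group_means = c(A = 1, C = 2, B = 3))
#' @export
compact_letter_display <- function(comparisons, group_means = NULL) {
  if (is.null(group_means)) group_means <- attr(comparisons, "group_means")
  groups <- unique(c(comparisons$group_a, comparisons$group_b))
  if (is.null(group_means)) {
    group_means <- stats::setNames(seq_along(groups), groups)
  }
  missing <- setdiff(groups, names(group_means))
  if (length(missing)) {
    stop("group_means missing groups: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # expected coverage: all unordered pairs
  if (nrow(comparisons) < choose(length(groups), 2)) {
    stop("comparisons must cover every pair of groups", call. = FALSE)
  }
  groups <- names(sort(group_means[groups]))

  classes <- list(groups)
  sig_rows <- which(comparisons$significant)
  for (r in sig_rows) {
    a <- comparisons$group_a[r]; b <- comparisons$group_b[r]
    hit <- vapply(classes, function(cl) a %in% cl && b %in% cl, logical(1))
    if (!any(hit)) next
    kept <- classes[!hit]
    split <- unlist(lapply(classes[hit], function(cl) {
      list(setdiff(cl, a), setdiff(cl, b))
    }), recursive = FALSE)
    classes <- c(kept, split)
    # absorb classes that are subsets of another class
    drop <- logical(length(classes))
    for (i in seq_along(classes)) {
      for (j in seq_along(classes)) {
        if (i != j && !drop[j] &&
            all(classes[[i]] %in% classes[[j]]) &&
            (length(classes[[i]]) < length(classes[[j]]) || i > j)) {
          drop[i] <- TRUE
          break
        }
      }
    }
    classes <- classes[!drop]
  }
  # order classes by the lowest-mean member they contain
  first_pos <- vapply(classes, function(cl) min(match(cl, groups)), numeric(1))
  classes <- classes[order(first_pos)]
  if (length(classes) > 26L) {
    stop("letter display limited to 26 classes", call. = FALSE)
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(classes)) {
    members <- classes[[i]]
    out[members] <- paste0(out[members], letters[i])
  }
  structure(out, class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  df <- data.frame(group = names(x), letters = unname(unclass(x)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-region group-difference screen
#'
#' Runs, for every region of a study, a one-way ANOVA across conditions
#' followed (when the ANOVA is significant at `alpha`) by the SNK post hoc
#' test and a compact letter display. Regions whose ANOVA is not
#' significant receive the single shared letter `"a"` with no post hoc
#' testing. Regions absent from some condition are skipped with a warning.
#'
#' No multiple-testing correction is applied across regions: each region is
#' screened at `alpha` on its own, so the family-wise error across regions
#' is not controlled (the `uncorrected` attribute flags this caveat).
#'
#' @param study A `"study_dataset"` (or named list of density tables).
#' @param alpha Per-region significance level; default 0.05.
#' @return Data frame of class `"region_screen"`: one row per region with
#'   `region`, `F`, `df1`, `df2`, `p`, `significant`, then one letter
#'   column per condition (`letters_<condition>`).
#' @examples
#' study <- simulate_sdmn_study(seed = 1)
#' screen_regions(study)
#' @export
screen_regions <- function(study, alpha = 0.05) {
  tables <- if (inherits(study, "study_dataset")) study$tables else study
  if (length(tables) < 2L) stop("need at least 2 conditions", call. = FALSE)
  conds <- names(tables)
  all_regions <- unique(unlist(lapply(tables, colnames)))
  shared <- Reduce(intersect, lapply(tables, colnames))
  skipped <- setdiff(all_regions, shared)
  if (length(skipped)) {
    warning("region(s) missing in some condition, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }

  rows <- vector("list", length(shared))
  letter_cols <- paste0("letters_", conds)
  for (i in seq_along(shared)) {
    reg <- shared[i]
    groups <- lapply(tables, function(tab) {
      v <- unclass(tab)[, reg]
      v[!is.na(v)]
    })
    gs <- group_samples(reg, groups)
    fit <- one_way_anova(gs)
    sig <- fit$p < alpha
    if (sig) {
      cld <- compact_letter_display(snk_posthoc(gs, alpha = alpha))
      lets <- unclass(cld)[conds]
    } else {
      lets <- stats::setNames(rep("a", length(conds)), conds)
    }
    row <- data.frame(region = reg, F = fit$F, df1 = fit$df_between,
                      df2 = fit$df_within, p = fit$p, significant = sig,
                      stringsAsFactors = FALSE)
    row[letter_cols] <- as.list(unname(lets))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("region_screen", "data.frame"),
            alpha = alpha, uncorrected = TRUE)
}
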