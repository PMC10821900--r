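#' Pool per-field counts into a per-mouse migration rate
#'
#' The migration rate of a mouse is the pooled ratio
#' `sum(n_mcsc) / sum(n_follicles)` over all its quantified fields —
#' melanocytes per hair follicle. Pooling equals the follicle-count-weighted
#' mean of per-field rates; an unweighted per-field mean is available as an
#' alternative. A mouse whose pooled denominator falls below
#' `min_follicles` (default 6000, the usual per-mouse quantification floor)
#' is flagged, not rejected.
#'
#' @param records data.frame with columns `mouse_id`, `n_follicles`,
#'   `n_mcsc` (one row per field), e.g. from [quantify_dataset()]. Rows with
#'   NA counts (failed fields) are dropped with a flag.
#' @param group,sex optional annotations stored on the result.
#' @param method "pooled" (default) or "mean_of_fields".
#' @param min_follicles flag threshold for the pooled denominator.
#' @return Object of class `MouseMigration`: `mouse_id`, `group`, `sex`,
#'   `total_follicles`, `total_mcsc`, `migration_rate`, `n_fields`, `flags`.
#' @examples
#' rec <- data.frame(mouse_id = "m1", n_follicles = c(320, 320),
#'                   n_mcsc = c(10, 6))
#' aggregate_mouse(rec)$migration_rate  # 16 / 640
#' @export
aggregate_mouse <- function(records, group = NA_character_,
                            sex = NA_character_, method = c("pooled",
                            "mean_of_fields"), min_follicles = 6000) {
  method <- match.arg(method)
  need <- c("mouse_id", "n_follicles", "n_mcsc")
  if (!is.data.frame(records) || !all(need %in% names(records)) ||
      nrow(records) == 0L)
    stop_mcsc("mcsc_validation_error",
              "'records' must be a non-empty data.frame with mouse_id, n_follicles, n_mcsc")
  if (length(unique(records$mouse_id)) != 1L)
    stop_mcsc("mcsc_validation_error",
              "records mix mouse_ids; aggregate one mouse at a time")
  flags <- character(0)
  bad <- is.na(records$n_follicles) | is.na(records$n_mcsc)
  if (any(bad)) {
    flags <- c(flags, sprintf("dropped_failed_fields:%d", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0L || sum(records$n_follicles) == 0)
    stop_mcsc("mcsc_validation_error",
              "zero total follicles; migration rate undefined")
  tf <- sum(records$n_follicles); tm <- sum(records$n_mcsc)
  rate <- if (method == "pooled") tm / tf
          else mean(records$n_mcsc / records$n_follicles)
  if (tf < min_follicles)
    flags <- c(flags, "below_quantification_floor")
  structure(list(
    mouse_id = records$mouse_id[1], group = group, sex = sex,
    total_follicles = tf, total_mcsc = tm,
    migration_rate = rate, n_fields = nrow(records), flags = flags
  ), class = "MouseMigration")
}

#' @export
print.MouseMigration <- function(x, ...) {
  cat(sprintf("MouseMigration [%s]: %d McSCs / %d follicles = %.4f (%d fields)%s\n",
              x$mouse_id, x$total_mcsc, x$total_follicles, x$migration_rate,
              x$n_fields,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]")
              else ""))
  invisible(x)
}

#' Normalize a migration rate by a per-mouse covariate
#'
#' Two schemes used in littermate-paired UVB designs: `"cox2"` divides the
#' raw rate by the mouse's own Cox-2 expression level (by default measured as
#' the Cox-2 immunofluorescence [area_ratio()] on matched sections, but any
#' positive scalar may be supplied), and `"littermate_control"` divides by
#' the migration rate of the matched control littermate in the same
#' experimental group, making the control itself exactly 1.
#'
#' @param raw a `MouseMigration` (or a single numeric raw rate).
#' @param normalizer positive scalar (Cox-2 level or control mouse's rate).
#' @param scheme `"cox2"` or `"littermate_control"`.
#' @return Object of class `NormalizedMigration`: `mouse_id`, `raw_rate`,
#'   `normalizer`, `normalized_rate`, `scheme`.
#' @export
normalize_migration <- function(raw, normalizer,
                                scheme = c("cox2", "littermate_control")) {
  scheme <- match.arg(scheme)
  assert_scalar_num(normalizer, "normalizer", lower = 0, strict_lower = TRUE)
  if (inherits(raw, "MouseMigration")) {
    mouse_id <- raw$mouse_id; raw_rate <- raw$migration_rate
  } else {
    assert_scalar_num(raw, "raw", lower = 0)
    mouse_id <- NA_character_; raw_rate <- raw
  }
  structure(list(
    mouse_id = mouse_id, raw_rate = raw_rate, normalizer = normalizer,
    normalized_rate = raw_rate / normalizer, scheme = scheme
  ), class = "NormalizedMigration")
}

#' Compare two groups of per-mouse values
#'
#' The three tests used for migration-rate and staining comparisons:
#' two-sided Welch t (unequal-variance degrees of freedom), paired t, and
#' Mann-Whitney U (Wilcoxon rank sum; exact p for groups of up to 8 without
#' ties, otherwise normal approximation with continuity and tie correction).
#' Group means and SEMs (sd/sqrt(n)) are reported alongside, matching the
#' SEM error-bar convention.
#'
#' @param a,b numeric vectors of per-mouse values (each n >= 2).
#' @param test `"welch_t"`, `"paired_t"` or `"mann_whitney"`.
#' @param paired_ids optional list with elements `a` and `b` giving matching
#'   identifiers; for `paired_t`, `b` is reordered so its ids align with
#'   `a`'s. Without ids, paired vectors are taken as already aligned.
#' @return Object of class `GroupComparison`: `test`, `statistic`,
#'   `p_value`, `group_means`, `group_sems`, `n`, `flags`. A paired design
#'   with zero variance of the differences (or a Welch comparison of two
#'   constant groups) sets a `degenerate_variance` flag and NA statistic/p
#'   instead of fabricating a p-value.
#' @examples
#' compare_groups(c(0.1, 0.2, 0.15), c(0.3, 0.35, 0.4), "welch_t")$p_value
#' @export
compare_groups <- function(a, b, test = c("welch_t", "paired_t",
                           "mann_whitney"), paired_ids = NULL) {
  test <- match.arg(test)
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stop_mcsc("mcsc_validation_error", "groups must be numeric without NA")
  if (length(a) < 2L || length(b) < 2L)
    stop_mcsc("mcsc_insufficient_data", "each group needs n >= 2")
  if (test == "paired_t") {
    if (length(a) != length(b))
      stop_mcsc("mcsc_validation_error", "paired groups must have equal length")
    if (!is.null(paired_ids)) {
      if (!all(sort(paired_ids$a) == sort(paired_ids$b)))
        stop_mcsc("mcsc_validation_error", "paired ids do not match one-to-one")
      b <- b[match(paired_ids$a, paired_ids$b)]
    }
  }
  flags <- character(0)
  statistic <- NA_real_; p <- NA_real_
  if (test == "welch_t") {
    if (sd(a) == 0 && sd(b) == 0) {
      flags <- "degenerate_variance"
    } else {
      ht <- t.test(a, b, var.equal = FALSE)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  } else if (test == "paired_t") {
    if (sd(a - b) == 0) {
      flags <- "degenerate_variance"
    } else {
      ht <- t.test(a, b, paired = TRUE)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    exact <- length(a) <= 8L && length(b) <= 8L
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    statistic <- unname(ht$statistic); p <- ht$p.value
    if (exact && anyDuplicated(c(a, b))) flags <- "ties_normal_approximation"
  }
  structure(list(
    test = test, statistic = statistic, p_value = p,
    group_means = c(mean(a), mean(b)),
    group_sems = c(sd(a) / sqrt(length(a)), sd(b) / sqrt(length(b))),
    n = c(length(a), length(b)), flags = flags
  ), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison (%s): statistic %.4g, p %.4g; means %.4g vs %.4g (SEM %.3g, %.3g; n %d, %d)\n",
              x$test, x$statistic, x$p_value, x$group_means[1],
              x$group_means[2], x$group_sems[1], x$group_sems[2],
              x$n[1], x$n[2]))
  invisible(x)
}
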