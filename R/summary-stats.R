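# Summary statistics used in family-evolution surveys: Pearson correlation
# of copy number vs genome loci, Student and paired t-tests, and grouped
# Ka/Ks means. Thin, defensively checked wrappers over the base R tests so
# degenerate inputs (zero variance) have defined behavior.

.stat_result <- function(statistic, estimate, p_value, n, df) {
  data.frame(statistic = statistic, estimate = estimate, p_value = p_value,
             n = n, df = df, stringsAsFactors = FALSE)
}

#' Pearson correlation with a two-sided t test
#'
#' @param x,y Equal-length numeric vectors (n >= 3, both with nonzero
#'   variance).
#' @return One-row data.frame: `statistic` (`"pearson_r"`), `estimate`
#'   (r), `p_value` (two-sided, from the t transform with n - 2 df), `n`,
#'   `df`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  .stat_result("pearson_r", unname(ct$estimate), ct$p.value,
               length(x), unname(ct$parameter))
}

#' Two-sample Student t test (equal variances)
#'
#' Classic pooled-variance two-sample t test, two-sided. When the pooled
#' variance is zero the limit is taken: p = 1 for equal means, p = 0
#' (t infinite) otherwise. Set `welch = TRUE` for the unequal-variance
#' form.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch correction instead of pooling.
#' @return One-row data.frame as in [pearson_r()] with `estimate` = t.
#' @export
students_t_test <- function(sample_a, sample_b, welch = FALSE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    equal <- mean(sample_a) == mean(sample_b)
    return(.stat_result("students_t", if (equal) 0 else Inf,
                        if (equal) 1 else 0,
                        length(sample_a) + length(sample_b),
                        length(sample_a) + length(sample_b) - 2L))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = !welch,
                      alternative = "two.sided")
  .stat_result(if (welch) "welch_t" else "students_t",
               unname(tt$statistic), tt$p.value,
               length(sample_a) + length(sample_b), unname(tt$parameter))
}

#' Paired t test
#'
#' Two-sided t test on the element-wise differences. If the differences
#' have zero variance, the limit is reported (p = 1 when all differences
#' are zero, otherwise p = 0 with a warning).
#'
#' @param sample_a,sample_b Numeric vectors of equal length >= 2.
#' @return One-row data.frame as in [pearson_r()] with `estimate` = t.
#' @export
paired_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) != length(sample_b)) {
    stop("paired samples must have equal length")
  }
  if (length(sample_a) < 2L) stop("paired test needs at least 2 pairs")
  d <- sample_a - sample_b
  if (stats::var(d) == 0) {
    if (all(d == 0)) {
      return(.stat_result("paired_t", 0, 1, length(d), length(d) - 1L))
    }
    warning("differences are constant and nonzero; reporting the p -> 0 limit")
    return(.stat_result("paired_t", sign(d[1]) * Inf, 0,
                        length(d), length(d) - 1L))
  }
  tt <- stats::t.test(sample_a, sample_b, paired = TRUE,
                      alternative = "two.sided")
  .stat_result("paired_t", unname(tt$statistic), tt$p.value,
               length(d), unname(tt$parameter))
}

#' Grouped Ka/Ks means
#'
#' Arithmetic mean of omega per lineage x duplication-type cell, to 4
#' decimals. Pairs with undefined omega (e.g. Ks = 0) are excluded from
#' both numerator and denominator, with the exclusion count reported;
#' empty cells are absent from the output rather than zero.
#'
#' @param results data.frame with a column `omega` plus the grouping
#'   columns.
#' @param lineage,duplication_type Column names used for grouping.
#' @return data.frame: grouping columns, `mean_omega`, `n`, `n_excluded`.
#' @export
group_kaks_means <- function(results, lineage = "lineage",
                             duplication_type = "duplication_type") {
  for (col in c("omega", lineage, duplication_type)) {
    if (!col %in% names(results)) stop("missing column: ", col)
  }
  groups <- unique(results[c(lineage, duplication_type)])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sub <- results[results[[lineage]] == groups[[lineage]][i] &
                     results[[duplication_type]] == groups[[duplication_type]][i], ]
    ok <- !is.na(sub$omega)
    if (!any(ok)) return(NULL)
    data.frame(lineage = groups[[lineage]][i],
               duplication_type = groups[[duplication_type]][i],
               mean_omega = round(mean(sub$omega[ok]), 4),
               n = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(lineage = character(), duplication_type = character(),
                      mean_omega = numeric(), n = integer(),
                      n_excluded = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
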