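# Two-timepoint statistical workflow for cosmetic-efficacy cohorts:
# Shapiro-Wilk normality gating, paired t-test (both samples normal) or
# Wilcoxon signed-rank (otherwise), and Spearman rank correlation with the
# conventional strength bands.  All tests are two-sided; no multiple-testing
# correction is applied and raw p-values are reported.

#' Shapiro-Wilk normality p-value
#'
#' Wraps the Shapiro-Wilk test; p < alpha flags a non-normal sample.  A
#' degenerate (constant) sample has no defined p-value and returns `NA`,
#' which downstream gating treats as non-normal.
#'
#' @param values Numeric sample, length >= 3.
#' @return p-value in `[0, 1]`, or `NA` for a constant sample.
#' @export
normality_test <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("normality test needs at least 3 observations", call. = FALSE)
  if (anyNA(values))
    stop("`values` must not contain NA", call. = FALSE)
  if (diff(range(values)) == 0) return(NA_real_)
  stats::shapiro.test(values)$p.value
}

#' Paired two-timepoint comparison with normality gating
#'
#' Tests whether a parameter changed between baseline (D0) and follow-up
#' (D45).  Both samples are first screened with the Shapiro-Wilk test at
#' `alpha`; if both pass, a two-sided paired t-test is used, otherwise the
#' two-sided Wilcoxon signed-rank test (normal approximation, zero
#' differences discarded in the classical manner).  If every difference is
#' zero the comparison is degenerate: no test is run and the result is not
#' significant.
#'
#' @param d0,d45 Paired numeric samples (same subjects, same order),
#'   length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `comparison_result`: `test_used`
#'   ("paired-t", "wilcoxon" or "degenerate"), `p_value`,
#'   `normality_p_d0`, `normality_p_d45`, `significant`, `direction`
#'   (sign of the mean D45 - D0 change), `zero_fraction` (share of zero
#'   differences), `n`.
#' @export
paired_compare <- function(d0, d45, alpha = 0.05) {
  d0 <- as.numeric(d0); d45 <- as.numeric(d45)
  if (length(d0) != length(d45))
    stop("`d0` and `d45` must have equal length (paired by subject)",
         call. = FALSE)
  if (length(d0) < 3L)
    stop("paired comparison needs at least 3 pairs", call. = FALSE)
  if (anyNA(d0) || anyNA(d45))
    stop("missing values are not allowed in paired samples", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  diffs <- d45 - d0
  p0 <- normality_test(d0)
  p45 <- normality_test(d45)
  normal_both <- !is.na(p0) && !is.na(p45) && p0 >= alpha && p45 >= alpha
  zero_frac <- mean(diffs == 0)
  if (all(diffs == 0)) {
    res <- list(test_used = "degenerate", p_value = NA_real_,
                significant = FALSE)
  } else if (normal_both) {
    p <- stats::t.test(d45, d0, paired = TRUE)$p.value
    res <- list(test_used = "paired-t", p_value = p,
                significant = p < alpha)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d45, d0, paired = TRUE, exact = FALSE))$p.value
    res <- list(test_used = "wilcoxon", p_value = p,
                significant = p < alpha)
  }
  structure(c(res, list(normality_p_d0 = p0, normality_p_d45 = p45,
                        direction = sign(mean(diffs)),
                        zero_fraction = zero_frac,
                        n = length(d0), alpha = alpha)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "Paired D0 vs D45 (n = %d): %s, p = %s%s, direction %s\n",
    x$n, x$test_used,
    if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4),
    if (isTRUE(x$significant)) sprintf(" (significant at %.2g)", x$alpha)
    else "",
    c("-1" = "decrease", "0" = "none", "1" = "increase")[
      as.character(x$direction)]))
  invisible(x)
}

#' Strength band of a Spearman coefficient
#'
#' Maps the magnitude of a correlation coefficient to the conventional
#' strength labels: 0-0.19 very weak, 0.2-0.39 weak, 0.4-0.69 moderate,
#' 0.7-0.89 strong, 0.9-1 very strong.  The intervals are closed as
#' printed; the magnitude is rounded to 2 decimals before lookup, which
#' resolves values falling between printed bounds (e.g. 0.195 becomes
#' 0.20 and joins the upper band).
#'
#' @param rs Correlation coefficient in `[-1, 1]` (the magnitude is
#'   banded; the sign is reported separately by
#'   [spearman_correlation()]).
#' @return One of "very weak", "weak", "moderate", "strong",
#'   "very strong".
#' @examples
#' correlation_band(0.47)  # "moderate"
#' @export
correlation_band <- function(rs) {
  stopifnot(is.numeric(rs), length(rs) == 1L, !is.na(rs),
            rs >= -1, rs <= 1)
  m <- round(abs(rs), 2)
  if (m <= 0.19) "very weak"
  else if (m <= 0.39) "weak"
  else if (m <= 0.69) "moderate"
  else if (m <= 0.89) "strong"
  else "very strong"
}

#' Spearman rank correlation with strength banding
#'
#' Rank-based correlation between two samples with a two-sided p-value
#' (asymptotic, tie-safe) and the strength band of the magnitude.
#'
#' @param x,y Numeric samples of equal length >= 3.
#' @return An object of class `correlation_result`: `rs`, `p_value`,
#'   `band`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("correlation needs at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("correlation is undefined for a constant sample", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(rs = unname(ct$estimate), p_value = ct$p.value,
                 band = correlation_band(unname(ct$estimate)),
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rs = %.3f (%s%s), p = %s, n = %d\n",
              x$rs, x$band, if (x$rs < 0) ", negative" else "",
              format(x$p_value, digits = 4), x$n))
  invisible(x)
}

#' Full cohort report: normality, paired comparisons, correlations
#'
#' Runs the complete two-timepoint workflow on a paired-measurement
#' table (columns `subject_id`, `parameter`, `d0`, `d45`, as produced by
#' [cohort_table()]): per parameter, Shapiro-Wilk normality at both
#' timepoints and the gated D0 vs D45 comparison; and, if a parameter
#' named `reference` is present (a gold-standard instrument), the
#' Spearman correlation of every other parameter against it at each
#' timepoint.
#'
#' @param table Paired-measurement data.frame.
#' @param alpha Significance level (default 0.05).
#' @param reference Name of the reference parameter (default
#'   "reference"); set `NULL` to skip correlations.
#' @return An object of class `cohort_report`: data.frames `comparisons`
#'   (parameter, n, normality p-values, test_used, p_value, significant,
#'   direction) and `correlations` (parameter, timepoint, rs, p_value,
#'   band).
#' @export
cohort_report <- function(table, alpha = 0.05, reference = "reference") {
  required <- c("subject_id", "parameter", "d0", "d45")
  if (!all(required %in% names(table)))
    stop("cohort table needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  if (anyNA(table$d0) || anyNA(table$d45)) {
    bad <- unique(table$subject_id[is.na(table$d0) | is.na(table$d45)])
    stop("missing pairs for subjects: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(table[c("subject_id", "parameter")])
  if (any(dup))
    stop("duplicate subject/parameter records: ",
         paste(unique(table$subject_id[dup]), collapse = ", "),
         call. = FALSE)
  params <- unique(table$parameter)
  comparisons <- do.call(rbind, lapply(params, function(p) {
    sub <- table[table$parameter == p, , drop = FALSE]
    cmp <- paired_compare(sub$d0, sub$d45, alpha = alpha)
    data.frame(parameter = p, n = cmp$n,
               normality_p_d0 = cmp$normality_p_d0,
               normality_p_d45 = cmp$normality_p_d45,
               test_used = cmp$test_used, p_value = cmp$p_value,
               significant = cmp$significant, direction = cmp$direction)
  }))
  correlations <- NULL
  if (!is.null(reference) && reference %in% params) {
    ref <- table[table$parameter == reference, , drop = FALSE]
    ref <- ref[order(ref$subject_id), , drop = FALSE]
    others <- setdiff(params, reference)
    correlations <- do.call(rbind, lapply(others, function(p) {
      sub <- table[table$parameter == p, , drop = FALSE]
      sub <- sub[order(sub$subject_id), , drop = FALSE]
      if (!identical(sub$subject_id, ref$subject_id))
        stop("parameter ", p, " and reference cover different subjects",
             call. = FALSE)
      do.call(rbind, lapply(c("d0", "d45"), function(tp) {
        cr <- tryCatch(spearman_correlation(sub[[tp]], ref[[tp]]),
                       error = function(e) NULL)
        if (is.null(cr))
          return(data.frame(parameter = p, timepoint = toupper(tp),
                            rs = NA_real_, p_value = NA_real_,
                            band = NA_character_))
        data.frame(parameter = p, timepoint = toupper(tp), rs = cr$rs,
                   p_value = cr$p_value, band = cr$band)
      }))
    }))
  }
  structure(list(comparisons = comparisons, correlations = correlations,
                 alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("D0 vs D45 paired comparisons (alpha =", x$alpha, "):\n")
  print(x$comparisons, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("\nSpearman correlations against the reference parameter:\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' Write a cohort report to CSV and plain text
#'
#' @param report A [cohort_report()] object.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_cohort_report <- function(report, dir, prefix = "cohort") {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  f <- file.path(dir, paste0(prefix, "_comparisons.csv"))
  utils::write.csv(report$comparisons, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(report$correlations)) {
    f <- file.path(dir, paste0(prefix, "_correlations.csv"))
    utils::write.csv(report$correlations, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, paste0(prefix, "_report.txt"))
  writeLines(utils::capture.output(print(report)), f)
  files <- c(files, f)
  invisible(files)
}
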