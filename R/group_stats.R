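#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation between two equal-length series, with the
#' two-tailed p-value from the t transform on `n - 2` degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `>= 3`, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("need length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("CONSTANT_INPUT: correlation undefined for a constant series",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Between-region correlation matrix across scans
#'
#' Entry (a, b) is the Pearson correlation, over the selected condition's
#' scans, between the per-scan mean entropies of regions a and b. Scans with
#' any missing cell among the selected regions are dropped listwise, so every
#' entry uses the same scan set and the matrix stays positive semidefinite.
#'
#' @param table A `roi_table`.
#' @param rois Character vector of region names to include (default: all).
#' @param condition `"rest"`, `"task"`, or `NULL` for all scans.
#' @return An object of class `cor_matrix`: list with `values` (K x K,
#'   symmetric, unit diagonal), `roi_names`, `n_scans`.
#' @export
correlation_matrix <- function(table, rois = NULL, condition = NULL) {
  stopifnot(inherits(table, "roi_table"))
  if (is.null(rois)) rois <- table$rois$name
  stopifnot(all(rois %in% colnames(table$mean)))
  rows <- if (is.null(condition)) rep(TRUE, nrow(table$mean))
          else table$scans$condition == condition
  m <- table$mean[rows, rois, drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L)
    stop("TOO_FEW_SCANS: need >= 3 complete scans, got ", nrow(m),
         call. = FALSE)
  values <- stats::cor(m)
  diag(values) <- 1
  structure(list(values = values, roi_names = rois, n_scans = nrow(m)),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat("Correlation matrix ", length(x$roi_names), " x ",
      length(x$roi_names), " over ", x$n_scans, " scans\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' Paired t-test with Bonferroni-adjusted p
#'
#' Classical paired t on `rest - task` differences; the adjusted p multiplies
#' the raw p by the size of the simultaneous-test family (e.g. 7 for the
#' seven-network table), capped at 1. If all differences are identical the t
#' statistic is undefined (zero-variance difference) and a sentinel result is
#' returned rather than an arbitrary value.
#'
#' @param rest,task Paired per-scan series (same subjects/scan indices, same
#'   order).
#' @param n_tests Bonferroni family size (default 1).
#' @return List with `t_stat`, `df`, `p_raw`, `p_adjusted`, `mean_diff`,
#'   `n_pairs`, and `degenerate` (`TRUE` when the difference has zero
#'   variance, in which case t/p are `NA`).
#' @export
paired_ttest <- function(rest, task, n_tests = 1L) {
  rest <- as.numeric(rest); task <- as.numeric(task)
  if (length(rest) != length(task)) stop("unequal lengths", call. = FALSE)
  d <- rest - task
  n <- length(d)
  if (n < 2L) stop("need >= 2 pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    return(list(t_stat = NA_real_, df = n - 1L, p_raw = NA_real_,
                p_adjusted = NA_real_, mean_diff = mean(d), n_pairs = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(rest, task, paired = TRUE)
  p <- tt$p.value
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = p, p_adjusted = bonferroni(p, n_tests),
       mean_diff = unname(tt$estimate), n_pairs = n, degenerate = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and caps at 1. The family size
#' defaults to the list length (the usual case: one family per reported
#' table) but can be set explicitly.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param n_tests Family size (default `length(p)`).
#' @return Adjusted p-values, same order.
#' @export
bonferroni <- function(p, n_tests = length(p)) {
  p <- as.numeric(p)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("OUT_OF_RANGE: p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, p * n_tests)
}

#' Balanced two-factor ANOVA with interaction
#'
#' Classical sum-of-squares partition for a fully crossed, balanced two-way
#' layout (e.g. condition x region class over all scans), fitted via
#' [stats::aov()]. The design must be balanced — with equal cell counts the
#' Type I/II/III decompositions coincide and
#' `SS(total) = SS(A) + SS(B) + SS(AB) + SS(error)` holds exactly.
#' Unbalanced input is rejected rather than silently re-weighted.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factor labels (any atomic type), fully crossed.
#' @param names_ab Length-2 character: row labels for the two factors in the
#'   output table.
#' @return Data frame with rows factor A, factor B, interaction, error,
#'   total and columns `source`, `ss`, `df`, `ms`, `f`, `p`. When all values
#'   are equal every SS is 0 and F/p are `NA`.
#' @export
two_factor_anova <- function(values, factor_a, factor_b,
                             names_ab = c("factor_a", "factor_b")) {
  values <- as.numeric(values)
  fa <- factor(factor_a); fb <- factor(factor_b)
  stopifnot(length(values) == length(fa), length(fa) == length(fb))
  counts <- table(fa, fb)
  if (any(counts == 0L) || length(unique(as.vector(counts))) != 1L)
    stop("UNBALANCED_DESIGN: cell counts ",
         paste(as.vector(counts), collapse = ","),
         " — a fully crossed balanced design is required", call. = FALSE)
  fit <- stats::aov(values ~ fa * fb)
  sm <- summary(fit)[[1]]
  ss <- sm[["Sum Sq"]]; df <- sm[["Df"]]
  ms <- sm[["Mean Sq"]]; f <- sm[["F value"]]; p <- sm[["Pr(>F)"]]
  tot_ss <- sum((values - mean(values))^2)
  out <- data.frame(
    source = c(names_ab[1], names_ab[2], "interaction", "error", "total"),
    ss = c(ss, tot_ss),
    df = c(df, length(values) - 1L),
    ms = c(ms, NA_real_),
    f = c(f, NA_real_),
    p = c(p, NA_real_),
    stringsAsFactors = FALSE)
  if (tot_ss == 0) {
    # constant response: every SS is exactly 0 and F is 0/0, reported missing
    out$ss[] <- 0; out$ms[1:4] <- 0
    out$f[] <- NA_real_; out$p[] <- NA_real_
  }
  out
}

#' Test-retest reliability: ICC(3,1)
#'
#' Two-way mixed, single-measure, consistency intraclass correlation from
#' the subjects x scans ANOVA decomposition:
#' `ICC = (BMS - EMS) / (BMS + (k - 1) * EMS)` with `k = 2` scans, where BMS
#' is the between-subject mean square and EMS the residual (subject x scan)
#' mean square. The consistency form is insensitive to a fixed shift between
#' the two scans.
#'
#' @param scan1,scan2 Per-subject series (same subjects, same order),
#'   length `>= 3`.
#' @return List with `icc`, `between_subject_ms`, `error_ms`, `n_subjects`,
#'   `k`.
#' @export
icc_3_1 <- function(scan1, scan2) {
  scan1 <- as.numeric(scan1); scan2 <- as.numeric(scan2)
  if (length(scan1) != length(scan2)) stop("unequal lengths", call. = FALSE)
  n <- length(scan1)
  if (n < 3L) stop("TOO_FEW_SUBJECTS: need >= 3 subjects", call. = FALSE)
  value <- c(scan1, scan2)
  subject <- factor(rep(seq_len(n), 2L))
  scan <- factor(rep(1:2, each = n))
  sm <- summary(stats::aov(value ~ subject + scan))[[1]]
  bms <- sm["subject", "Mean Sq"]
  ems <- sm["Residuals", "Mean Sq"]
  icc <- if (bms + ems == 0) NA_real_ else (bms - ems) / (bms + ems)
  list(icc = icc, between_subject_ms = bms, error_ms = ems,
       n_subjects = n, k = 2L)
}

#' Scan 1 vs scan 2 consistency of region entropies
#'
#' For cohorts scanned twice per condition: per region, the ICC(3,1) across
#' subjects, the Pearson correlation across subjects, and the two-tailed
#' paired-t p comparing the scan-1 and scan-2 means. At group level, the
#' Pearson correlation between the two length-K vectors of region means.
#'
#' @param table1,table2 `roi_table`s for scan 1 and scan 2: matching
#'   subjects (same order) and matching region columns.
#' @return List with `per_roi` (data frame: name, class, icc, r, p_two_tail)
#'   and `group_r` (correlation of region-mean vectors across scans).
#' @export
scan_consistency <- function(table1, table2) {
  stopifnot(inherits(table1, "roi_table"), inherits(table2, "roi_table"))
  if (!identical(table1$scans$subject_id, table2$scans$subject_id))
    stop("SUBJECT_MISMATCH: tables must cover the same subjects in the same order",
         call. = FALSE)
  if (!identical(colnames(table1$mean), colnames(table2$mean)))
    stop("SUBJECT_MISMATCH: region columns differ", call. = FALSE)
  rois <- colnames(table1$mean)
  per <- data.frame(name = rois, class = table1$rois$class,
                    icc = NA_real_, r = NA_real_, p_two_tail = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(rois)) {
    v1 <- table1$mean[, k]; v2 <- table2$mean[, k]
    per$icc[k] <- icc_3_1(v1, v2)$icc
    per$r[k] <- pearson_cor(v1, v2)$r
    tt <- paired_ttest(v1, v2)
    per$p_two_tail[k] <- tt$p_raw
  }
  mu1 <- colMeans(table1$mean); mu2 <- colMeans(table2$mean)
  group_r <- if (length(rois) >= 3L) pearson_cor(mu1, mu2)$r else NA_real_
  list(per_roi = per, group_r = group_r)
}
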