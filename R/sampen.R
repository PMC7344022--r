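#' Sample entropy parameters
#'
#' Bundles the tunable parameters of the sample entropy statistic. Defaults
#' follow the voxelwise brain-entropy convention: embedding dimension
#' `m = 3`, tolerance `r` equal to 0.6 times the standard deviation of each series
#' (sample SD, `n - 1` denominator), Chebyshev (maximum component) distance.
#'
#' @param m Embedding dimension: the number of consecutive points in a
#'   template vector. Positive integer.
#' @param r_factor Tolerance multiplier applied to the series SD when
#'   `sd_mode = "per-series"`. Dimensionless, must be positive.
#' @param sd_mode `"per-series"` (tolerance is `r_factor * sd(x)`, the
#'   voxelwise-mapping convention) or `"fixed"` (use `r_abs` as an absolute
#'   tolerance in signal units).
#' @param r_abs Absolute tolerance, required when `sd_mode = "fixed"`.
#' @param detrend If `TRUE`, remove a least-squares linear trend from each
#'   series before matching. Off by default: entropy is computed on the
#'   series as given.
#' @return An object of class `sampen_params`.
#' @export
sampen_params <- function(m = 3L, r_factor = 0.6,
                          sd_mode = c("per-series", "fixed"),
                          r_abs = NULL, detrend = FALSE) {
  sd_mode <- match.arg(sd_mode)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop("'m' must be a single integer >= 1", call. = FALSE)
  if (length(r_factor) != 1L || !is.finite(r_factor) || r_factor <= 0)
    stop("'r_factor' must be a single positive number", call. = FALSE)
  if (sd_mode == "fixed") {
    if (is.null(r_abs) || !is.finite(r_abs) || r_abs < 0)
      stop("'r_abs' must be a nonnegative number when sd_mode = 'fixed'",
           call. = FALSE)
  }
  structure(list(m = m, r_factor = r_factor, sd_mode = sd_mode,
                 r_abs = r_abs, detrend = isTRUE(detrend)),
            class = "sampen_params")
}

#' @export
print.sampen_params <- function(x, ...) {
  cat("Sample entropy parameters: m =", x$m, ", r =",
      if (x$sd_mode == "per-series") paste0(x$r_factor, " * SD(series)")
      else paste0(x$r_abs, " (absolute)"),
      if (x$detrend) ", linear detrend" else "", "\n")
  invisible(x)
}

linear_detrend <- function(x) {
  t <- seq_along(x)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' Template-match counts for sample entropy
#'
#' Counts, over all ordered pairs of template start indices
#' `i != j` in `1..(N-m)`, the m-length window matches (`b_total`) and the
#' (m+1)-length window matches (`a_total`) under the Chebyshev distance with
#' tolerance `r_abs`. Both counts use the common start-index range
#' `1..(N-m)`, so `a_total <= b_total` always holds and self-matches are
#' never counted.
#'
#' @param x Numeric series, all values finite, length at least `m + 2`.
#' @param m Embedding dimension.
#' @param r_abs Absolute tolerance in signal units (`>= 0`).
#' @return A list with `b_total`, `a_total` and `n_templates = N - m`.
#' @export
count_template_matches <- function(x, m, r_abs) {
  x <- as.numeric(x)
  if (anyNA(x) || !all(is.finite(x)))
    stop("INVALID_SERIES: series contains non-finite values", call. = FALSE)
  m <- as.integer(m)
  if (length(x) < m + 2L)
    stop("SHORT_SERIES: need length >= m + 2, got ", length(x), call. = FALSE)
  if (!is.finite(r_abs) || r_abs < 0)
    stop("'r_abs' must be >= 0", call. = FALSE)
  cc <- sampen_counts_cpp(x, m, r_abs)
  list(b_total = unname(cc["b_total"]), a_total = unname(cc["a_total"]),
       n_templates = as.integer(cc["n_templates"]))
}

#' Sample entropy of a single time series
#'
#' Computes `SE(m, r, N, x) = -ln(A / B)`, where `B` and `A` are the m- and
#' (m+1)-length template-match counts of [count_template_matches()]. The
#' normalisation constants in the match-frequency definitions cancel in the
#' ratio. Degenerate inputs yield `NA` with a reason attribute rather than an
#' arbitrary substitute value, because a substitute would bias downstream
#' region means.
#'
#' @param x Numeric series with finite values.
#' @param params A [sampen_params()] object.
#' @return A single numeric value (`>= 0` when defined). Undefined results
#'   are `NA` with attribute `reason` set to one of `"short-series"`,
#'   `"zero-variance"`, `"zero-matches"`.
#' @examples
#' sample_entropy(rep(c(0, 1), 50), sampen_params())  # periodic: exactly 0
#' @export
sample_entropy <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  x <- as.numeric(x)
  if (anyNA(x) || !all(is.finite(x)))
    stop("INVALID_SERIES: series contains non-finite values", call. = FALSE)
  if (length(x) < params$m + 2L)
    return(structure(NA_real_, reason = "short-series"))
  if (params$detrend) x <- linear_detrend(x)
  if (params$sd_mode == "per-series") {
    s <- stats::sd(x)
    if (s == 0) return(structure(NA_real_, reason = "zero-variance"))
    r_abs <- params$r_factor * s
  } else {
    r_abs <- params$r_abs
  }
  cc <- sampen_counts_cpp(x, params$m, r_abs)
  if (cc[["b_total"]] == 0 || cc[["a_total"]] == 0)
    return(structure(NA_real_, reason = "zero-matches"))
  -log(cc[["a_total"]] / cc[["b_total"]])
}

#' Voxelwise sample entropy map of a 4D volume
#'
#' Applies [sample_entropy()] to every in-mask voxel of a 4D array
#' (x, y, z, t). Out-of-mask voxels and undefined results are stored as `NA`
#' in the value lattice; a parallel integer lattice records why each voxel is
#' undefined, and a summary tally of undefined voxels by reason is attached.
#'
#' @param vol 4D numeric array, time on the fourth dimension.
#' @param mask Optional 3D logical array on the same spatial grid; `NULL`
#'   processes every voxel.
#' @param params A [sampen_params()] object.
#' @return An object of class `entropy_map`: list with `values` (3D array,
#'   `NA` where undefined or out of mask), `reason` (3D integer array: 0
#'   defined, 1 short series, 2 zero variance, 3 zero matches, `NA` out of
#'   mask) and `undefined_counts` (named integer vector).
#' @export
sample_entropy_map <- function(vol, mask = NULL, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  vol <- as_array4d(vol)
  dims <- dim(vol)
  grid <- dims[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, grid)
  } else {
    mask <- array(as.logical(mask), dim(mask))
    if (!identical(as.integer(dim(mask)), as.integer(grid)))
      stop("GRID_MISMATCH: mask grid ", paste(dim(mask), collapse = "x"),
           " != volume grid ", paste(grid, collapse = "x"), call. = FALSE)
  }
  n_t <- dims[4]
  values <- array(NA_real_, grid)
  reason <- array(NA_integer_, grid)
  idx <- which(mask)
  if (length(idx)) {
    # flatten to time x voxel for the compiled kernel
    flat <- matrix(vol, nrow = prod(grid), ncol = n_t)
    ts <- t(flat[idx, , drop = FALSE])
    if (params$detrend) ts <- apply(ts, 2L, linear_detrend)
    res <- sampen_map_cpp(ts, params$m, params$r_factor,
                          params$sd_mode == "per-series",
                          if (is.null(params$r_abs)) 0 else params$r_abs)
    values[idx] <- res$values
    reason[idx] <- res$reason
  }
  counts <- c(`short-series` = sum(reason == 1L, na.rm = TRUE),
              `zero-variance` = sum(reason == 2L, na.rm = TRUE),
              `zero-matches` = sum(reason == 3L, na.rm = TRUE))
  structure(list(values = values, reason = reason,
                 undefined_counts = counts),
            class = "entropy_map")
}

#' @export
print.entropy_map <- function(x, ...) {
  g <- dim(x$values)
  n_def <- sum(!is.na(x$values))
  cat("Entropy map ", paste(g, collapse = " x "), ": ", n_def,
      " defined voxels; undefined by reason: ",
      paste(names(x$undefined_counts), x$undefined_counts,
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Truncate a 4D volume in time
#'
#' Keeps the first `n_target` time points, leaving the spatial grid and any
#' metadata untouched. Used to cut rest scans down to the task-scan length so
#' that entropy is compared at a common series length.
#'
#' @param vol 4D numeric array (x, y, z, t).
#' @param n_target Number of leading time points to keep.
#' @return The truncated 4D array.
#' @export
truncate_bold <- function(vol, n_target) {
  vol <- as_array4d(vol)
  n_t <- dim(vol)[4]
  n_target <- as.integer(n_target)
  if (n_target < 1L || n_target > n_t)
    stop("BAD_LENGTH: n_target = ", n_target,
         " outside 1..", n_t, call. = FALSE)
  vol[, , , seq_len(n_target), drop = FALSE]
}

as_array4d <- function(vol) {
  vol <- unclass(vol)
  attributes(vol) <- list(dim = dim(vol))
  if (length(dim(vol)) != 4L)
    stop("expected a 4D array (x, y, z, t)", call. = FALSE)
  storage.mode(vol) <- "double"
  vol
}
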