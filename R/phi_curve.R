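#' Monte-Carlo reference curve: AR(1) regularity to expected sample entropy
#'
#' For each `phi`, simulates independent stationary AR(1) series and records
#' the mean and SD of their sample entropies. The resulting curve defines
#' the generator's entropy ground truth (effects are planted on `phi`, not
#' on entropy directly) and backs the fast parcel-level cohort path. The
#' packaged fixture (`inst/extdata/sampen_phi_curve_n405.csv`) was computed
#' with this function at the default 405-point series length.
#'
#' @param phi Vector of AR(1) coefficients in `[0, 0.98)`.
#' @param n Series length.
#' @param n_rep Series per `phi` value.
#' @param params [sampen_params()] used for the entropy statistic.
#' @param seed RNG seed.
#' @return Data frame with columns `phi`, `n`, `n_rep`, `mean_se`, `sd_se`.
#' @export
sampen_phi_curve <- function(phi = seq(0, 0.95, by = 0.05), n = 405L,
                             n_rep = 200L, params = sampen_params(),
                             seed = 20260920L) {
  set.seed(seed)
  out <- data.frame(phi = phi, n = as.integer(n), n_rep = as.integer(n_rep),
                    mean_se = NA_real_, sd_se = NA_real_)
  for (k in seq_along(phi)) {
    x <- simulate_ar1_matrix(phi[k], n, n_rep, 1)
    res <- sampen_map_cpp(x, params$m, params$r_factor,
                          params$sd_mode == "per-series",
                          if (is.null(params$r_abs)) 0 else params$r_abs)
    v <- res$values[res$reason == 0L]
    out$mean_se[k] <- mean(v)
    out$sd_se[k] <- stats::sd(v)
  }
  out
}

#' Load the packaged phi-to-entropy reference curve
#'
#' @param n Series length the curve was computed at (only 405 is packaged).
#' @return Data frame as returned by [sampen_phi_curve()].
#' @export
load_phi_curve <- function(n = 405L) {
  path <- system.file("extdata",
                      sprintf("sampen_phi_curve_n%d.csv", as.integer(n)),
                      package = "sampenmap")
  if (path == "")
    stop("no packaged reference curve for n = ", n,
         "; compute one with sampen_phi_curve()", call. = FALSE)
  utils::read.csv(path)
}

# Linear interpolation on the curve; constant extrapolation at the ends.
interp_phi_curve <- function(phi, curve, what = c("mean_se", "sd_se")) {
  what <- match.arg(what)
  stats::approx(curve$phi, curve[[what]], xout = phi, rule = 2)$y
}
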