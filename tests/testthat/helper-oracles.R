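# Independent oracles, deliberately written against the definitions rather
# than sharing any code with the package internals.

# Scalar double-loop template-match counter (the definitional form).
oracle_counts_loop <- function(x, m, r) {
  N <- length(x)
  nt <- as.integer(N - m)
  b <- 0L; a <- 0L
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      b <- b + 1L
      if (abs(x[i + m] - x[j + m]) <= r) a <- a + 1L
    }
  }
  list(b_total = b, a_total = a, n_templates = nt)
}

# Vectorised equivalent (embedded-window matrix), for larger sweeps.
oracle_counts <- function(x, m, r) {
  N <- length(x)
  nt <- as.integer(N - m)
  W <- stats::embed(x, m + 1)[, (m + 1):1, drop = FALSE]  # nt x (m+1)
  b <- 0L; a <- 0L
  for (i in seq_len(nt)) {
    d <- abs(W[, 1] - W[i, 1])
    if (m > 1) for (k in 2:m) d <- pmax(d, abs(W[, k] - W[i, k]))
    hit <- d <= r
    hit[i] <- FALSE
    b <- b + sum(hit)
    a <- a + sum(hit & abs(W[, m + 1] - W[i, m + 1]) <= r)
  }
  list(b_total = b, a_total = a, n_templates = nt)
}

oracle_sampen <- function(x, m, r_factor) {
  cc <- oracle_counts(x, m, r_factor * stats::sd(x))
  if (cc$b_total == 0 || cc$a_total == 0) return(NA_real_)
  -log(cc$a_total / cc$b_total)
}

# Balanced two-way ANOVA from cell means (textbook SS formulas).
hand_anova2 <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  a <- nlevels(fa); b <- nlevels(fb)
  n <- length(y) / (a * b)
  g <- mean(y)
  mi <- tapply(y, fa, mean)
  mj <- tapply(y, fb, mean)
  mij <- tapply(y, list(fa, fb), mean)
  ss_a <- b * n * sum((mi - g)^2)
  ss_b <- a * n * sum((mj - g)^2)
  ss_ab <- n * sum((mij - outer(mi - g, mj - g, "+") - g)^2)
  ss_e <- sum((y - mij[cbind(fa, fb)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), length(y) - a * b)
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  data.frame(ss = ss, df = df, ms = ms, f = f, p = p)
}

# ICC(3,1) from explicit sums of squares (two-way, consistency).
hand_icc31 <- function(y1, y2) {
  n <- length(y1)
  y <- cbind(y1, y2)
  g <- mean(y)
  ss_subj <- 2 * sum((rowMeans(y) - g)^2)
  ss_scan <- n * sum((colMeans(y) - g)^2)
  ss_tot <- sum((y - g)^2)
  ss_err <- ss_tot - ss_subj - ss_scan
  bms <- ss_subj / (n - 1)
  ems <- ss_err / (n - 1)
  (bms - ems) / (bms + ems)
}

# Pearson r and two-tailed p from the textbook formulas.
hand_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# A 4D volume whose every voxel carries the given series.
constant_series_volume <- function(series, grid = c(3L, 3L, 2L)) {
  array(rep(series, each = prod(grid)), c(grid, length(series)))
}

# Small two-parcel atlas on an arbitrary grid (first half / second half of
# the voxels in column-major order).
tiny_atlas <- function(grid = c(3L, 3L, 2L)) {
  nv <- prod(grid)
  labels <- c(rep(1L, nv %/% 2), rep(2L, nv - nv %/% 2))
  atlas_labels(array(labels, grid),
               c(`1` = "RegionA", `2` = "RegionB"),
               c(`1` = "cortical", `2` = "subcortical"))
}
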