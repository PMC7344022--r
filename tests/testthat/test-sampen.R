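test_that("parameter validation rejects malformed settings", {
  expect_error(sampen_params(m = 0), "m")
  expect_error(sampen_params(r_factor = -1), "r_factor")
  expect_error(sampen_params(sd_mode = "fixed"), "r_abs")
  p <- sampen_params()
  expect_equal(p$m, 3L)
  expect_equal(p$r_factor, 0.6)
})

test_that("match counts equal the definitional double-loop on small cases", {
  cases <- list(
    list(x = c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1), m = 2, r = 0.5),
    list(x = c(0, 1, 0, 1, 0, 1, 0, 1), m = 1, r = 0.3),
    list(x = sin(1:25), m = 3, r = 0.4))
  for (cs in cases) {
    got <- count_template_matches(cs$x, cs$m, cs$r)
    want <- oracle_counts_loop(cs$x, cs$m, cs$r)
    expect_identical(got$b_total, as.numeric(want$b_total))
    expect_identical(got$a_total, as.numeric(want$a_total))
    expect_identical(got$n_templates, want$n_templates)
    # the two oracle forms agree with each other too
    want2 <- oracle_counts(cs$x, cs$m, cs$r)
    expect_identical(want$b_total, want2$b_total)
    expect_identical(want$a_total, want2$a_total)
  }
})

test_that("strictly alternating series: every m-match extends", {
  cc <- count_template_matches(c(0, 1, 0, 1, 0, 1, 0, 1), 1, 0.3)
  expect_gt(cc$b_total, 0)
  expect_equal(cc$a_total, cc$b_total)
})

test_that("saturating tolerance matches everything and gives SE = 0", {
  set.seed(42)
  x <- rnorm(40)
  nt <- 40 - 2
  cc <- count_template_matches(x, 2, diff(range(x)) + 1)
  expect_equal(cc$b_total, nt * (nt - 1))
  expect_equal(cc$a_total, nt * (nt - 1))
  se <- sample_entropy(x, sampen_params(m = 2, sd_mode = "fixed",
                                        r_abs = diff(range(x)) + 1))
  expect_identical(unclass(se), 0)
})

test_that("short or malformed series are handled by contract", {
  expect_error(count_template_matches(c(1, 2, 3), 2, 0.5), "SHORT_SERIES")
  expect_error(sample_entropy(c(1, NA, 3, 4, 5, 6)), "INVALID_SERIES")
  se <- sample_entropy(c(1, 2, 3), sampen_params(m = 3))
  expect_true(is.na(se))
  expect_equal(attr(se, "reason"), "short-series")
})

test_that("degenerate series yield reasoned sentinels, not numbers", {
  se <- sample_entropy(rep(5, 50))
  expect_true(is.na(se))
  expect_equal(attr(se, "reason"), "zero-variance")
  # far-apart isolated levels with a tiny fixed tolerance: no matches
  x <- c(0, 100, -100, 200, -200, 300, -300, 400, -400, 500)
  se <- sample_entropy(x, sampen_params(m = 2, sd_mode = "fixed", r_abs = 1e-6))
  expect_true(is.na(se))
  expect_equal(attr(se, "reason"), "zero-matches")
})

test_that("strictly periodic series has exactly zero entropy", {
  expect_identical(unclass(sample_entropy(rep(c(0, 1), 50))), 0)
  expect_identical(unclass(sample_entropy(rep(c(1, 2, 3), 20),
                                          sampen_params(m = 2))), 0)
})

test_that("production entropy matches the oracle to floating point", {
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  got <- sample_entropy(x, sampen_params(m = 2))
  expect_equal(unclass(got), oracle_sampen(x, 2, 0.6), tolerance = 1e-14)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(20:120, 1))
    m <- sample(1:3, 1)
    rf <- sample(c(0.2, 0.6, 1.0), 1)
    got <- sample_entropy(x, sampen_params(m = m, r_factor = rf))
    expect_equal(as.numeric(got), oracle_sampen(x, m, rf), tolerance = 1e-12)
  }
})

test_that("per-series tolerance makes entropy affine-invariant", {
  set.seed(3)
  x <- rnorm(120)
  p <- sampen_params()
  base <- sample_entropy(x, p)
  expect_equal(unclass(sample_entropy(x + 17.5, p)), unclass(base),
               tolerance = 1e-12)
  expect_equal(unclass(sample_entropy(3.2 * x, p)), unclass(base),
               tolerance = 1e-12)
  cc1 <- count_template_matches(x, 3, 0.6 * sd(x))
  cc2 <- count_template_matches(2 * x + 1, 3, 0.6 * sd(2 * x + 1))
  expect_identical(cc1$b_total, cc2$b_total)
  expect_identical(cc1$a_total, cc2$a_total)
})

test_that("defined entropy is nonnegative and a-count never exceeds b-count", {
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(sample(20:100, 1))
    m <- sample(1:3, 1)
    cc <- count_template_matches(x, m, runif(1, 0.1, 1.5) * sd(x))
    expect_lte(cc$a_total, cc$b_total)
    expect_lte(cc$b_total, cc$n_templates * (cc$n_templates - 1))
    se <- sample_entropy(x, sampen_params(m = m))
    if (!is.na(se)) expect_gte(unclass(se), 0)
  }
})

test_that("voxelwise map reproduces per-voxel entropy and flags sentinels", {
  grid <- c(3, 3, 2)
  vol <- constant_series_volume(rep(c(0, 1), 25), grid)
  map <- sample_entropy_map(vol)
  expect_s3_class(map, "entropy_map")
  expect_true(all(map$values == 0))
  expect_equal(sum(map$undefined_counts), 0)

  set.seed(8)
  vol <- array(rnorm(prod(grid) * 60), c(grid, 60))
  vol[2, 2, 1, ] <- 7  # one constant-in-time voxel
  map <- sample_entropy_map(vol)
  expect_true(is.na(map$values[2, 2, 1]))
  expect_equal(map$reason[2, 2, 1], 2L)
  expect_equal(unname(map$undefined_counts["zero-variance"]), 1L)
  expect_equal(sum(is.na(map$values)), 1)
  # spot-check a voxel against the scalar path
  expect_equal(map$values[1, 1, 1],
               unclass(sample_entropy(vol[1, 1, 1, ])), tolerance = 1e-12)
})

test_that("mask controls which voxels are computed", {
  grid <- c(3, 3, 2)
  set.seed(9)
  vol <- array(rnorm(prod(grid) * 40), c(grid, 40))
  mask <- array(FALSE, grid); mask[1, , ] <- TRUE
  map <- sample_entropy_map(vol, mask = mask)
  expect_true(all(is.na(map$values[2:3, , ])))
  expect_true(all(!is.na(map$values[1, , ])))
  expect_error(sample_entropy_map(vol, mask = array(TRUE, c(2, 2, 2))),
               "GRID_MISMATCH")
})

test_that("time truncation keeps the leading points only", {
  set.seed(10)
  vol <- array(rnorm(2 * 2 * 2 * 50), c(2, 2, 2, 50))
  expect_identical(truncate_bold(vol, 50), vol)
  tr <- truncate_bold(vol, 20)
  expect_equal(dim(tr), c(2, 2, 2, 20))
  expect_identical(tr[1, 2, 1, ], vol[1, 2, 1, 1:20])
  expect_error(truncate_bold(vol, 51), "BAD_LENGTH")
  # map after truncation equals the oracle on the truncated series
  map <- sample_entropy_map(truncate_bold(vol, 30))
  expect_equal(map$values[2, 2, 2], oracle_sampen(vol[2, 2, 2, 1:30], 3, 0.6),
               tolerance = 1e-12)
})

test_that("fixed-absolute tolerance mode bypasses the per-series SD rule", {
  set.seed(12)
  x <- rnorm(80)
  p_fix <- sampen_params(m = 2, sd_mode = "fixed", r_abs = 0.5)
  cc <- count_template_matches(x, 2, 0.5)
  expect_equal(unclass(sample_entropy(x, p_fix)),
               -log(cc$a_total / cc$b_total), tolerance = 1e-14)
  # scaling the data now changes the result (no affine invariance)
  expect_false(isTRUE(all.equal(unclass(sample_entropy(3 * x, p_fix)),
                                unclass(sample_entropy(x, p_fix)))))
})
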