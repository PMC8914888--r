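test_that("Gaussian smoothing: constants invariant, fwhm 0 identity, peak", {
  v <- array(3, dim = c(12, 12, 12))
  expect_equal(smooth_gaussian(v, 1, 0.5), v, tolerance = 1e-12)
  set.seed(30)
  r <- array(rnorm(12^3), dim = c(12, 12, 12))
  expect_identical(smooth_gaussian(r, 0, 0.5), r)
  # unit impulse at 0.5 mm voxels, 1 mm FWHM: peak close to the analytic
  # 3D Gaussian density times the voxel volume
  imp <- array(0, dim = c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm <- smooth_gaussian(imp, 1, 0.5)
  sigma <- 1 / (2 * sqrt(2 * log(2)))
  peak_analytic <- (0.5^3) / ((2 * pi)^1.5 * sigma^3)
  expect_lt(abs(sm[11, 11, 11] - peak_analytic) / peak_analytic, 0.02)
  expect_equal(sum(sm), 1, tolerance = 1e-9) # kernel normalization
})

make_group_maps <- function(n, d = c(10, 10, 6), effect = 0, region = NULL,
                            seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- array(rnorm(prod(d)), dim = d)
    if (!is.null(region)) m[region] <- m[region] + effect
    m
  })
}

test_that("group-difference map: identical groups give t = 0, signs flip", {
  d <- c(8, 8, 6)
  maps <- make_group_maps(4, d, seed = 31)
  ages <- c(40, 50, 45, 55)
  g0 <- groupdiff_map(maps, maps, c(ages, ages))
  expect_lt(max(abs(g0$t_map)), 1e-8)
  p <- make_group_maps(5, d, seed = 32); q <- make_group_maps(5, d, seed = 33)
  ages10 <- rnorm(10, 50, 8)
  g1 <- groupdiff_map(p, q, ages10)
  g2 <- groupdiff_map(q, p, ages10[c(6:10, 1:5)])
  expect_equal(g1$t_map, -g2$t_map, tolerance = 1e-8)
})

test_that("a known regional offset appears in the mean-difference map", {
  d <- c(12, 12, 8)
  region <- array(FALSE, dim = d); region[4:8, 4:8, 3:6] <- TRUE
  p <- make_group_maps(8, d, effect = 39, region = region, seed = 34)
  q <- make_group_maps(8, d, seed = 35)
  g <- groupdiff_map(p, q, rnorm(16, 50, 8))
  expect_equal(mean(g$mean_diff[region]), 39, tolerance = 2)
  expect_lt(abs(mean(g$mean_diff[!region])), 1.5)
})

test_that("grid mismatch and undersized groups are rejected", {
  a <- list(array(0, dim = c(4, 4, 4)), array(0, dim = c(4, 4, 4)))
  b <- list(array(0, dim = c(5, 4, 4)), array(0, dim = c(5, 4, 4)))
  expect_error(groupdiff_map(a, b, rnorm(4)), "common grid")
  expect_error(permutation_fwe(a[1], a, rnorm(3)), "size")
})

test_that("TFCE: zero map, closed-form uniform cluster, analytic limit", {
  z <- array(0, dim = c(8, 8, 8))
  expect_equal(tfce_enhance(z), z)
  # rectangular cluster of height 3, extent 16: integral e^0.5 h^2 dh
  # over (0, 3] equals 4 * 9 = 36
  m <- array(0, dim = c(10, 10, 4)); m[3:6, 3:6, 2] <- 3
  cfg <- tfce_config(dh = 3 / 600)
  e <- tfce_enhance(m, cfg)
  expect_equal(e[4, 4, 2], 36, tolerance = 36 * 0.01) # dh discretization
  expect_equal(e[1, 1, 1], 0)
  # E = 0, H = 1: TFCE integrates h alone -> stat^2/2; compare shape via
  # ratio to the stat map on a nonnegative random field
  set.seed(36)
  s <- array(abs(rnorm(6^3)), dim = c(6, 6, 6))
  cfg2 <- tfce_config(height_exponent = 1, extent_exponent = 0, dh = max(s) / 400)
  e2 <- tfce_enhance(s, cfg2)
  expect_equal(e2, s^2 / 2, tolerance = 0.05 * max(s^2 / 2))
})

test_that("negative values are enhanced separately with sign preserved", {
  m <- array(0, dim = c(8, 8, 4))
  m[2:3, 2:3, 2] <- 2
  m[6:7, 6:7, 3] <- -2
  e <- tfce_enhance(m, tfce_config(dh = 2 / 200))
  expect_gt(e[2, 2, 2], 0)
  expect_lt(e[6, 6, 3], 0)
  expect_equal(e[2, 2, 2], -e[6, 6, 3], tolerance = 1e-10)
})

test_that("raising one voxel never lowers any TFCE value", {
  set.seed(37)
  d <- c(8, 8, 8)
  s <- array(pmax(rnorm(prod(d), 0.5), 0), dim = d)
  cfg <- tfce_config(dh = (max(s) + 1) / 150)
  base <- tfce_enhance(s, cfg, dh = cfg$dh)
  for (v in sample(prod(d), 40)) {
    s2 <- s
    s2[v] <- s2[v] + 0.8
    e2 <- tfce_enhance(s2, cfg, dh = cfg$dh)
    expect_true(all(e2 >= base - 1e-9))
  }
})

test_that("permutation FWE: determinism, p floor, and effect localization", {
  d <- c(12, 12, 8)
  region <- array(FALSE, dim = d); region[4:8, 4:8, 3:6] <- TRUE
  p <- make_group_maps(8, d, effect = 10, region = region, seed = 38)
  q <- make_group_maps(8, d, seed = 39)
  ages <- rnorm(16, 50, 8)
  r1 <- permutation_fwe(p, q, ages, n_perm = 150, seed = 9)
  r2 <- permutation_fwe(p, q, ages, n_perm = 150, seed = 9)
  expect_identical(r1$p_fwe_pos, r2$p_fwe_pos)
  expect_true(all(r1$p_fwe_pos >= 1 / 151))
  expect_equal(length(r1$null_max_pos), 150)
  sig <- r1$p_fwe_pos < 0.05
  dice <- 2 * sum(sig & region) / (sum(sig) + sum(region))
  expect_gt(dice, 0.5)
})

test_that("voxelwise correlation finds a built-in linear dependence", {
  d <- c(10, 10, 6)
  region <- array(FALSE, dim = d); region[3:7, 3:7, 2:5] <- TRUE
  set.seed(40)
  score <- rnorm(14, 15, 5)
  ages <- rnorm(14, 50, 8)
  maps <- lapply(seq_len(14), function(i) {
    m <- array(rnorm(prod(d)), dim = d)
    m[region] <- m[region] + 0.8 * score[i]
    m
  })
  r <- voxelwise_correlation(maps, score, ages, n_perm = 150, seed = 10)
  sig <- r$p_fwe_pos < 0.05
  expect_gt(sum(sig & region) / sum(region), 0.5)
  expect_error(voxelwise_correlation(maps, rep(1, 14), ages), "constant")
  # consistent subject reordering leaves the observed statistics unchanged
  ord <- sample(14)
  r2 <- voxelwise_correlation(maps[ord], score[ord], ages[ord],
                              n_perm = 150, seed = 10)
  expect_equal(r2$t_map, r$t_map, tolerance = 1e-9)
})
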