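test_that("hull rasterization equals brute-force membership on small sets", {
  set.seed(10)
  for (rep in 1:4) {
    S <- unique(matrix(sample(2:30, 30, replace = TRUE), ncol = 3))
    if (nrow(S) < 6) next
    fac <- convex_hull_facets(S)
    rng <- apply(S, 2, range)
    grid <- as.matrix(expand.grid(x = rng[1, 1]:rng[2, 1],
                                  y = rng[1, 2]:rng[2, 2],
                                  z = rng[1, 3]:rng[2, 3]))
    got <- point_in_hull(grid, fac)
    want <- oracle_in_hull(grid, S)
    expect_identical(got, unname(want))
  }
})

test_that("hull of a filled box is the box itself", {
  box <- as.matrix(expand.grid(x = 3:7, y = 2:9, z = 4:6))
  fac <- convex_hull_facets(box)
  grid <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:8))
  inside <- point_in_hull(grid, fac)
  want <- grid[, 1] >= 3 & grid[, 1] <= 7 & grid[, 2] >= 2 & grid[, 2] <= 9 &
    grid[, 3] >= 4 & grid[, 3] <= 6
  expect_identical(inside, unname(want))
})

test_that("degenerate (coplanar) point sets are rejected by name", {
  flat <- cbind(1:6, c(1, 3, 2, 5, 4, 6), 2)
  expect_error(convex_hull_facets(flat), "coplanar")
  lab <- array(0L, dim = c(12, 12, 12))
  lab[3:8, 3:8, 5] <- 1L
  expect_error(build_dn_bulk(lab, voxel_size_mm = 0.5), "left")
})

test_that("erosion matches the brute-force 27-neighbourhood oracle", {
  set.seed(11)
  m <- array(runif(14^3) > 0.35, dim = c(14, 14, 14))
  got <- dentateqsm:::erode_box3(m)
  expect_identical(got, oracle_erode27(m))
})

test_that("bulk of an already-convex silhouette is its erosion", {
  lab <- array(0L, dim = c(20, 20, 20))
  lab[4:12, 5:13, 6:14] <- 1L
  bulk <- build_dn_bulk(lab, r2star = NULL, voxel_size_mm = 0.5)
  expect_identical(bulk$labels > 0, oracle_erode27(lab > 0))
})

test_that("the hull fills the sac of a C-shaped shell", {
  # open spherical shell on a 32^3 grid: bulk must include interior voxels
  d <- c(32, 32, 32)
  co <- test_coords(32, 1)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  shell <- r >= 5 & r <= 6.5 & co$z < 3 # open top
  lab <- array(0L, dim = d); lab[shell] <- 1L
  bulk <- build_dn_bulk(lab, voxel_size_mm = 1)
  interior <- r <= 3 & co$z < 1
  expect_true(all(bulk$labels[interior] == 1L))
  expect_gt(sum(bulk$labels > 0 & lab == 0L), sum(interior))
})

test_that("voxels below the R2* threshold are excluded from the bulk", {
  lab <- array(0L, dim = c(16, 16, 16))
  lab[3:13, 3:13, 3:13] <- 1L
  r2 <- array(25, dim = dim(lab))
  pocket <- array(FALSE, dim = dim(lab)); pocket[7:9, 7:9, 7:9] <- TRUE
  r2[pocket] <- 10
  bulk <- build_dn_bulk(lab, r2, r2star_min = 15, voxel_size_mm = 0.5)
  expect_true(all(bulk$labels[pocket] == 0L))
  bulk_no <- build_dn_bulk(lab, r2, r2star_min = 5, voxel_size_mm = 0.5)
  expect_true(all(bulk_no$labels[pocket] == 1L))
})

test_that("hemisphere labels follow the midline of the brain mask", {
  d <- c(24, 24, 24)
  brain <- array(TRUE, dim = d)
  m <- array(0L, dim = d)
  m[4:8, 10:14, 10:14] <- 1L   # left blob
  m[17:21, 10:14, 10:14] <- 1L # right blob
  sp <- split_hemispheres(m, brain, 0.5)
  expect_equal(sum(sp$labels == 1), sum(sp$labels == 2))
  ix_l <- which(sp$labels == 1)
  expect_true(all(((ix_l - 1) %% d[1]) + 1 <= 8))
  # single-sided mask: everything labeled left
  m2 <- array(0L, dim = d); m2[3:6, 3:6, 3:6] <- 1L
  expect_true(all(split_hemispheres(m2, brain, 0.5)$labels[m2 > 0] == 1L))
})

test_that("a straddling component is assigned by majority with a warning", {
  d <- c(20, 20, 20)
  brain <- array(TRUE, dim = d)
  m <- array(0L, dim = d)
  m[7:16, 9:11, 9:11] <- 1L # 60% of voxels on the right of midline (10.5)
  expect_warning(sp <- split_hemispheres(m, brain, 0.5), "straddles")
  expect_true(all(sp$labels[m > 0] == 2L))
})

test_that("VOI metrics follow the volume and mass identities", {
  d <- c(20, 20, 20)
  lab <- array(0L, dim = d)
  lab[1:10, 1:10, 1:10] <- 1L # 1000 voxels at 0.5 mm
  chi <- array(100, dim = d)
  met <- voi_metrics(chi, lab, voxel_size_mm = 0.5)
  expect_equal(met$volume_mm3, 125)
  expect_equal(met$mean_chi_ppb, 100)
  expect_equal(met$chi_mass_ppb_cm3, 12.5)
  # mass identity on an arbitrary map, per hemisphere too
  set.seed(12)
  chi2 <- array(rnorm(prod(d), 50, 20), dim = d)
  lab[15:18, 2:6, 2:6] <- 2L
  met2 <- voi_metrics(chi2, lab, voxel_size_mm = 0.5)
  expect_equal(met2$chi_mass_ppb_cm3,
               met2$volume_mm3 / 1000 * met2$mean_chi_ppb)
  for (i in seq_len(nrow(met2$hemispheres))) {
    h <- met2$hemispheres[i, ]
    expect_equal(h$chi_mass_ppb_cm3, h$volume_mm3 / 1000 * h$mean_chi_ppb)
  }
})

test_that("group-level mass arithmetic matches the worked group means", {
  # 625.6 mm^3 at 58.1 ppb gives 36.3 ppb cm^3 (approximately the group
  # mean of per-subject products)
  expect_equal(625.6 / 1000 * 58.1, 36.3, tolerance = 0.05)
})

test_that("empty masks yield NaN metrics with a warning", {
  expect_warning(met <- voi_metrics(array(1, dim = c(4, 4, 4)),
                                    array(0L, dim = c(4, 4, 4))), "empty")
  expect_true(is.nan(met$volume_mm3))
  expect_true(is.nan(met$chi_mass_ppb_cm3))
})

test_that("bulk construction on the phantom overlaps truth (Dice > 0.8)", {
  tr <- make_dentate_phantom(small_phantom_spec())
  sil <- split_hemispheres(tr$dn_sil, tr$brain_mask, 0.5)
  bulk <- build_dn_bulk(sil, tr$r2star, 15)
  a <- bulk$labels > 0; b <- tr$dn_bulk > 0
  expect_gt(2 * sum(a & b) / (sum(a) + sum(b)), 0.8)
  # no bulk voxel below the R2* threshold, and bulk inside the hull side
  expect_true(all(tr$r2star[a] >= 15))
})
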