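# Independent brute-force oracles used across tests.

# wrap to (-pi, pi], independent of the package helper
oracle_wrap <- function(x) {
  y <- x - 2 * pi * floor(x / (2 * pi))   # [0, 2pi)
  ifelse(y > pi, y - 2 * pi, ifelse(y == 0 & x != 0, y, y))
}

# brute-force 27-neighbourhood erosion (out-of-grid = background)
oracle_erode27 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    keep <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3] ||
          !mask[xx, yy, zz]) keep <- FALSE
    }
    out[x, y, z] <- keep
  }
  out
}

# brute-force point-in-hull by Caratheodory: p is in conv(S) iff some
# tetrahedron of 4 points of S contains it (S small). Boundary-inclusive.
oracle_in_hull <- function(p_mat, S, tol = 1e-9) {
  combs <- utils::combn(nrow(S), 4)
  inside <- rep(FALSE, nrow(p_mat))
  for (j in seq_len(ncol(combs))) {
    tet <- S[combs[, j], , drop = FALSE]
    A <- rbind(t(tet), rep(1, 4))          # 4x4: barycentric system
    if (abs(det(A)) < 1e-12) next          # degenerate tetrahedron
    rhs <- rbind(t(p_mat), rep(1, nrow(p_mat)))
    lam <- solve(A, rhs)                   # 4 x npts
    ok <- apply(lam >= -tol, 2, all)
    inside <- inside | ok
    if (all(inside)) break
  }
  inside
}

# analytic external field of a uniformly magnetized sphere, with the
# sphere's discrete (voxelized) dipole moment
oracle_sphere_field <- function(co, R, dchi_ppb, veff_mm3, f0) {
  r2 <- co$x^2 + co$y^2 + co$z^2
  r <- sqrt(pmax(r2, 1e-12))
  cost2 <- co$z^2 / pmax(r2, 1e-12)
  R3 <- 3 * veff_mm3 / (4 * pi)
  f0 * dchi_ppb * 1e-9 / 3 * R3 / r^3 * (3 * cost2 - 1)
}

# centered coordinate arrays (mm)
test_coords <- function(n, vs = 0.5) {
  cc <- (seq_len(n) - (n + 1) / 2) * vs
  list(x = array(rep(cc, times = n * n), c(n, n, n)),
       y = array(rep(rep(cc, each = n), times = n), c(n, n, n)),
       z = array(rep(cc, each = n * n), c(n, n, n)))
}

# small, fast phantom used by several suites
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 48, 48), brain_radii_mm = c(9, 9, 9),
               shell_center_mm = c(3.8, 0, -0.7),
               shell_radii_mm = c(2.4, 2.0, 1.8),
               wall_thickness_mm = 0.8, csf_radius_mm = 0.9, ...)
}
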