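#' Larmor frequency used for ppm/Hz conversion
#'
#' Proton Larmor frequency at the field strength of the acquisition
#' (3 T x 42.576 MHz/T = 127.728 MHz).  Stated once here; every operation that
#' converts between susceptibility (dimensionless) and frequency (Hz) takes
#' `f0_hz` as an argument defaulting to this value.
#'
#' @param b0_tesla Static field strength in tesla.
#' @return Larmor frequency in Hz.
#' @export
qsm_f0 <- function(b0_tesla = 3) 42.576e6 * b0_tesla

#' Default echo times of the multi-echo gradient-echo protocol
#'
#' @return Echo times in seconds (6.47, 17.23, 27.99, 38.75 ms).
#' @export
qsm_default_tes <- function() c(0.00647, 0.01723, 0.02799, 0.03875)

# FFT sample frequencies (cycles per unit), standard FFT ordering
fft_freqs <- function(n, d = 1) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

fftn <- function(x) stats::fft(x)
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# k-space coordinate arrays for a 3D grid with per-axis spacing
kgrid3 <- function(dim, voxel_size) {
  vs <- rep_len(voxel_size, 3)
  kx <- fft_freqs(dim[1], vs[1])
  ky <- fft_freqs(dim[2], vs[2])
  kz <- fft_freqs(dim[3], vs[3])
  list(
    kx = array(kx, dim = dim),
    ky = aperm(array(ky, dim = dim[c(2, 1, 3)]), c(2, 1, 3)),
    kz = aperm(array(kz, dim = dim[c(3, 1, 2)]), c(2, 3, 1))
  )
}

#' Unit dipole kernel in k-space
#'
#' D(k) = 1/3 - (k . b0)^2 / |k|^2 with the undefined k = 0 term set to zero
#' (this fixes the arbitrary constant of the field; maps are referenced later).
#' Anisotropic voxels are handled through the per-axis k-space spacing.
#'
#' @param dim Grid dimensions (3 integers).
#' @param voxel_size_mm Voxel spacing in mm (scalar or length 3).
#' @param b0_direction Unit vector of the static field (default +z).
#' @return 3D array of dipole kernel values in standard FFT ordering.
#' @export
dipole_kernel <- function(dim, voxel_size_mm, b0_direction = c(0, 0, 1)) {
  if (length(b0_direction) != 3 || abs(sqrt(sum(b0_direction^2)) - 1) > 1e-6)
    stop("b0_direction must be a unit 3-vector")
  k <- kgrid3(dim, voxel_size_mm)
  kb <- k$kx * b0_direction[1] + k$ky * b0_direction[2] + k$kz * b0_direction[3]
  k2 <- k$kx^2 + k$ky^2 + k$kz^2
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- 0
  D
}

# wrap phase to (-pi, pi], half-open at -pi
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi)
  y[y == 0] <- 2 * pi
  y - pi
}

# voxel-center coordinates (mm), centered so the grid midpoint is the origin;
# the mid-sagittal plane of an even grid falls between voxel columns
grid_coords_mm <- function(dim, voxel_size_mm) {
  vs <- rep_len(voxel_size_mm, 3)
  lapply(1:3, function(a) (seq_len(dim[a]) - (dim[a] + 1) / 2) * vs[a])
}

# expand axis coordinate vectors to full 3D arrays
coord_arrays <- function(cc, dim) {
  list(
    x = array(cc[[1]], dim = dim),
    y = aperm(array(cc[[2]], dim = dim[c(2, 1, 3)]), c(2, 1, 3)),
    z = aperm(array(cc[[3]], dim = dim[c(3, 1, 2)]), c(2, 3, 1))
  )
}

# deterministic per-stage child seeds from one global seed
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(index)) %%
               2147483647)
}

# zero-filled shift of a logical/numeric 3D array by whole voxels
shift3 <- function(x, dx, dy, dz, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, dim = d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
  out[sx, sy, sz] <- x[sx - dx, sy - dy, sz - dz]
  out
}

# binary erosion with the full 3x3x3 (27-neighbourhood) structuring element;
# out-of-grid neighbours count as background
erode_box3 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out & shift3(mask, dx, dy, dz, fill = FALSE)
  }
  out
}
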