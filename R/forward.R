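#' Forward dipole model: susceptibility to field shift
#'
#' Computes the Larmor frequency offset induced by a susceptibility
#' distribution through the k-space unit dipole response,
#' `field = f0 * IFFT(D(k) * FFT(chi))` with `D(k) = 1/3 - (k.b0)^2/|k|^2`
#' and `D(0) = 0`.  Susceptibility is supplied in ppb and converted to a
#' dimensionless fraction internally.  The operator is linear and
#' shift-equivariant (periodic boundaries).
#'
#' @param chi_ppb 3D array of susceptibility in parts per billion.
#' @param voxel_size_mm Voxel spacing in mm (scalar or length 3).
#' @param b0_direction Unit vector of the static field (default +z).
#' @param f0_hz Larmor frequency in Hz, see [qsm_f0()].
#' @return 3D array of frequency offsets in Hz (zero mean over the grid).
#' @export
forward_field <- function(chi_ppb, voxel_size_mm = 0.5,
                          b0_direction = c(0, 0, 1), f0_hz = qsm_f0()) {
  d <- dim(chi_ppb)
  if (length(d) != 3) stop("chi_ppb must be a 3D array")
  D <- dipole_kernel(d, voxel_size_mm, b0_direction)
  Re(ifftn(D * fftn(chi_ppb * 1e-9))) * f0_hz
}

#' Simulate a multi-echo gradient-echo acquisition
#'
#' `S(TE) = s0 exp(-R2* TE) exp(i (phi0 + 2 pi field TE)) + noise`, with
#' i.i.d. complex Gaussian noise of standard deviation `noise_sigma` per
#' channel (single-coil model).  Magnitude and phase are stored per echo;
#' phase is wrapped to (-pi, pi] (half-open at -pi).
#'
#' @param field_hz 3D frequency-offset map in Hz.
#' @param s0 Proton-density magnitude (scalar or 3D array).
#' @param r2star Effective transverse relaxation rate in 1/s (scalar or array).
#' @param tes_s Echo times in seconds, strictly increasing.
#' @param phi0 Global receiver phase offset in radians.
#' @param noise_sigma Complex Gaussian noise sd per channel.
#' @param seed Optional RNG seed for the noise.
#' @param voxel_size_mm Voxel spacing recorded with the series.
#' @return An `echo_series` object: lists `magnitude` and `phase` (one 3D
#'   array per echo), `tes_s`, `voxel_size_mm`, `dim`.
#' @export
synthesize_echoes <- function(field_hz, s0 = 1, r2star = 0,
                              tes_s = qsm_default_tes(), phi0 = 0,
                              noise_sigma = 0, seed = NULL,
                              voxel_size_mm = 0.5) {
  d <- dim(field_hz)
  if (length(d) != 3) stop("field_hz must be a 3D array")
  if (any(diff(tes_s) <= 0)) stop("tes_s must be strictly increasing")
  if (any(r2star < 0)) stop("negative R2* voxels are not physical")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  s0a <- if (length(s0) == 1) array(s0, dim = d) else s0
  r2a <- if (length(r2star) == 1) array(r2star, dim = d) else r2star
  mags <- vector("list", length(tes_s))
  phs <- vector("list", length(tes_s))
  for (i in seq_along(tes_s)) {
    te <- tes_s[i]
    sig <- s0a * exp(-r2a * te) * exp(1i * (phi0 + 2 * pi * field_hz * te))
    if (noise_sigma > 0) {
      sig <- sig + array(stats::rnorm(prod(d), sd = noise_sigma) +
                           1i * stats::rnorm(prod(d), sd = noise_sigma),
                         dim = d)
    }
    mags[[i]] <- Mod(sig)
    phs[[i]] <- wrap_phase(Arg(sig))
  }
  structure(list(magnitude = mags, phase = phs, tes_s = tes_s,
                 voxel_size_mm = voxel_size_mm, dim = d),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat("Multi-echo GRE series:", length(x$tes_s), "echoes,",
      paste(x$dim, collapse = "x"), "grid,",
      x$voxel_size_mm, "mm voxels\n")
  cat("  TEs (ms):", paste(format(x$tes_s * 1e3), collapse = ", "), "\n")
  invisible(x)
}
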