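#' Specification of the synthetic dentate phantom
#'
#' Describes a scaled-down digital head: a large ellipsoidal "brain" mask
#' containing two mirrored, open-topped, corrugated ellipsoidal shells that
#' emulate the thin high-susceptibility walls of the dentate nuclei, the
#' lower-susceptibility white matter inside the sac they form, a small CSF
#' pocket, smooth harmonic background fields, and per-compartment R2*.
#' The dentate geometry is a synthetic choice (no quantitative geometry is
#' published for the nuclei); susceptibility and R2* levels are set to
#' physiologically plausible magnitudes.
#'
#' The shell wall is the band `|rho(u) - rho0(u)| <= wall/(2 rbar)` in
#' radius-normalized coordinates `u` (so the wall thickness is approximately
#' `wall_thickness_mm` at the mean radius `rbar`), where
#' `rho0 = 1 + (corrugation_amplitude_mm/rbar) sin(corrugation_lobes * azimuth)
#' * sin(polar)` is the corrugated target radius.  Voxels whose direction lies
#' within `opening_deg` of +z are removed, leaving an open sac.
#'
#' @param grid_shape Voxels per axis (3 integers, all >= 16).
#' @param voxel_size_mm Isotropic voxel spacing in mm (default 0.5, matching
#'   the acquisition the pipeline emulates).
#' @param wall_chi_ppb Susceptibility of the dentate shell (ppb).
#' @param interior_chi_ppb Susceptibility of the white matter inside the sac.
#' @param tissue_chi_ppb Susceptibility of surrounding tissue.
#' @param brain_radii_mm Semi-axes of the ellipsoidal brain mask (mm).
#' @param shell_center_mm Center of the right-hemisphere shell (mm; mirrored
#'   about the mid-sagittal plane for the left hemisphere).
#' @param shell_radii_mm Semi-axes of the shell (mm).
#' @param wall_thickness_mm Shell wall thickness (mm); must be smaller than
#'   the smallest shell radius.
#' @param corrugation_amplitude_mm Amplitude of the sinusoidal radial
#'   corrugation (mm); 0 gives a smooth ellipsoidal annulus.
#' @param corrugation_lobes Number of corrugation lobes around the azimuth.
#' @param opening_deg Half-angle (degrees) of the removed polar cap that opens
#'   the sac.
#' @param csf_radius_mm Radius of the CSF pocket inside each sac (0 disables).
#' @param background_poly_coeffs Named coefficients (Hz) of the harmonic
#'   polynomial background field over coordinates normalized to the half
#'   field of view: `x, y, z, xy, xz, yz, x2y2` (x^2-y^2), `z2` (2z^2-x^2-y^2).
#' @param external_source_positions Matrix (k x 3) of point-dipole background
#'   source positions in mm (outside the brain mask).
#' @param external_source_strengths Strengths (Hz mm^3) of those sources.
#' @param r2star_tissue,r2star_wall,r2star_interior,r2star_csf,r2star_outside
#'   Per-compartment R2* (1/s).
#' @param s0_brain,s0_outside Proton-density magnitude inside/outside brain.
#' @param noise_sigma Complex Gaussian noise sd per channel for simulated
#'   echoes (default s0/40, i.e. SNR 40).
#' @param seed RNG seed for reproducibility of any randomized element.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_shape = c(80, 80, 80),
                         voxel_size_mm = 0.5,
                         wall_chi_ppb = 100,
                         interior_chi_ppb = 40,
                         tissue_chi_ppb = 0,
                         brain_radii_mm = c(15, 15, 15),
                         shell_center_mm = c(5.8, 0, -1),
                         shell_radii_mm = c(3.8, 3.2, 2.8),
                         wall_thickness_mm = 1.0,
                         corrugation_amplitude_mm = 0.3,
                         corrugation_lobes = 6,
                         opening_deg = 50,
                         csf_radius_mm = 1.1,
                         background_poly_coeffs = c(x = 3, y = -2, z = 4,
                                                    xy = 2, xz = -1.5, yz = 1,
                                                    x2y2 = 2.5, z2 = 2),
                         external_source_positions =
                           rbind(c(0, 0, 18), c(14, -4, -16)),
                         external_source_strengths = c(1500, -1200),
                         r2star_tissue = 20, r2star_wall = 35,
                         r2star_interior = 28, r2star_csf = 4,
                         r2star_outside = 1,
                         s0_brain = 1, s0_outside = 0.05,
                         noise_sigma = 0.025,
                         seed = 1L) {
  spec <- as.list(environment())
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 16))
    stop("grid_shape must have 3 entries, all >= 16")
  if (spec$voxel_size_mm <= 0) stop("voxel_size_mm must be > 0")
  if (spec$wall_thickness_mm >= min(spec$shell_radii_mm))
    stop("wall_thickness_mm must be smaller than the smallest shell radius")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  fov_half <- spec$grid_shape * spec$voxel_size_mm / 2
  ext <- abs(spec$shell_center_mm) + spec$shell_radii_mm +
    spec$wall_thickness_mm / 2 + spec$corrugation_amplitude_mm
  for (a in 1:3) {
    if (ext[a] > fov_half[a])
      stop(sprintf("shell exceeds the grid along axis %d (%s)", a,
                   c("x", "y", "z")[a]))
  }
  structure(spec, class = "phantom_spec")
}

# evaluate the harmonic polynomial + external dipole background field (Hz)
background_field <- function(spec) {
  d <- spec$grid_shape
  cc <- grid_coords_mm(d, spec$voxel_size_mm)
  co <- coord_arrays(cc, d)
  half <- d * spec$voxel_size_mm / 2
  nx <- co$x / half[1]; ny <- co$y / half[2]; nz <- co$z / half[3]
  p <- spec$background_poly_coeffs
  g <- function(nm) if (nm %in% names(p)) as.numeric(p[[nm]]) else 0
  bg <- g("x") * nx + g("y") * ny + g("z") * nz +
    g("xy") * nx * ny + g("xz") * nx * nz + g("yz") * ny * nz +
    g("x2y2") * (nx^2 - ny^2) + g("z2") * (2 * nz^2 - nx^2 - ny^2)
  pos <- spec$external_source_positions
  if (!is.null(pos) && NROW(pos) > 0) {
    for (k in seq_len(NROW(pos))) {
      dx <- co$x - pos[k, 1]; dy <- co$y - pos[k, 2]; dz <- co$z - pos[k, 3]
      r2 <- dx^2 + dy^2 + dz^2
      r2[r2 < 1e-6] <- 1e-6
      bg <- bg + spec$external_source_strengths[k] *
        (3 * dz^2 - r2) / r2^2.5
    }
  }
  bg
}

#' Build the ground-truth dentate phantom
#'
#' Generates the true susceptibility map, the silhouette (shell) and bulk
#' (filled, eroded sac) dentate masks with left/right labels, brain mask,
#' true R2* map, and the true frequency map (internal dipole field of the
#' susceptibility distribution plus the harmonic background).
#'
#' @param spec A [phantom_spec()].
#' @return A `dn_ground_truth` object with elements `chi_ppb`, `dn_sil`,
#'   `dn_bulk`, `brain_mask`, `r2star`, `s0`, `field_internal_hz`,
#'   `field_background_hz`, `field_true_hz`, `voxel_size_mm`, `spec`.
#'   Mask arrays carry labels 0 (outside), 1 (left), 2 (right).
#' @export
make_dentate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size_mm
  cc <- grid_coords_mm(d, vs)
  co <- coord_arrays(cc, d)

  brain <- (co$x / spec$brain_radii_mm[1])^2 +
    (co$y / spec$brain_radii_mm[2])^2 +
    (co$z / spec$brain_radii_mm[3])^2 <= 1

  rbar <- mean(spec$shell_radii_mm)
  hhalf <- spec$wall_thickness_mm / (2 * rbar)
  amp <- spec$corrugation_amplitude_mm / rbar
  cos_open <- cos(spec$opening_deg * pi / 180)

  sil <- array(0L, dim = d)
  fill <- array(0L, dim = d)
  csf <- array(FALSE, dim = d)
  for (side in 1:2) { # 1 = left (x < 0), 2 = right
    sgn <- if (side == 2) 1 else -1
    ux <- (sgn * co$x - spec$shell_center_mm[1]) / spec$shell_radii_mm[1]
    uy <- (co$y - spec$shell_center_mm[2]) / spec$shell_radii_mm[2]
    uz <- (co$z - spec$shell_center_mm[3]) / spec$shell_radii_mm[3]
    rho <- sqrt(ux^2 + uy^2 + uz^2)
    rho_safe <- pmax(rho, 1e-9)
    cos_pol <- uz / rho_safe
    sin_pol <- sqrt(pmax(0, 1 - cos_pol^2))
    az <- atan2(uy, ux)
    rho0 <- 1 + amp * sin(spec$corrugation_lobes * az) * sin_pol
    open_ok <- cos_pol <= cos_open
    sh <- abs(rho - rho0) <= hhalf & open_ok
    fl <- rho <= rho0 + hhalf & uz <= cos_open * (1 + hhalf)
    sil[sh] <- side
    fill[fl] <- side
    if (spec$csf_radius_mm > 0) {
      ctr <- spec$shell_center_mm * c(sgn, 1, 1)
      csf <- csf | ((co$x - ctr[1])^2 + (co$y - ctr[2])^2 +
                      (co$z - ctr[3])^2 <= spec$csf_radius_mm^2)
    }
  }
  sil[!brain] <- 0L
  fill[!brain] <- 0L

  chi <- array(spec$tissue_chi_ppb, dim = d)
  chi[!brain] <- 0
  chi[fill > 0] <- spec$interior_chi_ppb
  chi[sil > 0] <- spec$wall_chi_ppb
  chi[csf] <- 0

  r2 <- array(spec$r2star_outside, dim = d)
  r2[brain] <- spec$r2star_tissue
  r2[fill > 0] <- spec$r2star_interior
  r2[sil > 0] <- spec$r2star_wall
  r2[csf] <- spec$r2star_csf

  s0 <- array(spec$s0_outside, dim = d)
  s0[brain] <- spec$s0_brain

  bulk <- fill
  er <- erode_box3(fill > 0)
  bulk[!er] <- 0L
  bulk[csf] <- 0L

  f_int <- forward_field(chi, vs)
  f_bg <- background_field(spec)

  structure(list(
    chi_ppb = chi,
    dn_sil = sil,
    dn_bulk = bulk,
    brain_mask = brain,
    csf_mask = csf,
    r2star = r2,
    s0 = s0,
    field_internal_hz = f_int,
    field_background_hz = f_bg,
    field_true_hz = f_int + f_bg,
    voxel_size_mm = vs,
    spec = spec
  ), class = "dn_ground_truth")
}

#' @export
print.dn_ground_truth <- function(x, ...) {
  cat("Dentate ground-truth phantom:",
      paste(dim(x$chi_ppb), collapse = "x"), "grid,",
      x$voxel_size_mm, "mm voxels\n")
  cat(sprintf("  DN_sil %d voxels, DN_bulk %d voxels, brain %d voxels\n",
              sum(x$dn_sil > 0), sum(x$dn_bulk > 0), sum(x$brain_mask)))
  invisible(x)
}

#' Simulate the multi-echo acquisition of a phantom
#'
#' Convenience wrapper: synthesizes the echo series of a ground-truth phantom
#' from its total field (internal + background), compartment R2* and proton
#' density, at the noise level of its spec.
#'
#' @param truth A `dn_ground_truth` object.
#' @param tes_s Echo times in seconds.
#' @param phi0 Global phase offset (radians).
#' @param noise_sigma Noise sd; defaults to the phantom's value.
#' @param seed RNG seed; defaults to the phantom's seed.
#' @return An `echo_series`.
#' @export
simulate_acquisition <- function(truth, tes_s = qsm_default_tes(), phi0 = 0,
                                 noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(truth, "dn_ground_truth"))
  if (is.null(noise_sigma)) noise_sigma <- truth$spec$noise_sigma
  if (is.null(seed)) seed <- truth$spec$seed
  synthesize_echoes(truth$field_true_hz, s0 = truth$s0, r2star = truth$r2star,
                    tes_s = tes_s, phi0 = phi0, noise_sigma = noise_sigma,
                    seed = seed, voxel_size_mm = truth$voxel_size_mm)
}
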