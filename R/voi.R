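#' Convex-hull half-spaces of a 3D point set
#'
#' Incremental 3D convex hull; returns the facet half-space representation
#' (unit outward normals and offsets), so a point `x` lies in the hull iff
#' `normals %*% x <= offsets + tol` for every facet (boundary-inclusive).
#'
#' @param points Numeric matrix (n x 3), n >= 4 non-coplanar points.
#' @return List with `normals` (K x 3), `offsets` (K), `scale`.
#' @export
convex_hull_facets <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  res <- convhull3_facets_cpp(points)
  if (!isTRUE(res$ok)) stop("degenerate hull: ", res$message)
  res
}

#' Point-in-hull membership test
#'
#' @param points Numeric matrix (m x 3) of query points.
#' @param facets Result of [convex_hull_facets()].
#' @param tol Boundary tolerance (relative to the hull scale).
#' @return Logical vector of length m (boundary counts as inside).
#' @export
point_in_hull <- function(points, facets, tol = 1e-7) {
  points <- as.matrix(points)
  viol <- points %*% t(facets$normals) -
    matrix(facets$offsets, nrow(points), length(facets$offsets), byrow = TRUE)
  apply(viol <= tol * facets$scale, 1, all)
}

#' Assign left/right hemisphere labels to a dentate mask
#'
#' Labels each 26-connected component of the mask left (1) or right (2) by
#' the position of its centroid relative to the mid-sagittal plane of the
#' brain mask (the plane through the brain-mask centroid along the first
#' array axis).  A component straddling the midline is assigned to the side
#' holding the majority of its voxels, with a warning.
#'
#' @param mask Logical or 0/1 3D array (the dentate silhouette or similar).
#' @param brain_mask Logical 3D array defining the midline.
#' @param voxel_size_mm Voxel spacing carried to the result.
#' @param kind `"sil"` or `"bulk"` label recorded on the result.
#' @return A `dn_mask` object: `labels` array (0/1 = left/2 = right),
#'   `kind`, `voxel_size_mm`.
#' @export
split_hemispheres <- function(mask, brain_mask, voxel_size_mm = 0.5,
                              kind = "sil") {
  d <- dim(mask)
  m <- mask > 0
  if (!any(m)) stop("mask is empty")
  lab <- array(label_components_cpp(m, as.integer(d), 26L), dim = d)
  idx <- which(brain_mask)
  bx <- mean(((idx - 1) %% d[1]) + 1)
  labels <- array(0L, dim = d)
  for (comp in seq_len(max(lab))) {
    vox <- which(lab == comp)
    cx <- ((vox - 1) %% d[1]) + 1
    n_left <- sum(cx < bx)
    n_right <- sum(cx >= bx)
    if (n_left > 0 && n_right > 0)
      warning(sprintf(
        "component %d straddles the midline (%d left / %d right voxels); %s",
        comp, n_left, n_right,
        if (n_left >= n_right) "assigned left" else "assigned right"))
    labels[vox] <- if (n_left >= n_right) 1L else 2L
  }
  structure(list(labels = labels, kind = kind,
                 voxel_size_mm = voxel_size_mm),
            class = "dn_mask")
}

#' @export
print.dn_mask <- function(x, ...) {
  cat(sprintf("DN_%s mask: %d left / %d right voxels (%g mm voxels)\n",
              x$kind, sum(x$labels == 1), sum(x$labels == 2),
              x$voxel_size_mm))
  invisible(x)
}

#' Build the dentate bulk VOI from the silhouette
#'
#' Per hemisphere: (1) convex hull of the silhouette voxel centers;
#' (2) rasterization (a voxel belongs to the hull if its center lies inside,
#' boundary-inclusive); (3) one binary erosion with a 3x3x3 box kernel
#' (out-of-grid neighbours count as background); (4) exclusion of voxels
#' with `R2* < r2star_min` (CSF correction).  The result is the bulk of the
#' iron-rich dentate region enclosed by the traced walls.
#'
#' @param dn_sil A `dn_mask` (kind `"sil"`) with hemisphere labels, or a
#'   labeled array (1 = left, 2 = right).
#' @param r2star 3D array of R2* (1/s); NULL skips the CSF exclusion.
#' @param r2star_min CSF exclusion threshold (default 15 1/s).
#' @param voxel_size_mm Voxel spacing (taken from `dn_sil` if present).
#' @param override Optional externally edited bulk label array; when given
#'   it replaces the automatic result (manual-correction hook).
#' @return A `dn_mask` of kind `"bulk"` with hemisphere labels.
#' @export
build_dn_bulk <- function(dn_sil, r2star = NULL, r2star_min = 15,
                          voxel_size_mm = NULL, override = NULL) {
  if (inherits(dn_sil, "dn_mask")) {
    if (is.null(voxel_size_mm)) voxel_size_mm <- dn_sil$voxel_size_mm
    labels <- dn_sil$labels
  } else {
    if (is.null(voxel_size_mm)) voxel_size_mm <- 0.5
    labels <- dn_sil
  }
  d <- dim(labels)
  if (!is.null(override)) {
    return(structure(list(labels = override, kind = "bulk",
                          voxel_size_mm = voxel_size_mm), class = "dn_mask"))
  }
  out <- array(0L, dim = d)
  for (side in sort(unique(labels[labels > 0]))) {
    vox <- which(labels == side)
    if (length(vox) < 4)
      stop(sprintf("hemisphere %s: fewer than 4 silhouette voxels",
                   c("left", "right")[side]))
    pts <- cbind(((vox - 1) %% d[1]) + 1,
                 ((vox - 1) %/% d[1]) %% d[2] + 1,
                 ((vox - 1) %/% (d[1] * d[2])) + 1)
    facets <- tryCatch(convex_hull_facets(pts), error = function(e)
      stop(sprintf("hemisphere %s: %s", c("left", "right")[side],
                   conditionMessage(e)), call. = FALSE))
    # rasterize over the bounding box only
    rng <- apply(pts, 2, range)
    xs <- rng[1, 1]:rng[2, 1]
    ys <- rng[1, 2]:rng[2, 2]
    zs <- rng[1, 3]:rng[2, 3]
    grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    inside <- point_in_hull(grid, facets)
    hull <- array(FALSE, dim = d)
    hull[grid[inside, , drop = FALSE]] <- TRUE
    er <- erode_box3(hull)
    if (!is.null(r2star)) er <- er & !(r2star < r2star_min) & !is.na(r2star)
    if (!any(er))
      warning(sprintf("hemisphere %s: bulk mask empty after erosion/CSF %s",
                      c("left", "right")[side], "exclusion"))
    out[er] <- side
  }
  structure(list(labels = out, kind = "bulk", voxel_size_mm = voxel_size_mm),
            class = "dn_mask")
}

#' VOI metrics: volume, mean susceptibility, susceptibility mass
#'
#' Volume is the voxel count times the voxel volume, summed across
#' hemispheres; mean susceptibility is taken over all mask voxels; the
#' susceptibility mass is the non-normalized volume (in cm^3) times the mean
#' susceptibility (ppb), in ppb cm^3 — a proxy for total iron content
#' rather than concentration.
#'
#' @param chi 3D susceptibility array (ppb), or a list with `chi_ppb`.
#' @param mask A `dn_mask` or a labeled array (1 = left, 2 = right).
#' @param voxel_size_mm Voxel spacing (taken from the mask if present).
#' @return List with `volume_mm3`, `mean_chi_ppb`, `chi_mass_ppb_cm3`,
#'   `n_voxels`, and a per-hemisphere data frame `hemispheres`.
#' @export
voi_metrics <- function(chi, mask, voxel_size_mm = NULL) {
  if (is.list(chi) && !is.null(chi$chi_ppb)) chi <- chi$chi_ppb
  if (inherits(mask, "dn_mask")) {
    if (is.null(voxel_size_mm)) voxel_size_mm <- mask$voxel_size_mm
    labels <- mask$labels
  } else {
    if (is.null(voxel_size_mm)) voxel_size_mm <- 0.5
    labels <- mask
  }
  vvol <- voxel_size_mm^3
  if (!any(labels > 0)) {
    warning("empty mask: metrics are NaN")
    return(list(volume_mm3 = NaN, mean_chi_ppb = NaN,
                chi_mass_ppb_cm3 = NaN, n_voxels = 0L,
                hemispheres = data.frame()))
  }
  if (any(!is.finite(chi[labels > 0])))
    stop("chi must be finite on the mask")
  hemi <- do.call(rbind, lapply(sort(unique(labels[labels > 0])),
    function(side) {
      sel <- labels == side
      n <- sum(sel)
      v <- n * vvol
      mc <- mean(chi[sel])
      data.frame(hemisphere = c("left", "right")[side], n_voxels = n,
                 volume_mm3 = v, mean_chi_ppb = mc,
                 chi_mass_ppb_cm3 = v / 1000 * mc)
    }))
  n <- sum(labels > 0)
  vol <- n * vvol
  mc <- mean(chi[labels > 0])
  list(volume_mm3 = vol, mean_chi_ppb = mc,
       chi_mass_ppb_cm3 = vol / 1000 * mc, n_voxels = n,
       hemispheres = hemi)
}
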