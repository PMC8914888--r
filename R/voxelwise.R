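#' Separable 3D Gaussian smoothing
#'
#' Kernel sigma per axis is `fwhm / (2 sqrt(2 ln 2))` in mm, converted to
#' voxels; the discrete kernel is truncated at 4 sigma and normalized to
#' sum 1, with replicated edges, so constant maps are exactly invariant.
#' `fwhm_mm = 0` is the identity.
#'
#' @param vol 3D array.
#' @param fwhm_mm Full width at half maximum in mm (>= 0).
#' @param voxel_size_mm Voxel spacing (scalar or length 3).
#' @return Smoothed 3D array.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 1, voxel_size_mm = 0.5) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  vs <- rep_len(voxel_size_mm, 3)
  d <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs[ax]
    r <- max(1L, ceiling(4 * sigma_vox))
    k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
    k <- k / sum(k)
    acc <- array(0, dim = d)
    n <- d[ax]
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      acc <- acc + k[j + r + 1] * switch(ax,
        out[idx, , , drop = FALSE],
        out[, idx, , drop = FALSE],
        out[, , idx, drop = FALSE])
    }
    out <- acc
  }
  out
}

# stack a list of 3D maps (or 4D array) into a subjects x voxels matrix
maps_to_matrix <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 4) {
    d <- dim(maps)[1:3]
    y <- t(matrix(maps, prod(d), dim(maps)[4]))
  } else {
    d <- dim(maps[[1]])
    for (m in maps) if (!identical(dim(m), d))
      stop("maps are not on a common grid")
    y <- do.call(rbind, lapply(maps, as.numeric))
  }
  list(Y = y, dim = d)
}

# vectorized GLM t-statistics for one design column across all voxels
glm_tmap <- function(Y, X, col) {
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  dfres <- nrow(X) - ncol(X)
  mse <- colSums(res^2) / dfres
  se <- sqrt(mse * XtXi[col, col])
  t <- as.numeric(B[col, ]) / pmax(se, 1e-300)
  t[se == 0] <- 0
  list(t = t, beta = as.numeric(B[col, ]), df = dfres)
}

#' Voxelwise group-difference map with age covariate
#'
#' Per-voxel GLM `value ~ group + age` over the two groups; returns the
#' group-contrast t map (patients > controls) and the raw mean-difference
#' map.
#'
#' @param patient_maps,control_maps Lists of 3D arrays (or 4D arrays) on a
#'   common grid.
#' @param ages Numeric vector, patients first then controls.
#' @param mask Optional logical analysis mask; statistics are zero outside.
#' @return List with `t_map`, `mean_diff`, `mask`, `contrast`, `df`.
#' @export
groupdiff_map <- function(patient_maps, control_maps, ages, mask = NULL) {
  mp <- maps_to_matrix(patient_maps)
  mc <- maps_to_matrix(control_maps)
  if (!identical(mp$dim, mc$dim)) stop("maps are not on a common grid")
  np <- nrow(mp$Y); nc <- nrow(mc$Y)
  if (np < 2 || nc < 2) stop("need >= 2 subjects per group")
  if (length(ages) != np + nc) stop("ages must cover all subjects")
  d <- mp$dim
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  Y <- rbind(mp$Y, mc$Y)
  X <- cbind(1, c(rep(1, np), rep(0, nc)), ages - mean(ages))
  g <- glm_tmap(Y, X, 2L)
  tm <- array(g$t, dim = d)
  md <- array(colMeans(mp$Y) - colMeans(mc$Y), dim = d)
  tm[!mask] <- 0
  md[!mask] <- 0
  list(t_map = tm, mean_diff = md, mask = mask,
       contrast = "patients>controls", df = g$df)
}

#' TFCE configuration
#'
#' @param height_exponent H (default 2).
#' @param extent_exponent E (default 0.5).
#' @param dh Threshold step; NULL selects `max(stat)/100`.
#' @param connectivity Cluster connectivity: 6, 18 or 26 (default).
#' @return A `tfce_config` object.
#' @export
tfce_config <- function(height_exponent = 2, extent_exponent = 0.5,
                        dh = NULL, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (height_exponent < 0 || extent_exponent < 0)
    stop("exponents must be >= 0")
  if (!is.null(dh) && dh <= 0) stop("dh must be > 0")
  structure(list(height_exponent = height_exponent,
                 extent_exponent = extent_exponent, dh = dh,
                 connectivity = connectivity), class = "tfce_config")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, integrates `extent(h)^E * h^H * dh` over thresholds `h`,
#' where `extent(h)` is the size of the supra-threshold cluster supporting
#' the voxel at height `h`.  Negative values are enhanced by applying TFCE
#' to the negated map separately; the returned map carries both signs.
#'
#' @param stat_map 3D statistic array.
#' @param cfg A [tfce_config()].
#' @param dh Threshold step; overrides `cfg$dh` (useful to keep the step
#'   fixed across permutations).  NULL selects `max(|stat|)/100`.
#' @return 3D array of signed TFCE scores.
#' @export
tfce_enhance <- function(stat_map, cfg = tfce_config(), dh = NULL) {
  d <- dim(stat_map)
  explicit <- !is.null(dh)
  if (is.null(dh)) dh <- cfg$dh
  mx <- max(abs(stat_map))
  if (mx == 0) return(array(0, dim = d))
  if (is.null(dh)) dh <- mx / 100
  if (!explicit && mx / dh < 20)
    stop("dh too coarse: must resolve >= 20 steps over the map's range")
  pos <- pmax(stat_map, 0)
  neg <- pmax(-stat_map, 0)
  out <- tfce_cpp(as.numeric(pos), as.integer(d), dh,
                  cfg$extent_exponent, cfg$height_exponent,
                  as.integer(cfg$connectivity))
  if (any(neg > 0))
    out <- out - tfce_cpp(as.numeric(neg), as.integer(d), dh,
                          cfg$extent_exponent, cfg$height_exponent,
                          as.integer(cfg$connectivity))
  array(out, dim = d)
}

# shared permutation engine: Freedman-Lane residual permutation of Y under
# the reduced model, TFCE of the effect t-map, max-statistic FWE correction
permute_tfce_fwe <- function(Y, X, col, Xred, d, mask, n_perm, cfg, seed) {
  set.seed(seed)
  obs <- glm_tmap(Y, X, col)
  t_obs <- array(obs$t, dim = d)
  t_obs[!mask] <- 0
  dh <- max(abs(t_obs)) / 100
  if (dh == 0) dh <- 1 # degenerate all-zero map; enhancement stays zero
  enh <- tfce_enhance(t_obs, cfg, dh = dh)
  enh_pos <- pmax(enh, 0)
  enh_neg <- pmax(-enh, 0)
  # reduced-model fit (covariates only)
  XrXi <- solve(crossprod(Xred))
  Br <- XrXi %*% crossprod(Xred, Y)
  fit_r <- Xred %*% Br
  res_r <- Y - fit_r
  n <- nrow(Y)
  max_pos <- max_neg <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    pm <- sample.int(n)
    Yp <- fit_r + res_r[pm, , drop = FALSE]
    g <- glm_tmap(Yp, X, col)
    tp <- array(g$t, dim = d)
    tp[!mask] <- 0
    ep <- tfce_enhance(tp, cfg, dh = dh)
    max_pos[j] <- max(ep[mask], 0)
    max_neg[j] <- max(-ep[mask], 0)
  }
  p_pos <- array(1, dim = d)
  p_neg <- array(1, dim = d)
  iv <- which(mask)
  p_pos[iv] <- (1 + vapply(enh_pos[iv], function(v) sum(max_pos >= v),
                           numeric(1))) / (n_perm + 1)
  p_neg[iv] <- (1 + vapply(enh_neg[iv], function(v) sum(max_neg >= v),
                           numeric(1))) / (n_perm + 1)
  list(t_map = t_obs, tfce_map = enh, p_fwe_pos = p_pos, p_fwe_neg = p_neg,
       null_max_pos = max_pos, null_max_neg = max_neg, n_perm = n_perm,
       seed = seed, mask = mask, dh = dh)
}

#' Permutation test of a voxelwise group difference with TFCE and FWE
#'
#' Voxelwise GLM `value ~ group + age`; inference by Freedman-Lane
#' permutation of the reduced-model (age-only) residuals, enhancing each
#' permuted t map with TFCE and recording the maximum statistic, which
#' yields family-wise-error-corrected p maps
#' `p(v) = (1 + #\{perm max >= observed(v)\}) / (n_perm + 1)`.
#' Positive (patients > controls) and negative contrasts are tested
#' separately, each against its own max-statistic null.
#'
#' @param patient_maps,control_maps Lists of 3D arrays (or 4D arrays).
#' @param ages Numeric vector, patients first then controls.
#' @param n_perm Number of permutations (>= 100 for a meaningful p floor).
#' @param cfg A [tfce_config()].
#' @param mask Logical analysis mask (e.g. the dentate template mask).
#' @param seed RNG seed (permutations are reproducible).
#' @return List with `t_map`, `tfce_map`, `p_fwe_pos`, `p_fwe_neg`,
#'   `null_max_pos`, `null_max_neg`, `n_perm`, `seed`, `mask`, `dh`.
#' @export
permutation_fwe <- function(patient_maps, control_maps, ages, n_perm = 1000,
                            cfg = tfce_config(), mask = NULL, seed = 1) {
  mp <- maps_to_matrix(patient_maps)
  mc <- maps_to_matrix(control_maps)
  if (!identical(mp$dim, mc$dim)) stop("maps are not on a common grid")
  np <- nrow(mp$Y); nc <- nrow(mc$Y)
  if (np < 2 || nc < 2) stop("groups of size < 2 are not permutable")
  d <- mp$dim
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  Y <- rbind(mp$Y, mc$Y)
  X <- cbind(1, c(rep(1, np), rep(0, nc)), ages - mean(ages))
  Xred <- X[, c(1, 3), drop = FALSE]
  permute_tfce_fwe(Y, X, 2L, Xred, d, mask, n_perm, cfg, seed)
}

#' Voxelwise score correlation with TFCE and FWE
#'
#' Voxelwise GLM `value ~ score + age` (score residualized against age so
#' the permuted quantity is exchangeable under the null); permutation of
#' the score residuals with TFCE max-statistic FWE correction, as in
#' [permutation_fwe()].
#'
#' @param maps List of 3D arrays (or 4D array), one per subject.
#' @param scores Numeric score (e.g. SARA), non-constant.
#' @param ages Numeric covariate.
#' @param n_perm Number of permutations.
#' @param cfg A [tfce_config()].
#' @param mask Logical analysis mask.
#' @param seed RNG seed.
#' @return As [permutation_fwe()].
#' @export
voxelwise_correlation <- function(maps, scores, ages, n_perm = 1000,
                                  cfg = tfce_config(), mask = NULL,
                                  seed = 1) {
  mm <- maps_to_matrix(maps)
  n <- nrow(mm$Y)
  if (n < 5) stop("need >= 5 subjects")
  if (stats::sd(scores) == 0) stop("constant score")
  d <- mm$dim
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  age_c <- ages - mean(ages)
  s_res <- resid(stats::lm(scores ~ age_c))
  X <- cbind(1, s_res, age_c)
  Xred <- X[, c(1, 3), drop = FALSE]
  permute_tfce_fwe(mm$Y, X, 2L, Xred, d, mask, n_perm, cfg, seed)
}
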