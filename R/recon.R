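#' Edge-preserving denoising of complex multi-echo data
#'
#' Applies an edge-preserving 3x3x3 median filter to the real and imaginary
#' channels of each echo independently; `strength` is the number of filter
#' passes (rounded), and 0 is the identity.  Median filtering leaves the
#' interior of piecewise-constant regions untouched while reducing noise
#' variance, which is the property the reconstruction needs; the filter is
#' off the quantitative acceptance path and can be disabled.
#'
#' @param echoes An `echo_series`.
#' @param strength Number of filter passes (>= 0).
#' @return A denoised `echo_series`.
#' @export
denoise_complex <- function(echoes, strength = 1) {
  stopifnot(inherits(echoes, "echo_series"))
  if (strength < 0) stop("strength must be >= 0")
  passes <- round(strength)
  if (passes == 0) return(echoes)
  d <- echoes$dim
  for (i in seq_along(echoes$tes_s)) {
    re <- echoes$magnitude[[i]] * cos(echoes$phase[[i]])
    im <- echoes$magnitude[[i]] * sin(echoes$phase[[i]])
    for (p in seq_len(passes)) {
      re <- array(median3_cpp(re, d), dim = d)
      im <- array(median3_cpp(im, d), dim = d)
    }
    z <- complex(real = re, imaginary = im)
    echoes$magnitude[[i]] <- array(Mod(z), dim = d)
    echoes$phase[[i]] <- array(wrap_phase(Arg(z)), dim = d)
  }
  echoes
}

#' Quality-guided 3D phase unwrapping
#'
#' Region-growing ("best path") unwrapping: voxel quality is the negated sum
#' of squared wrapped second differences of the wrapped phase along the three
#' axes; growth proceeds through 6-connected neighbours, always unwrapping
#' the highest-quality candidate next (ties broken by linear voxel index for
#' determinism).  Each connected component of the mask is unwrapped
#' independently, so the result is defined up to one global 2*pi*k offset
#' per component.
#'
#' @param wrapped_phase 3D array of wrapped phase in (-pi, pi].
#' @param mask Logical 3D array; voxels outside are returned unchanged.
#' @return 3D array of unwrapped phase.
#' @export
unwrap_phase_3d <- function(wrapped_phase, mask) {
  d <- dim(wrapped_phase)
  if (length(d) != 3) stop("wrapped_phase must be a 3D array")
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (!any(mask)) stop("mask is empty")
  out <- unwrap_bestpath_cpp(as.numeric(wrapped_phase),
                             as.logical(mask), as.integer(d))
  array(out, dim = d)
}

#' Combine per-echo phases into a frequency map
#'
#' Per-echo frequency `f_i = phi_i / (2 pi TE_i)`; the combined map is the
#' per-voxel weighted average with weights `w_i = (magnitude_i * TE_i)^2`
#' (the SNR-optimal weighting for frequency estimation from a decaying
#' signal).  A temporal-consistency pass precedes the combination: each
#' echo's unwrapped phase is shifted by the multiple of 2*pi that best
#' matches the prediction from the earlier echoes, enforcing one 2*pi
#' convention across echoes.
#'
#' @param unwrapped_phases List of 3D arrays (one per echo), spatially
#'   unwrapped.
#' @param tes_s Echo times in seconds.
#' @param magnitudes List of magnitude arrays (weights); NULL gives equal
#'   weights.
#' @param mask Optional logical array restricting the output.
#' @return List with `freq_hz` (3D array), `mask`, and `single_echo`
#'   (TRUE when only one echo was available, with a warning).
#' @export
echoes_to_frequency <- function(unwrapped_phases, tes_s, magnitudes = NULL,
                                mask = NULL) {
  ne <- length(unwrapped_phases)
  if (ne < 1) stop("need at least one echo")
  if (length(tes_s) != ne) stop("tes_s length must match number of echoes")
  d <- dim(unwrapped_phases[[1]])
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (is.null(magnitudes)) magnitudes <- rep(list(array(1, dim = d)), ne)
  single <- ne == 1
  if (single) {
    warning("single echo: returning f = phi / (2 pi TE) with no combination")
    return(list(freq_hz = unwrapped_phases[[1]] / (2 * pi * tes_s[1]) *
                  ifelse(mask, 1, 0),
                mask = mask, single_echo = TRUE))
  }
  w <- lapply(seq_len(ne), function(i) (magnitudes[[i]] * tes_s[i])^2)
  phi <- unwrapped_phases
  # temporal consistency: running weighted frequency estimate
  num <- w[[1]] * phi[[1]] / (2 * pi * tes_s[1])
  den <- w[[1]]
  for (i in 2:ne) {
    f_est <- num / pmax(den, 1e-30)
    pred <- 2 * pi * f_est * tes_s[i]
    k <- round((pred - phi[[i]]) / (2 * pi))
    phi[[i]] <- phi[[i]] + 2 * pi * k
    num <- num + w[[i]] * phi[[i]] / (2 * pi * tes_s[i])
    den <- den + w[[i]]
  }
  freq <- num / pmax(den, 1e-30)
  freq[!mask] <- 0
  list(freq_hz = freq, mask = mask, single_echo = FALSE)
}

#' Fit R2* from multi-echo magnitude decay
#'
#' Per-voxel weighted least-squares fit of `log|S|` against TE with weights
#' `|S|^2` (so late, noise-dominated echoes contribute little);
#' `R2* = -slope`, with negative slopes clipped to zero and flagged in the
#' quality map.  Voxels with any zero magnitude are excluded (NaN).
#'
#' @param echoes An `echo_series` with at least 3 echoes.
#' @param mask Optional logical array; voxels outside are NaN.
#' @return List with `r2star` (1/s), `r_squared` (weighted fit quality),
#'   and `clipped` (logical array of clipped negative slopes).
#' @export
fit_r2star <- function(echoes, mask = NULL) {
  stopifnot(inherits(echoes, "echo_series"))
  tes <- echoes$tes_s
  if (length(tes) < 3) stop("need >= 3 echoes for a slope with quality")
  d <- echoes$dim
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  zero <- Reduce(`|`, lapply(echoes$magnitude, function(m) m <= 0))
  ok <- mask & !zero
  sw <- swx <- swy <- swxx <- swxy <- swyy <- array(0, dim = d)
  for (i in seq_along(tes)) {
    m <- echoes$magnitude[[i]]
    y <- log(pmax(m, 1e-300))
    w <- m^2
    sw <- sw + w
    swx <- swx + w * tes[i]
    swy <- swy + w * y
    swxx <- swxx + w * tes[i]^2
    swxy <- swxy + w * tes[i] * y
    swyy <- swyy + w * y^2
  }
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  r2star <- -slope
  clipped <- ok & (r2star < 0)
  r2star[r2star < 0] <- 0
  # weighted R^2 of the log-linear fit
  ybar <- swy / sw
  sstot <- swyy - sw * ybar^2
  ssreg <- slope^2 * (swxx - swx^2 / sw)
  rsq <- ifelse(sstot > 0, pmin(1, ssreg / sstot), 1)
  r2star[!ok] <- NaN
  rsq[!ok] <- NaN
  list(r2star = r2star, r_squared = rsq, clipped = clipped)
}
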