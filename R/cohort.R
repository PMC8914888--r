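#' Specification of a synthetic two-group cohort
#'
#' Parameterizes a patient/control cohort of dentate phantoms with
#' controllable group effects: a shift of the dentate susceptibility
#' (`delta_chi_ppb`, applied uniformly to wall and interior so the expected
#' patient-control difference in true bulk mean susceptibility equals the
#' parameter exactly), a multiplicative dentate-volume factor for patients,
#' a linear volume-TIV relationship, and a clinical severity (SARA) model
#' for patients.  Defaults follow the group sizes and effect magnitudes of
#' a 16-versus-16 ataxia subgroup: susceptibility difference +39 ppb,
#' patient volume factor 0.78, TIV 1546 +/- 135 cm^3; per-subject
#' dispersions (`chi_sd_ppb`, `volume_noise_sd`) are synthetic choices on
#' the scale of reported between-subject standard deviations.
#'
#' @param n_patients,n_controls Group sizes (each >= 2).
#' @param delta_chi_ppb Patient-minus-control shift of dentate
#'   susceptibility (ppb).
#' @param volume_scale Multiplicative dentate-volume factor for patients.
#' @param chi_sd_ppb Between-subject sd of the dentate susceptibility shift.
#' @param volume_noise_sd Between-subject sd of dentate volume (mm^3) beyond
#'   the TIV component.
#' @param tiv_mean_cm3,tiv_sd_cm3 Total intracranial volume distribution.
#' @param volume_tiv_slope Dentate volume change per cm^3 of TIV (mm^3/cm^3).
#' @param age_range_years Uniform age range for both groups.
#' @param sara_model List: `intercept`, `slope_volume` (per mm^3 deviation
#'   from the nominal patient volume), `slope_chi` (per ppb deviation),
#'   `slope_age` (per year from the mid-range), `sd` (noise). SARA is
#'   clipped to the 0-40 range; controls get near-zero scores.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 16, n_controls = 16,
                        delta_chi_ppb = 39, volume_scale = 0.78,
                        chi_sd_ppb = 30, volume_noise_sd = 25,
                        tiv_mean_cm3 = 1546, tiv_sd_cm3 = 135,
                        volume_tiv_slope = 0.15,
                        age_range_years = c(31.6, 68.3),
                        sara_model = list(intercept = 14,
                                          slope_volume = -0.05,
                                          slope_chi = 0.05,
                                          slope_age = 0.1, sd = 4),
                        seed = 1L) {
  spec <- as.list(environment())
  if (spec$n_patients < 2 || spec$n_controls < 2)
    stop("need n >= 2 per group (the statistics downstream require it)")
  if (spec$tiv_sd_cm3 <= 0) stop("tiv_sd_cm3 must be > 0")
  if (spec$volume_scale <= 0) stop("volume_scale must be > 0")
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic cohort of dentate phantoms
#'
#' Draws per-subject covariates (age, sex, TIV), per-subject dentate
#' susceptibility and volume around group means shifted by the cohort
#' effects, builds each subject's ground-truth phantom, records true VOI
#' metrics in the cohort table, and (optionally) simulates and writes each
#' subject's multi-echo acquisition and ground-truth volumes as NIfTI.
#'
#' @param spec A [cohort_spec()].
#' @param phantom A [phantom_spec()] used as the base geometry; per-subject
#'   shell radii and susceptibilities are varied around it.
#' @param dir Output directory; NULL keeps everything in memory.
#' @param write_echoes Also write per-echo magnitude/phase NIfTIs (only
#'   relevant with `dir`).
#' @param keep_volumes Keep per-subject `truth`/`echoes` objects in the
#'   returned list (default: only when `dir` is NULL).
#' @return A `dn_cohort` object: `table` (the cohort table), `spec`,
#'   `phantom`, and (optionally) `subjects`.
#' @export
make_cohort <- function(spec = cohort_spec(), phantom = phantom_spec(),
                        dir = NULL, write_echoes = TRUE,
                        keep_volumes = is.null(dir)) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(phantom, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients + spec$n_controls
  group <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  age <- stats::runif(n, spec$age_range_years[1], spec$age_range_years[2])
  sex <- sample(c("m", "f"), n, replace = TRUE)
  tiv <- stats::rnorm(n, spec$tiv_mean_cm3, spec$tiv_sd_cm3)
  dchi <- stats::rnorm(n, ifelse(group == "patient", spec$delta_chi_ppb, 0),
                       spec$chi_sd_ppb)
  vnoise <- stats::rnorm(n, 0, spec$volume_noise_sd)
  sara_noise <- stats::rnorm(n, 0, spec$sara_model$sd)
  ctrl_sara <- round(2 * abs(stats::rnorm(n, 0, 0.3))) / 2

  # nominal bulk volume of the base geometry
  base <- make_dentate_phantom(phantom)
  v_nom <- sum(base$dn_bulk > 0) * phantom$voxel_size_mm^3

  rows <- vector("list", n)
  subjects <- if (keep_volumes) vector("list", n) else NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(n)) {
    id <- sprintf("S%02d", i)
    gfac <- if (group[i] == "patient") spec$volume_scale else 1
    v_target <- v_nom * gfac +
      spec$volume_tiv_slope * (tiv[i] - spec$tiv_mean_cm3) + vnoise[i]
    v_target <- max(v_target, 0.2 * v_nom)
    sfac <- (v_target / v_nom)^(1 / 3)
    sseed <- child_seed(spec$seed, i)
    pspec <- phantom
    pspec$shell_radii_mm <- phantom$shell_radii_mm * sfac
    pspec$wall_chi_ppb <- phantom$wall_chi_ppb + dchi[i]
    pspec$interior_chi_ppb <- phantom$interior_chi_ppb + dchi[i]
    pspec$seed <- sseed
    truth <- make_dentate_phantom(pspec)
    m_sil <- voi_metrics(truth$chi_ppb, truth$dn_sil,
                         voxel_size_mm = pspec$voxel_size_mm)
    m_bulk <- voi_metrics(truth$chi_ppb, truth$dn_bulk,
                          voxel_size_mm = pspec$voxel_size_mm)
    sara <- if (group[i] == "patient") {
      s <- spec$sara_model$intercept +
        spec$sara_model$slope_volume * (m_bulk$volume_mm3 - v_nom * gfac) +
        spec$sara_model$slope_chi * (dchi[i] - spec$delta_chi_ppb) +
        spec$sara_model$slope_age * (age[i] - mean(spec$age_range_years)) +
        sara_noise[i]
      min(max(s, 0), 40)
    } else {
      min(ctrl_sara[i], 2)
    }
    row <- data.frame(
      subject_id = id, group = group[i], age_years = age[i], sex = sex[i],
      sara = sara, tiv_cm3 = tiv[i],
      true_sil_volume_mm3 = m_sil$volume_mm3,
      true_sil_chi_ppb = m_sil$mean_chi_ppb,
      true_bulk_volume_mm3 = m_bulk$volume_mm3,
      true_bulk_chi_ppb = m_bulk$mean_chi_ppb,
      true_bulk_mass_ppb_cm3 = m_bulk$chi_mass_ppb_cm3,
      subject_seed = sseed, stringsAsFactors = FALSE)

    echoes <- NULL
    if (write_echoes || keep_volumes)
      echoes <- simulate_acquisition(truth, seed = sseed)
    if (!is.null(dir)) {
      vs <- pspec$voxel_size_mm
      pre <- file.path(dir, id)
      write_nifti_vol(truth$chi_ppb, paste0(pre, "_chi_true.nii"), vs)
      write_nifti_vol(truth$r2star, paste0(pre, "_r2star_true.nii"), vs)
      write_nifti_vol(truth$brain_mask, paste0(pre, "_brain_mask.nii"), vs)
      write_nifti_vol(truth$dn_sil, paste0(pre, "_dn_sil.nii"), vs)
      write_nifti_vol(truth$dn_bulk, paste0(pre, "_dn_bulk_true.nii"), vs)
      write_nifti_vol(truth$field_true_hz, paste0(pre, "_field_true.nii"), vs)
      if (write_echoes) {
        for (k in seq_along(echoes$tes_s)) {
          write_nifti_vol(echoes$magnitude[[k]],
                          sprintf("%s_echo%d_mag.nii", pre, k), vs)
          write_nifti_vol(echoes$phase[[k]],
                          sprintf("%s_echo%d_phase.nii", pre, k), vs)
        }
      }
    }
    rows[[i]] <- row
    if (keep_volumes) subjects[[i]] <- list(truth = truth, echoes = echoes)
  }
  table <- do.call(rbind, rows)
  if (!is.null(dir)) write_tsv(table, file.path(dir, "cohort.tsv"))
  structure(list(table = table, spec = spec, phantom = phantom,
                 subjects = subjects), class = "dn_cohort")
}

#' @export
print.dn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic dentate cohort: %d patients, %d controls\n",
              sum(x$table$group == "patient"),
              sum(x$table$group == "control")))
  invisible(x)
}
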