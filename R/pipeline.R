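#' Default pipeline configuration
#'
#' Nested named list covering every stage: phantom geometry, cohort effects,
#' reconstruction (SHARP radii 1..10, high-pass 0.01, TKD inversion), VOI
#' construction (R2* CSF cutoff 15 1/s), VOI statistics (alpha 0.05, Sidak
#' post hocs), and voxelwise analysis (1 mm FWHM smoothing, TFCE,
#' permutation count).  The demo scale (6 per group on a 48^3 grid) keeps a
#' full run interactive.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  ph <- lapply(formals(phantom_spec), eval)
  co <- lapply(formals(cohort_spec), eval)
  ph$seed <- NULL
  co$seed <- NULL
  # demo scale: small enough for an interactive full run
  ph$grid_shape <- c(56, 56, 56)
  ph$brain_radii_mm <- c(10, 10, 10)
  ph$shell_center_mm <- c(4.2, 0, -0.7)
  ph$shell_radii_mm <- c(2.5, 2.1, 1.9)
  ph$wall_thickness_mm <- 0.8
  co$n_patients <- 6
  co$n_controls <- 6
  list(
    work_dir = "dentateqsm_run",
    seed = 1L,
    phantom = ph,
    cohort = co,
    recon = list(radii_voxels = 1:10, highpass_threshold = 0.01,
                 method = "tikhonov", tkd_threshold = 0.2,
                 tikhonov_lambda = 1e-3, psf_correction = TRUE,
                 denoise_strength = 0),
    voi = list(r2star_min = 15),
    stats = list(alpha = 0.05, sidak = TRUE),
    voxelwise = list(n_perm = 200, fwhm_mm = 1, height_exponent = 2,
                     extent_exponent = 0.5, connectivity = 26)
  )
}

check_num <- function(errs, val, name, lo = -Inf, hi = Inf, len = 1) {
  if (!is.numeric(val) || length(val) != len)
    return(c(errs, sprintf("%s must be numeric of length %d", name, len)))
  if (any(val < lo) || any(val > hi))
    return(c(errs, sprintf("%s must be in [%g, %g]", name, lo, hi)))
  errs
}

#' Validate and complete a pipeline configuration
#'
#' Fills unspecified keys from [default_config()], rejects unknown keys,
#' and checks types and ranges; all violations are reported together in a
#' single error.
#'
#' @param raw Nested list (e.g. from [read_config()]); NULL gives the full
#'   defaults.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(raw = NULL) {
  def <- default_config()
  if (is.null(raw)) raw <- list()
  errs <- character(0)
  bad_top <- setdiff(names(raw), names(def))
  if (length(bad_top))
    errs <- c(errs, paste("unknown key(s):", paste(bad_top, collapse = ", ")))
  for (sec in intersect(names(raw), names(def))) {
    if (is.list(def[[sec]]) && !is.null(names(def[[sec]]))) {
      bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
      if (length(bad))
        errs <- c(errs, sprintf("unknown key(s) in %s: %s", sec,
                                paste(bad, collapse = ", ")))
    }
  }
  cfg <- utils::modifyList(def, raw[intersect(names(raw), names(def))])
  # canonical serializable forms (YAML maps/sequences keep these intact):
  # polynomial coefficients as a named list, dipole sources as a list of
  # x/y/z triplets
  bp <- cfg$phantom$background_poly_coeffs
  cfg$phantom$background_poly_coeffs <- as.list(unlist(bp))
  esp <- cfg$phantom$external_source_positions
  if (is.matrix(esp)) esp <- lapply(seq_len(nrow(esp)), function(i)
    unname(esp[i, ]))
  if (is.numeric(esp)) esp <- list(esp)
  cfg$phantom$external_source_positions <- lapply(esp, function(v) {
    v <- unname(unlist(v))
    if (length(v) != 3) errs <<- c(errs,
      "phantom$external_source_positions entries must be x/y/z triplets")
    v
  })
  cfg$phantom$external_source_strengths <-
    unname(unlist(cfg$phantom$external_source_strengths))
  r <- cfg$recon$radii_voxels
  if (!is.numeric(r) || any(r <= 0) || any(diff(r) <= 0))
    errs <- c(errs, "recon$radii_voxels: radii must be increasing")
  if (!is.numeric(cfg$recon$highpass_threshold) ||
      cfg$recon$highpass_threshold <= 0 || cfg$recon$highpass_threshold >= 1)
    errs <- c(errs, "recon$highpass_threshold must be in (0, 1)")
  if (!cfg$recon$method %in% c("tkd", "tikhonov"))
    errs <- c(errs, "recon$method must be 'tkd' or 'tikhonov'")
  errs <- check_num(errs, cfg$stats$alpha, "stats$alpha", 0, 1)
  errs <- check_num(errs, cfg$voi$r2star_min, "voi$r2star_min", 0, Inf)
  errs <- check_num(errs, cfg$voxelwise$n_perm, "voxelwise$n_perm", 20, Inf)
  errs <- check_num(errs, cfg$voxelwise$fwhm_mm, "voxelwise$fwhm_mm", 0, Inf)
  errs <- check_num(errs, cfg$seed, "seed", 1, 2^31 - 1)
  errs <- check_num(errs, cfg$phantom$grid_shape, "phantom$grid_shape",
                    16, Inf, len = 3)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration file (YAML)
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

stage_files_ok <- function(files, old_manifest) {
  if (length(files) == 0 || is.null(old_manifest)) return(FALSE)
  if (!setequal(old_manifest$path, files)) return(FALSE)
  if (!all(file.exists(files))) return(FALSE)
  sums <- unname(tools::md5sum(files))
  all(sums == old_manifest$md5[match(files, old_manifest$path)])
}

manifest_of <- function(files) {
  data.frame(path = files, md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate -> reconstruct -> voi -> stats -> voxelwise from one
#' configuration, writing all intermediates under `work_dir` and a JSON run
#' report (parameter echo, per-stage status and timing, output manifest
#' with checksums).  Stages whose outputs already exist with matching
#' checksums are skipped unless `force = TRUE`; a corrupted intermediate is
#' detected by its checksum and the stage re-run.  A stage failure aborts
#' with the failing stage named; prior outputs are retained.
#'
#' @param config A `pipeline_config` (see [validate_config()]).
#' @param force Re-run all stages even when outputs are up to date.
#' @return The run report (list), invisibly written as
#'   `work_dir/run_report.json`.
#' @export
run_pipeline <- function(config = validate_config(), force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$work_dir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  report_path <- file.path(wd, "run_report.json")
  old <- if (file.exists(report_path))
    jsonlite::read_json(report_path, simplifyVector = TRUE) else NULL
  report <- list(config = unclass(config), stages = list())

  stage_defs <- list(
    simulate = stage_simulate, reconstruct = stage_reconstruct,
    voi = stage_voi, stats = stage_stats, voxelwise = stage_voxelwise)

  for (si in seq_along(stage_defs)) {
    nm <- names(stage_defs)[si]
    expected <- stage_expected_files(nm, config)
    old_man <- NULL
    if (!is.null(old$stages[[nm]]$files))
      old_man <- as.data.frame(old$stages[[nm]]$files)
    if (!force && stage_files_ok(expected, old_man)) {
      report$stages[[nm]] <- list(status = "skipped",
                                  files = manifest_of(expected),
                                  seconds = 0)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stage_defs[[si]](config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[nm]] <- list(status = "failed",
                                  message = conditionMessage(res))
      jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", nm,
                   conditionMessage(res)))
    }
    report$stages[[nm]] <- list(status = "done", files = manifest_of(res),
                                seconds = proc.time()[["elapsed"]] - t0)
  }
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}

stage_expected_files <- function(stage, cfg) {
  wd <- cfg$work_dir
  n <- cfg$cohort$n_patients + cfg$cohort$n_controls
  ids <- sprintf("S%02d", seq_len(n))
  switch(stage,
    simulate = c(file.path(wd, "cohort.tsv"),
                 as.vector(vapply(ids, function(id) c(
                   file.path(wd, paste0(id, c("_chi_true.nii",
                     "_r2star_true.nii", "_brain_mask.nii", "_dn_sil.nii",
                     "_dn_bulk_true.nii", "_field_true.nii"))),
                   file.path(wd, sprintf("%s_echo%d_%s.nii", id,
                     rep(1:4, each = 2), rep(c("mag", "phase"), 4))))
                   , character(14)))),
    reconstruct = c(file.path(wd, "recon_params.json"),
                    file.path(wd, paste0(ids, "_chi_recon.nii")),
                    file.path(wd, paste0(ids, "_r2star_fit.nii"))),
    voi = file.path(wd, "metrics.tsv"),
    stats = c(file.path(wd, "stats_report.json"),
              file.path(wd, "stats_report.txt")),
    voxelwise = c(file.path(wd, "voxelwise_t.nii"),
                  file.path(wd, "voxelwise_tfce.nii"),
                  file.path(wd, "voxelwise_p_fwe_pos.nii"),
                  file.path(wd, "voxelwise_p_fwe_neg.nii"),
                  file.path(wd, "voxelwise_summary.json")))
}

build_phantom_spec <- function(cfg) {
  ph <- cfg$phantom
  ph$background_poly_coeffs <- unlist(ph$background_poly_coeffs)
  ph$external_source_positions <- do.call(rbind, ph$external_source_positions)
  do.call(phantom_spec, c(ph, list(seed = child_seed(cfg$seed, 1))))
}

stage_simulate <- function(cfg) {
  ph <- build_phantom_spec(cfg)
  cs <- do.call(cohort_spec, c(cfg$cohort, list(seed = child_seed(cfg$seed, 2))))
  make_cohort(cs, ph, dir = cfg$work_dir, keep_volumes = FALSE)
  stage_expected_files("simulate", cfg)
}

stage_reconstruct <- function(cfg) {
  wd <- cfg$work_dir
  tab <- read_tsv(file.path(wd, "cohort.tsv"))
  scfg <- sharp_config(cfg$recon$radii_voxels, cfg$recon$highpass_threshold)
  icfg <- inversion_config(cfg$recon$method, cfg$recon$tkd_threshold,
                           cfg$recon$tikhonov_lambda,
                           cfg$recon$psf_correction)
  for (id in tab$subject_id) {
    pre <- file.path(wd, id)
    brain <- read_nifti_vol(paste0(pre, "_brain_mask.nii"))
    vs <- brain$voxel_size_mm
    mags <- phs <- list()
    for (k in 1:4) {
      mags[[k]] <- read_nifti_vol(sprintf("%s_echo%d_mag.nii", pre, k))$vol
      phs[[k]] <- read_nifti_vol(sprintf("%s_echo%d_phase.nii", pre, k))$vol
    }
    echoes <- structure(list(magnitude = mags, phase = phs,
                             tes_s = qsm_default_tes(), voxel_size_mm = vs,
                             dim = dim(brain$vol)), class = "echo_series")
    rec <- reconstruct_qsm(echoes, brain$vol > 0.5, scfg, icfg,
                           denoise_strength = cfg$recon$denoise_strength)
    write_nifti_vol(rec$chi_ppb, paste0(pre, "_chi_recon.nii"), vs)
    write_nifti_vol(rec$r2star, paste0(pre, "_r2star_fit.nii"), vs)
  }
  jsonlite::write_json(cfg$recon, file.path(wd, "recon_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_expected_files("reconstruct", cfg)
}

stage_voi <- function(cfg) {
  wd <- cfg$work_dir
  tab <- read_tsv(file.path(wd, "cohort.tsv"))
  rows <- list()
  for (id in tab$subject_id) {
    pre <- file.path(wd, id)
    chi <- read_nifti_vol(paste0(pre, "_chi_recon.nii"))
    vs <- chi$voxel_size_mm
    sil <- read_nifti_vol(paste0(pre, "_dn_sil.nii"))$vol
    brain <- read_nifti_vol(paste0(pre, "_brain_mask.nii"))$vol > 0.5
    r2 <- read_nifti_vol(paste0(pre, "_r2star_fit.nii"))$vol
    sil_m <- split_hemispheres(sil, brain, vs, kind = "sil")
    bulk_m <- build_dn_bulk(sil_m, r2, cfg$voi$r2star_min)
    for (kind in c("sil", "bulk")) {
      mk <- if (kind == "sil") sil_m else bulk_m
      met <- voi_metrics(chi$vol, mk)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = id, voi_kind = kind, volume_mm3 = met$volume_mm3,
        mean_chi_ppb = met$mean_chi_ppb,
        chi_mass_ppb_cm3 = met$chi_mass_ppb_cm3,
        stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, rows), file.path(wd, "metrics.tsv"))
  stage_expected_files("voi", cfg)
}

stage_stats <- function(cfg) {
  wd <- cfg$work_dir
  tab <- read_tsv(file.path(wd, "cohort.tsv"))
  met <- read_tsv(file.path(wd, "metrics.tsv"))
  is_ctl <- tab$group == "control"
  res <- list()
  txt <- c("VOI-based statistical report", "")
  group_ps <- c()
  for (kind in c("sil", "bulk")) {
    mk <- met[met$voi_kind == kind, ]
    mk <- mk[match(tab$subject_id, mk$subject_id), ]
    rz <- residualize(mk$volume_mm3, tab$tiv_cm3, is_ctl)
    measures <- list(volume_z = rz$z, mean_chi_ppb = mk$mean_chi_ppb,
                     chi_mass_ppb_cm3 = mk$chi_mass_ppb_cm3)
    for (mn in names(measures)) {
      an <- ancova(measures[[mn]], tab$group, tab$age_years)
      key <- paste0(kind, "_", mn)
      res$ancova[[key]] <- an
      group_ps[key] <- an$p[an$term == "group"]
      txt <- c(txt, sprintf(
        "%s: F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f",
        key, an$df_effect[1], an$df_error[1], an$F[1], an$p[1],
        an$partial_eta_squared[1]))
    }
    res$residualization[[kind]] <- rz$model
    pat <- tab$group == "patient"
    res$sara_correlations[[kind]] <- if (sum(pat) >= 5) {
      lapply(measures, function(v) {
        co <- partial_spearman(v[pat], tab$sara[pat], tab$age_years[pat])
        list(r = co$r, p = co$p, n = co$n)
      })
    } else list(note = "fewer than 5 patients: correlations not computed")
  }
  if (isTRUE(cfg$stats$sidak)) {
    res$group_p_sidak <- as.list(setNames(
      sidak_adjust(unname(group_ps), m = length(group_ps)), names(group_ps)))
  }
  res$demographics <- cohort_summary(tab, c("age_years", "sara", "tiv_cm3"))
  res$alpha <- cfg$stats$alpha
  jsonlite::write_json(res, file.path(wd, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(txt, file.path(wd, "stats_report.txt"))
  stage_expected_files("stats", cfg)
}

stage_voxelwise <- function(cfg) {
  wd <- cfg$work_dir
  tab <- read_tsv(file.path(wd, "cohort.tsv"))
  vs <- NULL
  maps <- list()
  mask <- NULL
  for (i in seq_len(nrow(tab))) {
    pre <- file.path(wd, tab$subject_id[i])
    chi <- read_nifti_vol(paste0(pre, "_chi_recon.nii"))
    vs <- chi$voxel_size_mm
    maps[[i]] <- smooth_gaussian(chi$vol, cfg$voxelwise$fwhm_mm, vs)
    bulk <- read_nifti_vol(paste0(pre, "_dn_bulk_true.nii"))$vol > 0.5
    mask <- if (is.null(mask)) bulk else mask | bulk
  }
  pat <- tab$group == "patient"
  tcfg <- tfce_config(cfg$voxelwise$height_exponent,
                      cfg$voxelwise$extent_exponent,
                      connectivity = cfg$voxelwise$connectivity)
  pr <- permutation_fwe(maps[pat], maps[!pat],
                        c(tab$age_years[pat], tab$age_years[!pat]),
                        n_perm = cfg$voxelwise$n_perm, cfg = tcfg,
                        mask = mask, seed = child_seed(cfg$seed, 5))
  write_nifti_vol(pr$t_map, file.path(wd, "voxelwise_t.nii"), vs)
  write_nifti_vol(pr$tfce_map, file.path(wd, "voxelwise_tfce.nii"), vs)
  write_nifti_vol(pr$p_fwe_pos, file.path(wd, "voxelwise_p_fwe_pos.nii"), vs)
  write_nifti_vol(pr$p_fwe_neg, file.path(wd, "voxelwise_p_fwe_neg.nii"), vs)
  alpha <- cfg$stats$alpha
  jsonlite::write_json(list(
    n_perm = pr$n_perm, alpha = alpha,
    n_sig_pos = sum(pr$p_fwe_pos[mask] < alpha),
    n_sig_neg = sum(pr$p_fwe_neg[mask] < alpha),
    mask_voxels = sum(mask)),
    file.path(wd, "voxelwise_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  stage_expected_files("voxelwise", cfg)
}
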