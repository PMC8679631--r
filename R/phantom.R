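#' Digital 4D liver phantom configuration
#'
#' Defines a seeded dynamic FLT liver phantom: a cirrhotic liver background
#' with high physiologic delivery, a blood pool, and one or more spherical
#' tumors whose kinetics span the fitted-parameter ranges of the clinical
#' cohort. Every voxel's noise-free TAC is the two-tissue-compartment forward
#' model of its tissue driven by the configured input function; frame noise
#' is zero-mean Gaussian with `SD = noise_coeff * sqrt(value /
#' frame_duration)` (the usual count-statistics scaling), clipped at 0.
#'
#' @param grid_dim Grid size in voxels (length 3).
#' @param voxel_mm Voxel size in mm (scalar or length 3).
#' @param schedule A [frame_schedule()].
#' @param aif_params [aif_params()] of the simulated whole-blood bolus.
#' @param parent_model [parent_fraction_model()] for metabolite correction.
#' @param plasma_to_blood Constant plasma-to-whole-blood ratio.
#' @param liver_params Liver background kinetics: a high-delivery,
#'   low-trapping [two_tissue_params()] default reproduces the high summed
#'   liver signal that makes HCC conspicuity difficult.
#' @param lesions List of [phantom_lesion()]s (centers in voxel indices).
#' @param liver_center,liver_semiaxes Liver ellipsoid, voxel units.
#' @param blood_center_xy,blood_radius_mm,blood_z Blood-pool cylinder
#'   (x, y center in voxels, radius in mm, z index range).
#' @param noise_coeff Dimensionless noise coefficient; 0 disables noise.
#' @param seed Integer seed; phantom output is a pure function of the config.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(40, 40, 24), voxel_mm = 3,
                           schedule = default_frame_schedule(),
                           aif_params = fltpet::aif_params(),
                           parent_model = parent_fraction_model(),
                           plasma_to_blood = 1,
                           liver_params = two_tissue_params(0.25, 0.9, 0.02,
                                                            0.01, 0.1),
                           lesions = list(phantom_lesion()),
                           liver_center = NULL, liver_semiaxes = NULL,
                           blood_center_xy = NULL, blood_radius_mm = 6,
                           blood_z = NULL,
                           noise_coeff = 0.5, seed = 1) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3)
  if (noise_coeff < 0) abort("noise_coeff must be >= 0")
  liver_center <- liver_center %||% (grid_dim / 2)
  liver_semiaxes <- liver_semiaxes %||% (grid_dim * c(0.30, 0.33, 0.38))
  blood_center_xy <- blood_center_xy %||% c(round(grid_dim[1] * 0.9),
                                            round(grid_dim[2] / 2))
  blood_z <- blood_z %||% c(2L, grid_dim[3] - 1L)
  structure(list(grid_dim = as.integer(grid_dim), voxel_mm = voxel_mm,
                 schedule = schedule, aif_params = aif_params,
                 parent_model = parent_model,
                 plasma_to_blood = plasma_to_blood,
                 liver_params = liver_params, lesions = lesions,
                 liver_center = liver_center, liver_semiaxes = liver_semiaxes,
                 blood_center_xy = blood_center_xy,
                 blood_radius_mm = blood_radius_mm, blood_z = blood_z,
                 noise_coeff = noise_coeff, seed = as.integer(seed)),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @param center Sphere center, voxel indices.
#' @param diameter_mm Lesion diameter in mm; the study's lesions ranged
#'   10-117 mm (median 29.5), so the default is a 30-mm sphere.
#' @param params Lesion [two_tissue_params()]; the default is the cohort's
#'   patient-3 fit.
#' @export
phantom_lesion <- function(center = c(20, 20, 12), diameter_mm = 30,
                           params = two_tissue_params(0.31, 0.40, 0.24,
                                                      0.04, 0.019)) {
  if (diameter_mm <= 0) abort("diameter_mm must be positive")
  structure(list(center = center, diameter_mm = diameter_mm, params = params),
            class = "phantom_lesion")
}

sphere_mask <- function(grid_dim, voxel_mm, center, diameter_mm) {
  cx <- (seq_len(grid_dim[1]) - center[1]) * voxel_mm[1]
  cy <- (seq_len(grid_dim[2]) - center[2]) * voxel_mm[2]
  cz <- (seq_len(grid_dim[3]) - center[3]) * voxel_mm[3]
  r2 <- (diameter_mm / 2)^2
  outer(outer(cx^2, cy^2, `+`), cz^2, `+`) <= r2
}

ellipsoid_mask <- function(grid_dim, center, semiaxes) {
  cx <- ((seq_len(grid_dim[1]) - center[1]) / semiaxes[1])^2
  cy <- ((seq_len(grid_dim[2]) - center[2]) / semiaxes[2])^2
  cz <- ((seq_len(grid_dim[3]) - center[3]) / semiaxes[3])^2
  outer(outer(cx, cy, `+`), cz, `+`) <= 1
}

phantom_aif <- function(config, grid_dt = 0.05) {
  t_end <- max(config$schedule$end_min)
  wb <- feng_aif(config$aif_params, seq(0, t_end, by = grid_dt))
  metabolite_correct(wb, config$parent_model,
                     plasma_to_blood = config$plasma_to_blood)
}

#' Generate a seeded dynamic liver phantom
#'
#' Builds the tissue geometry, evaluates each tissue's noise-free
#' frame-averaged TAC from the forward compartment model, broadcasts the
#' curves onto the voxel grid, and adds seeded frame-scaled Gaussian noise.
#' The same config (including seed) always yields bit-identical output.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom`: `series` (noisy [pet_series()]),
#'   `truth` (class masks as [roi_mask()]s, per-tissue true parameters, the
#'   noise-free series, the simulated [aif()] and per-tissue frame TACs), and
#'   the `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  gd <- config$grid_dim; vox <- config$voxel_mm; sched <- config$schedule
  nf <- nrow(sched)

  liver <- ellipsoid_mask(gd, config$liver_center, config$liver_semiaxes)
  bx <- config$blood_center_xy[1]; by <- config$blood_center_xy[2]
  dx <- (seq_len(gd[1]) - bx) * vox[1]; dy <- (seq_len(gd[2]) - by) * vox[2]
  disc <- outer(dx^2, dy^2, `+`) <= config$blood_radius_mm^2
  blood <- array(FALSE, gd)
  for (z in config$blood_z[1]:config$blood_z[2]) blood[, , z] <- disc
  if (any(blood & liver))
    abort("config-error: blood pool overlaps the liver")

  lesion_masks <- lapply(config$lesions, function(l) {
    m <- sphere_mask(gd, vox, l$center, l$diameter_mm)
    if (!any(m)) abort("config-error: lesion lies outside the grid")
    if (any(m & blood)) abort("config-error: lesion overlaps the blood pool")
    m
  })
  if (length(lesion_masks) > 1L) {
    tot <- Reduce(`+`, lapply(lesion_masks, function(m) m * 1L))
    if (any(tot > 1L)) abort("config-error: lesions overlap")
  }
  lesion_all <- Reduce(`|`, lesion_masks, array(FALSE, gd))
  liver_only <- liver & !lesion_all & !blood

  aif_obj <- phantom_aif(config)
  t_end <- max(sched$end_min)
  frame_tac <- function(params) {
    fine <- model_tac_fine(params, aif_obj, t_max = t_end)
    frame_average(tac(fine$t, fine$ct), sched)$value
  }
  wb_frames <- frame_average(
    tac(aif_obj$time_min, aif_obj$whole_blood), sched)$value

  tissue_curves <- rbind(
    air = numeric(nf),
    liver = frame_tac(config$liver_params),
    blood = wb_frames,
    do.call(rbind, lapply(config$lesions, function(l) frame_tac(l$params)))
  )
  lesion_names <- paste0("tumor_", seq_along(config$lesions))
  rownames(tissue_curves) <- c("air", "liver", "blood", lesion_names)

  class_idx <- array(1L, gd)
  class_idx[liver_only] <- 2L
  class_idx[blood] <- 3L
  for (i in seq_along(lesion_masks)) class_idx[lesion_masks[[i]]] <- 3L + i

  clean_mat <- tissue_curves[as.vector(class_idx), , drop = FALSE]
  clean <- array(clean_mat, dim = c(gd, nf))

  if (config$noise_coeff > 0) {
    sd_mat <- config$noise_coeff *
      sqrt(sweep(clean_mat, 2, sched$duration_min, "/"))
    z <- with_seed(config$seed,
                   matrix(rnorm(length(sd_mat)), nrow(sd_mat), ncol(sd_mat)))
    noisy <- pmax(clean_mat + sd_mat * z, 0)
    noisy <- array(noisy, dim = c(gd, nf))
  } else {
    noisy <- clean
  }

  masks <- c(
    list(liver = roi_mask(liver_only, "liver"),
         blood = roi_mask(blood, "blood_pool")),
    setNames(lapply(lesion_masks, roi_mask, label = "tumor"), lesion_names)
  )
  true_params <- c(list(liver = config$liver_params),
                   setNames(lapply(config$lesions, `[[`, "params"),
                            lesion_names))

  structure(
    list(series = pet_series(noisy, vox, sched),
         truth = list(class_masks = masks, params = true_params,
                      noise_free = pet_series(clean, vox, sched),
                      aif = aif_obj,
                      tissue_tacs = tissue_curves),
         config = config),
    class = "phantom"
  )
}

#' Simulate the post-TACE scan of a phantom
#'
#' Chemoembolization abruptly cuts the tumor's arterial supply, so its
#' delivery `K1` (and, for responding tumors, trapping `k3`) falls while the
#' liver background is unchanged. Factors are multiplicative on the baseline
#' lesion parameters and must lie in `(0, 1]`; factors of exactly 1 with the
#' same seed reproduce the baseline scan bit-identically.
#'
#' @param phantom A [generate_phantom()] result.
#' @param k1_factor,k3_factor Multiplicative factors on each lesion's `K1`
#'   and `k3` (scalar or one per lesion).
#' @param seed Optional seed override for the post scan (defaults to the
#'   baseline seed).
#' @return A `phantom` of the post-treatment scan.
#' @export
simulate_post_tace <- function(phantom, k1_factor = 0.34, k3_factor = 0.5,
                               seed = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  nl <- length(phantom$config$lesions)
  k1_factor <- rep_len(k1_factor, nl); k3_factor <- rep_len(k3_factor, nl)
  if (any(k1_factor <= 0 | k1_factor > 1) || any(k3_factor <= 0 | k3_factor > 1))
    abort("factors must be in (0, 1]")
  config <- phantom$config
  config$lesions <- purrr::map2(config$lesions, seq_len(nl), function(l, i) {
    p <- l$params
    l$params <- two_tissue_params(p$k1 * k1_factor[i], p$k2,
                                  p$k3 * k3_factor[i], p$k4, p$vb)
    l
  })
  if (!is.null(seed)) config$seed <- as.integer(seed)
  generate_phantom(config)
}
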