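#' Dynamic PET series
#'
#' Container for a 4D dynamic PET acquisition: an `(x, y, z, frame)` array of
#' activity concentrations (kBq/mL), the voxel size in mm, and the frame
#' schedule. Decay correction is assumed to have been applied during
#' reconstruction, as is standard for clinical PET; the assumption is recorded
#' in the `decay_corrected` field.
#'
#' @param values 4D numeric array `(x, y, z, frame)`, all values `>= 0`.
#' @param voxel_mm Voxel edge lengths in mm (length 3, or a scalar recycled).
#' @param schedule A [frame_schedule()] whose length matches `dim(values)[4]`.
#' @param decay_corrected Flag recording that input activities are
#'   decay-corrected to injection time.
#' @return An object of class `pet_series`.
#' @export
pet_series <- function(values, voxel_mm, schedule, decay_corrected = TRUE) {
  if (length(dim(values)) != 4L) abort("values must be a 4D array")
  if (any(values < 0, na.rm = TRUE)) abort("activity concentrations must be >= 0")
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(values)[4] != nrow(schedule))
    abort("frame axis length must equal the schedule length")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    abort("voxel_mm must be 3 positive lengths")
  structure(
    list(values = values, voxel_mm = as.numeric(voxel_mm),
         schedule = schedule, decay_corrected = isTRUE(decay_corrected)),
    class = "pet_series"
  )
}

#' @export
print.pet_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_series> %d x %d x %d voxels, %d frames (%.1f min), voxel %s mm\n",
              d[1], d[2], d[3], d[4], max(x$schedule$end_min),
              paste(signif(x$voxel_mm, 3), collapse = " x ")))
  invisible(x)
}

#' Subject metadata for SUV normalization
#'
#' @param injected_mbq Injected activity in MBq, decay-corrected to injection
#'   time; must be positive.
#' @param weight_g Body weight in grams; must be positive.
#' @return An object of class `subject_info`.
#' @examples
#' subject_info(370, 70000)
#' @export
subject_info <- function(injected_mbq, weight_g) {
  if (!is.finite(injected_mbq) || injected_mbq <= 0)
    abort("invalid-subject: injected activity must be positive")
  if (!is.finite(weight_g) || weight_g <= 0)
    abort("invalid-subject: body weight must be positive")
  structure(list(injected_mbq = injected_mbq, weight_g = weight_g),
            class = "subject_info")
}

#' Region-of-interest mask on the image grid
#'
#' Masks live on the voxel grid of the image they index (no world-coordinate
#' resampling); they are logical 3D arrays plus a free-text label such as
#' `"tumor"`, `"background_liver"` or `"blood_pool"`.
#'
#' @param mask Logical 3D array; at least one voxel must be `TRUE`.
#' @param label Free-text tissue label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "roi") {
  if (length(dim(mask)) != 3L) abort("mask must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) abort("mask must contain at least one voxel")
  structure(list(mask = mask, label = as.character(label)), class = "roi_mask")
}

check_grid <- function(vol_dim, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(as.integer(vol_dim[1:3]), as.integer(dim(mask$mask))))
    abort("geometry-error: mask grid does not match the image grid")
  invisible(TRUE)
}

frames_in_window <- function(schedule, window) {
  if (length(window) != 2L || window[2] <= window[1])
    abort("invalid-window: window must be an increasing (start, end) pair in minutes")
  which(schedule$mid_min >= window[1] & schedule$mid_min <= window[2])
}

#' Summed (static) image over a time window
#'
#' Collapses a dynamic series into the static volume on which ROIs are drawn:
#' the voxelwise duration-weighted mean concentration over all frames whose
#' mid-time falls in the window.
#'
#' @param series A [pet_series()].
#' @param window Numeric `(start, end)` in minutes; defaults to the 50-60 min
#'   late window used for "SUV at 60 min".
#' @return A 3D array of mean concentrations (kBq/mL).
#' @export
summed_image <- function(series, window = c(50, 60)) {
  stopifnot(inherits(series, "pet_series"))
  idx <- frames_in_window(series$schedule, window)
  if (length(idx) == 0L)
    abort("invalid-window: no frame mid-time falls inside the window")
  w <- series$schedule$duration_min[idx]
  w <- w / sum(w)
  d <- dim(series$values)
  out <- array(0, dim = d[1:3])
  for (k in seq_along(idx)) out <- out + w[k] * series$values[, , , idx[k]]
  out
}

#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV convention: `SUV = C[kBq/mL] / (injected[MBq] * 1000 /
#' weight[g])`, a dimensionless value in the g/mL sense. Doubling the injected
#' activity halves the SUV.
#'
#' @param volume Numeric array (any shape) of concentrations in kBq/mL.
#' @param subject A [subject_info()].
#' @return Array of SUVs with the same shape.
#' @examples
#' compute_suv(5.2857, subject_info(370, 70000))
#' @export
compute_suv <- function(volume, subject) {
  stopifnot(inherits(subject, "subject_info"))
  volume / (subject$injected_mbq * 1000 / subject$weight_g)
}

#' SUV summary statistics over an ROI
#'
#' @param suv_volume 3D SUV array.
#' @param mask A [roi_mask()] on the same grid.
#' @return A one-row tibble: `label`, `suv_mean`, `suv_max`, `n_voxels`.
#' @export
suv_stats <- function(suv_volume, mask) {
  check_grid(dim(suv_volume), mask)
  v <- suv_volume[mask$mask]
  tibble(label = mask$label, suv_mean = mean(v), suv_max = max(v),
         n_voxels = length(v))
}

#' Extract the mean time-activity curve of an ROI
#'
#' Per-frame spatial mean over the mask, sampled at frame mid-times.
#'
#' @param series A [pet_series()].
#' @param mask A [roi_mask()] on the series grid.
#' @return A [tac()] in the series' concentration units.
#' @export
extract_tac <- function(series, mask) {
  stopifnot(inherits(series, "pet_series"))
  check_grid(dim(series$values), mask)
  nf <- dim(series$values)[4]
  m <- matrix(series$values, ncol = nf)[as.vector(mask$mask), , drop = FALSE]
  tac(series$schedule$mid_min, colMeans(m))
}

#' Tumor-to-liver conspicuity ratio
#'
#' Lesion `SUV_max` divided by the background-liver `SUV_mean` of a tumor-free
#' 3-cm liver ROI.
#'
#' @param tumor_suv_max Lesion SUV_max.
#' @param liver_suv_mean Background liver SUV_mean; must be positive.
#' @return The ratio (dimensionless), vectorized.
#' @examples
#' tumor_to_liver_ratio(20.4, 7.7)
#' @export
tumor_to_liver_ratio <- function(tumor_suv_max, liver_suv_mean) {
  if (any(!is.finite(liver_suv_mean)) || any(liver_suv_mean <= 0))
    abort("invalid-background: liver SUV_mean must be positive")
  tumor_suv_max / liver_suv_mean
}

#' Read/write PET volumes as NIfTI-1
#'
#' 4D dynamic volumes pair with a timing sidecar JSON (see
#' [read_frame_schedule()]); masks are NIfTI volumes with 0/1 voxels.
#'
#' @param image Path to a `.nii`/`.nii.gz` 4D image.
#' @param timing Path to the timing sidecar JSON.
#' @return `read_dynamic_pet()` returns a [pet_series()].
#' @export
read_dynamic_pet <- function(image, timing) {
  img <- RNifti::readNifti(image)
  sched <- read_frame_schedule(timing)
  vox <- RNifti::pixdim(img)[1:3]
  pet_series(array(as.numeric(img), dim = dim(img)), voxel_mm = vox,
             schedule = sched)
}

#' @rdname read_dynamic_pet
#' @param series A [pet_series()].
#' @param path Output `.nii.gz` path (timing JSON written alongside as
#'   `<path>.timing.json`).
#' @export
write_dynamic_pet <- function(series, path) {
  stopifnot(inherits(series, "pet_series"))
  img <- RNifti::asNifti(series$values)
  RNifti::pixdim(img) <- c(series$voxel_mm, 1)
  RNifti::writeNifti(img, path)
  write_frame_schedule(series$schedule, paste0(path, ".timing.json"))
  invisible(path)
}

#' @rdname read_dynamic_pet
#' @param label Label attached to the mask read from `path`.
#' @export
read_mask <- function(path, label = "roi") {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) > 0.5, dim = dim(img)[1:3]), label = label)
}

#' @rdname read_dynamic_pet
#' @param mask A [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask$mask),
                                           dim = dim(mask$mask))), path)
  invisible(path)
}
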